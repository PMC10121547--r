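#' Smooth-IC distributional regression (formula interface)
#'
#' Fits the normal location-scale regression with simultaneous BIC-type
#' variable selection in both the mean and the log-variance. The same set of
#' covariates is offered to both components; the smooth-IC penalty decides,
#' per component, which survive. See [fit_mpr_sic()] for the algorithm.
#'
#' @param formula model formula, e.g. `y ~ .`. The intercept is always
#'   included (and never penalized); an explicit `- 1` is ignored.
#' @param data data frame holding the variables.
#' @param model `"mpr"` (covariates in mean and log-variance, default) or
#'   `"spr"` (constant variance).
#' @param penalty `"bic"` (`penalty_weight = log(n)`, default) or `"aic"`
#'   (`penalty_weight = 2`).
#' @param eps_start,eps_end,n_steps telescope settings, see [make_schedule()].
#' @param zero_tol threshold below which final coefficients are set to zero.
#' @param scale,center predictor standardization, see [mpr_data()].
#' @param ... passed on to [fit_mpr_sic()] / [fit_spr_sic()].
#' @return An object of classes `"mpr_sic"` and `"sic_fit"`, supporting
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `logLik`, `predict`,
#'   `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' set.seed(1)
#' n <- 500
#' df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
#' df$y <- 1 + df$x1 + rnorm(n, sd = exp((0.5 + 0.5 * df$x2) / 2))
#' fit <- mpr_sic(y ~ ., df, n_steps = 40)
#' coef(fit)
#' @export
mpr_sic <- function(formula, data, model = c("mpr", "spr"),
                    penalty = c("bic", "aic"),
                    eps_start = 10, eps_end = 1e-5, n_steps = 100L,
                    zero_tol = 1e-8, scale = TRUE, center = FALSE, ...) {
  model <- match.arg(model)
  penalty <- match.arg(penalty)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tt <- stats::terms(mf)
  attr(tt, "intercept") <- 1L
  mm <- stats::model.matrix(tt, mf)
  x <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  d <- mpr_data(y, x, scale = scale, center = center)
  lambda <- if (penalty == "bic") log(length(d$y)) else 2
  sch <- make_schedule(eps_start, eps_end, n_steps)
  fit <- if (model == "mpr")
    fit_mpr_sic(d, sch, penalty_weight = lambda, zero_tol = zero_tol, ...)
  else
    fit_spr_sic(d, sch, penalty_weight = lambda, zero_tol = zero_tol, ...)
  fit$terms <- tt
  fit$penalty <- penalty
  fit$call <- match.call()
  class(fit) <- c("mpr_sic", class(fit))
  fit
}

coef_names <- function(object) {
  cn <- colnames(object$data$X)
  if (is.null(cn)) cn <- c("(intercept)",
                           paste0("x", seq_len(length(object$params_hat$beta) - 1L)))
  cn
}

#' Extract coefficients from a smooth-IC fit
#'
#' @param object a fitted `"sic_fit"`.
#' @param component `"both"` (named vector `b.*`/`a.*`), `"location"` or
#'   `"dispersion"`.
#' @param type `"sparse"` (thresholded, default) or `"raw"` (pre-threshold).
#' @param original_scale if TRUE, map coefficients of scaled predictors back
#'   to the original predictor units (divide by the recorded SDs).
#' @param ... unused.
#' @export
coef.sic_fit <- function(object,
                         component = c("both", "location", "dispersion"),
                         type = c("sparse", "raw"), original_scale = FALSE,
                         ...) {
  component <- match.arg(component)
  type <- match.arg(type)
  pr <- if (type == "sparse") object$params_sparse else object$params_hat
  b <- pr$beta; a <- pr$alpha
  if (original_scale && !is.null(object$data$scale_factors)) {
    b <- unscale_coef(b, object$data$scale_factors, object$data$centers)
    a <- unscale_coef(a, object$data$scale_factors, object$data$centers)
  }
  nm <- coef_names(object)
  names(b) <- names(a) <- nm
  switch(component,
         location = b,
         dispersion = a,
         both = c(stats::setNames(b, paste0("b.", nm)),
                  stats::setNames(a, paste0("a.", nm))))
}

#' @export
vcov.sic_fit <- function(object, ...) {
  nm <- coef_names(object)
  v <- object$cov_hat
  dimnames(v) <- list(c(paste0("b.", nm), paste0("a.", nm)),
                      c(paste0("b.", nm), paste0("a.", nm)))
  v
}

#' @export
logLik.sic_fit <- function(object, ...) {
  structure(object$loglik_sparse, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
print.sic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Smooth-IC %s fit: n = %d, p = %d\n",
              if (identical(x$model, "mpr")) "location-scale (MPR)"
              else "constant-variance (SPR)",
              x$n, length(x$params_hat$beta) - 1L))
  cat(sprintf("log-likelihood %.3f, SIC %.2f, BIC %.2f, df %d%s\n",
              x$loglik, x$sic, x$bic, x$df,
              if (x$converged) "" else " (not fully converged)"))
  cat("\nLocation (beta):\n")
  print(round(coef(x, "location"), digits))
  cat("\nDispersion (alpha, log-variance):\n")
  print(round(coef(x, "dispersion"), digits))
  invisible(x)
}

#' Summarize a smooth-IC fit
#'
#' Builds a coefficient table for the active (selected) effects with sandwich
#' standard errors and Wald confidence intervals; optionally the BIC increase
#' from dropping each active effect from its component ([delta_bic()]), which
#' requires one telescope refit per active non-intercept effect.
#'
#' @param object a fitted `"sic_fit"`.
#' @param level confidence level (default 0.95, using z = 1.96 exactly).
#' @param delta_bic logical; compute BIC-drop importance (default FALSE).
#' @param ... unused.
#' @export
summary.sic_fit <- function(object, level = 0.95, delta_bic = FALSE, ...) {
  tab <- wald_cis(object, level = level)
  if (isTRUE(delta_bic)) {
    dbic <- get("delta_bic", mode = "function")  # arg shadows the function
    tab$delta_bic <- NA_real_
    for (i in seq_len(nrow(tab))) {
      j <- tab$index[i]
      if (j >= 1L)
        tab$delta_bic[i] <- dbic(object, j, tab$component[i])
    }
  }
  out <- list(fit = object, coefficients = tab, level = level)
  class(out) <- "summary.sic_fit"
  out
}

#' @export
print.summary.sic_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nActive coefficients (%.0f%% Wald intervals):\n",
              100 * x$level))
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

# Build the design matrix for new data (formula fits take a data frame;
# matrix-interface fits take a raw predictor matrix), applying the training
# centering/scaling.
newdata_design <- function(object, newdata) {
  if (is.null(newdata)) return(object$data$X)
  if (is.matrix(newdata) || is.null(object$terms)) {
    x <- as.matrix(newdata)
  } else {
    tt <- stats::delete.response(object$terms)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    x <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  if (ncol(x) == ncol(object$data$X)) return(x)  # already has intercept
  x <- sweep(x, 2L, object$data$centers, "-")
  x <- sweep(x, 2L, object$data$scale_factors, "/")
  cbind(1, x)
}

#' Predict from a smooth-IC fit
#'
#' @param object a fitted `"sic_fit"`.
#' @param newdata data frame (formula fits) or predictor matrix on the
#'   original scale (matrix fits); `NULL` predicts the training data. A
#'   matrix with p+1 columns is taken as an already-scaled design with
#'   intercept.
#' @param type `"mean"` (fitted means), `"moments"` (data frame of
#'   conditional mean and variance) or `"prediction"` (95 percent prediction
#'   intervals `fit`, `lwr`, `upr`, `sd`).
#' @param level prediction-interval level.
#' @param ... unused.
#' @export
predict.sic_fit <- function(object, newdata = NULL,
                            type = c("mean", "moments", "prediction"),
                            level = 0.95, ...) {
  type <- match.arg(type)
  X <- newdata_design(object, newdata)
  cm <- conditional_moments(X, object$params_sparse)
  switch(type,
         mean = cm$mean,
         moments = data.frame(mean = cm$mean, variance = cm$variance),
         prediction = {
           pi <- prediction_interval(X, object$params_sparse, level = level)
           data.frame(fit = pi$center, lwr = pi$lower, upr = pi$upper,
                      sd = sqrt(cm$variance))
         })
}

#' @export
fitted.sic_fit <- function(object, ...) predict(object, type = "mean")

#' Residuals of a smooth-IC fit
#'
#' @param object a fitted `"sic_fit"`.
#' @param type `"response"` (y - fitted mean) or `"pearson"` (scaled by the
#'   fitted per-observation SD).
#' @param ... unused.
#' @export
residuals.sic_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  cm <- conditional_moments(object$data$X, object$params_sparse)
  r <- object$data$y - cm$mean
  if (type == "pearson") r <- r / sqrt(cm$variance)
  r
}

#' @export
simulate.sic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cm <- conditional_moments(object$data$X, object$params_sparse)
  n <- length(cm$mean)
  out <- as.data.frame(
    replicate(nsim, stats::rnorm(n, cm$mean, sqrt(cm$variance)),
              simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot telescope coefficient paths
#'
#' Shows each coefficient's trajectory as the smoothing parameter epsilon
#' decreases (log10 scale), one panel per model component. Paths collapsing
#' to zero correspond to de-selected effects.
#'
#' @param x a fitted `"sic_fit"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sic_fit <- function(x, ...) {
  tr <- x$trace
  le <- log10(tr[, "eps"])
  kb <- length(x$params_hat$beta)
  bcols <- 3L + seq_len(kb)
  acols <- setdiff(seq_len(ncol(tr)), c(1:3, bcols))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(le, tr[, bcols, drop = FALSE], type = "l", lty = 1,
                    xlab = expression(log[10](epsilon)), ylab = "coefficient",
                    main = "location (beta)", ...)
  graphics::abline(h = 0, col = "grey")
  if (length(acols)) {
    graphics::matplot(le, tr[, acols, drop = FALSE], type = "l", lty = 1,
                      xlab = expression(log[10](epsilon)),
                      ylab = "coefficient", main = "dispersion (alpha)", ...)
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}
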