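#' Benchmark simulation design (12 covariates, mixed distributions)
#'
#' The reference design used throughout the package's Monte Carlo studies:
#' p = 12 covariates with a realistic mix of marginals — two skewed
#' (X1, X11 ~ Exponential(1)), two unbalanced binary (X3, X10 ~
#' Bernoulli(0.75)), four independent standard normal (X4, X5, X7, X8) and a
#' four-variable correlated Gaussian block ((X2, X6, X9, X12) = (Z1..Z4),
#' corr(Zj, Zk) = 0.8^|j-k|). True coefficients take values 0 / 0.5 / 1
#' (none / weak / strong effects):
#' beta = (0, 1, 0.5, 0.5, 1, 0.5, 1, 0, 0, 0, 0, 0, 0) and
#' alpha = (0, 0.5, 1, 0.5, 1, 0, 0, 0.5, 1, 0, 0, 0, 0), so X1-X4 act on
#' both components, X5-X6 on the location only, X7-X8 on the dispersion only
#' and X9-X12 are pure noise.
#'
#' @param n sample size per replicate.
#' @param seed master seed; replicate seeds are derived from it.
#' @return An object of class `"sim_design"`.
#' @export
table2_design <- function(n = 1000, seed = 1L) {
  structure(
    list(n = as.integer(n),
         beta = c(0, 1, 0.5, 0.5, 1, 0.5, 1, 0, 0, 0, 0, 0, 0),
         alpha = c(0, 0.5, 1, 0.5, 1, 0, 0, 0.5, 1, 0, 0, 0, 0),
         seed = as.integer(seed)),
    class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("simulation design: n = %d, 12 mixed covariates, seed = %d\n",
              x$n, x$seed))
  cat("beta :", x$beta, "\nalpha:", x$alpha, "\n")
  invisible(x)
}

# draw the 12-covariate block using the current RNG state
gen_cov_raw <- function(n) {
  S <- 0.8^abs(outer(1:4, 1:4, "-"))
  Z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% chol(S)
  X <- matrix(0, n, 12L)
  X[, 1L] <- stats::rexp(n, rate = 1)
  X[, c(2L, 6L, 9L, 12L)] <- Z
  X[, 3L] <- stats::rbinom(n, 1L, 0.75)
  X[, 4L] <- stats::rnorm(n)
  X[, 5L] <- stats::rnorm(n)
  X[, 7L] <- stats::rnorm(n)
  X[, 8L] <- stats::rnorm(n)
  X[, 10L] <- stats::rbinom(n, 1L, 0.75)
  X[, 11L] <- stats::rexp(n, rate = 1)
  colnames(X) <- paste0("x", 1:12)
  X
}

gen_resp_raw <- function(Xi, beta, alpha) {
  mu <- drop(Xi %*% beta)
  sd <- exp(drop(Xi %*% alpha) / 2)
  stats::rnorm(nrow(Xi), mu, sd)
}

#' Generate the covariate block of the benchmark design
#'
#' @param design a [table2_design()] object; its `seed` fixes the draw.
#' @return An n x 12 matrix of unscaled covariates.
#' @export
gen_covariates <- function(design) {
  set.seed(design$seed)
  gen_cov_raw(design$n)
}

#' Generate responses from the location-scale normal model
#'
#' Draws \eqn{y_i = x_i^T\beta + \sigma_i z_i} with
#' \eqn{\sigma_i = \exp(x_i^T\alpha / 2)} and iid standard normal \eqn{z_i}.
#'
#' @param X_with_intercept n x (p+1) design, intercept first.
#' @param beta_true,alpha_true true coefficient vectors, length p+1.
#' @param seed integer seed for the draw.
#' @return Numeric response vector of length n.
#' @export
gen_response <- function(X_with_intercept, beta_true, alpha_true, seed) {
  set.seed(seed)
  gen_resp_raw(as.matrix(X_with_intercept), beta_true, alpha_true)
}

# deterministic, independent-ish child seeds below 2^31
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 104729) %% 2147483629)
}

#' Monte Carlo study of selection, inference and prediction performance
#'
#' Replicates the full pipeline: generate training data from `design`, scale
#' predictors to unit sample SD, fit the chosen method, and score it against
#' the truth. Reported metrics:
#' \itemize{
#'   \item C / IC: average number of truly-zero coefficients correctly set to
#'     zero and of truly-non-zero coefficients incorrectly zeroed, per
#'     component;
#'   \item PT: proportion of replicates recovering the exact true support,
#'     per component;
#'   \item MSE: average of \eqn{(\hat\theta-\theta)^T X^TX (\hat\theta-\theta)/n}
#'     per component;
#'   \item per-coefficient mean estimate, empirical SE (SD over replicates),
#'     mean estimated (sandwich) SE (SEE), and empirical coverage (CP) of
#'     nominal 95 percent Wald intervals — an estimate thresholded to zero
#'     counts as covering iff the truth is zero;
#'   \item PCP: out-of-sample prediction-interval coverage on a fresh holdout
#'     of size `ceiling(holdout_fraction * n)`, overall and stratified by the
#'     true SDs with cutpoints (1, 2.2).
#' }
#' Estimates are compared to the truth on the generated covariate scale
#' (fitting happens on the scaled scale; estimates and SEs are transformed
#' back with the training scale factors).
#'
#' @param design a [table2_design()].
#' @param n_replicates number of Monte Carlo replicates.
#' @param method `"mpr"`, `"spr"`, or `"oracle"` (estimates fixed at the
#'   truth; a bookkeeping check).
#' @param holdout_fraction holdout size as a fraction of n (default 0.2).
#' @param schedule telescope settings, see [make_schedule()].
#' @param penalty_weight NULL for log(n) (BIC-type), or a number.
#' @param zero_tol zeroing threshold.
#' @param verbose print a progress line every 25 replicates.
#' @return An object of class `"sic_study"`.
#' @export
run_study <- function(design, n_replicates = 200,
                      method = c("mpr", "spr", "oracle"),
                      holdout_fraction = 0.2, schedule = make_schedule(),
                      penalty_weight = NULL, zero_tol = 1e-8,
                      verbose = FALSE) {
  method <- match.arg(method)
  n <- design$n
  beta_t <- design$beta
  alpha_t <- design$alpha
  k <- length(beta_t)
  lambda <- if (is.null(penalty_weight)) log(n) else penalty_weight
  m <- as.integer(ceiling(holdout_fraction * n))
  R <- n_replicates
  if (R < 1) stop("'n_replicates' must be >= 1", call. = FALSE)

  est_b <- se_b <- cov_b <- matrix(NA_real_, R, k)
  est_a <- se_a <- cov_a <- matrix(NA_real_, R, k)
  Cm <- ICm <- PTm <- MSEm <- matrix(NA_real_, R, 2L,
                                     dimnames = list(NULL, c("beta", "alpha")))
  pcp_rep <- matrix(NA_real_, R, 4L,
                    dimnames = list(NULL, c("overall", "low", "medium",
                                            "high")))
  seeds <- vapply(seq_len(R), function(i) child_seed(design$seed, i),
                  integer(1))
  failed <- integer(0)

  for (rep in seq_len(R)) {
    res <- tryCatch({
      set.seed(seeds[rep])
      Xr <- gen_cov_raw(n)
      X1r <- cbind(1, Xr)
      y <- gen_resp_raw(X1r, beta_t, alpha_t)
      Xh <- gen_cov_raw(m)
      X1h <- cbind(1, Xh)
      sig_h <- exp(drop(X1h %*% alpha_t) / 2)
      yh <- gen_resp_raw(X1h, beta_t, alpha_t)

      s <- apply(Xr, 2L, stats::sd)
      sc <- c(1, s)  # coefficient scale map: theta_scaled = theta_gen * sc
      Xs <- sweep(Xr, 2L, s, "/")
      dat <- structure(
        list(y = y, X = cbind("(intercept)" = 1, Xs), scale_factors = s,
             centers = rep(0, k - 1L),
             var_names = colnames(Xr)),
        class = "mpr_data")

      if (method == "oracle") {
        bs <- beta_t * sc; as_ <- alpha_t * sc
        fit <- list(params_hat = mpr_params(bs, as_),
                    params_sparse = mpr_params(bs, as_),
                    active_beta = which(c(TRUE, beta_t[-1L] != 0)),
                    active_alpha = which(c(TRUE, alpha_t[-1L] != 0)),
                    cov_hat = matrix(0, 2L * k, 2L * k))
      } else if (method == "mpr") {
        fit <- fit_mpr_sic(dat, schedule, penalty_weight = lambda,
                           zero_tol = zero_tol)
      } else {
        fit <- fit_spr_sic(dat, schedule, penalty_weight = lambda,
                           zero_tol = zero_tol)
      }

      se_s <- sqrt(pmax(diag(fit$cov_hat), 0))
      list(
        b_gen = fit$params_sparse$beta / sc,
        a_gen = fit$params_sparse$alpha / sc,
        braw_s = fit$params_hat$beta, araw_s = fit$params_hat$alpha,
        bsp_s = fit$params_sparse$beta, asp_s = fit$params_sparse$alpha,
        seb_s = se_s[seq_len(k)], sea_s = se_s[k + seq_len(k)],
        sc = sc, X1r = X1r, X1h = X1h, Xs = Xs, sig_h = sig_h, yh = yh,
        active_b = fit$active_beta, active_a = fit$active_alpha)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      failed <- c(failed, rep)
      next
    }

    est_b[rep, ] <- res$b_gen
    est_a[rep, ] <- res$a_gen
    se_b[rep, ] <- res$seb_s / res$sc
    se_a[rep, ] <- res$sea_s / res$sc

    truth_bs <- beta_t * res$sc
    truth_as <- alpha_t * res$sc
    cov_b[rep, ] <- coef_covers(res$bsp_s, res$braw_s, res$seb_s, truth_bs)
    cov_a[rep, ] <- coef_covers(res$asp_s, res$araw_s, res$sea_s, truth_as)

    sel_b <- res$bsp_s[-1L] != 0
    sel_a <- res$asp_s[-1L] != 0
    tru_b <- beta_t[-1L] != 0
    tru_a <- alpha_t[-1L] != 0
    Cm[rep, ] <- c(sum(!sel_b & !tru_b), sum(!sel_a & !tru_a))
    ICm[rep, ] <- c(sum(!sel_b & tru_b), sum(!sel_a & tru_a))
    PTm[rep, ] <- c(all(sel_b == tru_b), all(sel_a == tru_a))

    XtX <- crossprod(res$X1r)
    db <- res$b_gen - beta_t
    da <- res$a_gen - alpha_t
    MSEm[rep, ] <- c(drop(db %*% XtX %*% db), drop(da %*% XtX %*% da)) / n

    mu_h <- drop(res$X1h %*% res$b_gen)
    sd_h <- exp(pmin(pmax(drop(res$X1h %*% res$a_gen), -LP_CLAMP),
                     LP_CLAMP) / 2)
    pint <- data.frame(lower = mu_h - 1.96 * sd_h, upper = mu_h + 1.96 * sd_h)
    pc <- pcp(pint, res$yh, sigma_true = res$sig_h)
    pcp_rep[rep, ] <- c(pc$overall, pc$by_level)

    if (verbose && rep %% 25 == 0)
      message(sprintf("replicate %d / %d", rep, R))
  }

  if (length(failed) > 0.05 * R)
    stop(sprintf("too many replicate failures (%d of %d)", length(failed), R),
         call. = FALSE)
  ok <- setdiff(seq_len(R), failed)

  coef_tab <- rbind(
    data.frame(component = "beta", index = 0:(k - 1L), truth = beta_t,
               est_mean = colMeans(est_b[ok, , drop = FALSE]),
               SE = apply(est_b[ok, , drop = FALSE], 2L, stats::sd),
               SEE = colMeans(se_b[ok, , drop = FALSE]),
               CP = colMeans(cov_b[ok, , drop = FALSE])),
    data.frame(component = "alpha", index = 0:(k - 1L), truth = alpha_t,
               est_mean = colMeans(est_a[ok, , drop = FALSE]),
               SE = apply(est_a[ok, , drop = FALSE], 2L, stats::sd),
               SEE = colMeans(se_a[ok, , drop = FALSE]),
               CP = colMeans(cov_a[ok, , drop = FALSE])))
  structure(
    list(method = method, design = design,
         n_replicates = length(ok), n_failed = length(failed),
         C = colMeans(Cm[ok, , drop = FALSE]),
         IC = colMeans(ICm[ok, , drop = FALSE]),
         PT = colMeans(PTm[ok, , drop = FALSE]),
         MSE = colMeans(MSEm[ok, , drop = FALSE]),
         coef = coef_tab,
         pcp = colMeans(pcp_rep[ok, , drop = FALSE], na.rm = TRUE),
         estimates = list(beta = est_b[ok, , drop = FALSE],
                          alpha = est_a[ok, , drop = FALSE]),
         seeds = seeds),
    class = "sic_study")
}

# CP convention: if the final (thresholded) estimate is zero the interval is
# the point {0}, covering iff the truth is zero; otherwise a Wald interval at
# the raw estimate with z = 1.96.
coef_covers <- function(sparse, raw, se, truth) {
  ifelse(sparse == 0, truth == 0, abs(raw - truth) <= 1.96 * se)
}

#' @export
print.sic_study <- function(x, digits = 3, ...) {
  cat(sprintf("Monte Carlo study: method = %s, n = %d, %d replicates",
              toupper(x$method), x$design$n, x$n_replicates))
  if (x$n_failed > 0) cat(sprintf(" (%d failed)", x$n_failed))
  cat("\n\nSelection metrics (per component):\n")
  print(round(rbind(C = x$C, IC = x$IC, PT = x$PT, MSE = x$MSE), digits))
  cat("\nPrediction coverage (nominal 0.95):\n")
  print(round(x$pcp, digits))
  cat("\nCoefficient metrics (non-null truths):\n")
  print(x$coef[x$coef$truth != 0 | x$coef$index == 0, ], digits = digits,
        row.names = FALSE)
  invisible(x)
}

# tidy CSV + JSON manifest, used by the command-line interface
write_study <- function(study, out_prefix) {
  long <- rbind(
    data.frame(metric = "C", component = names(study$C), coefficient = NA,
               value = unname(study$C)),
    data.frame(metric = "IC", component = names(study$IC), coefficient = NA,
               value = unname(study$IC)),
    data.frame(metric = "PT", component = names(study$PT), coefficient = NA,
               value = unname(study$PT)),
    data.frame(metric = "MSE", component = names(study$MSE), coefficient = NA,
               value = unname(study$MSE)),
    data.frame(metric = "PCP", component = names(study$pcp), coefficient = NA,
               value = unname(study$pcp)))
  for (mcol in c("est_mean", "SE", "SEE", "CP"))
    long <- rbind(long, data.frame(
      metric = mcol, component = study$coef$component,
      coefficient = study$coef$index, value = study$coef[[mcol]]))
  utils::write.csv(long, paste0(out_prefix, "_metrics.csv"),
                   row.names = FALSE)
  manifest <- list(
    method = study$method,
    design = list(n = study$design$n, beta = study$design$beta,
                  alpha = study$design$alpha, seed = study$design$seed,
                  truth_scale = "generated covariates; estimates mapped back from the unit-SD fitting scale"),
    n_replicates = study$n_replicates, n_failed = study$n_failed,
    package_version = as.character(utils::packageVersion("sicreg")))
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(long)
}
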