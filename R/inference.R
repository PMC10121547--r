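#' Conditional mean and variance surfaces
#'
#' For covariate vector(s) x (including the leading intercept 1), returns the
#' model's mean-variance pair \eqn{(\mu(x), \sigma^2(x))} with
#' \eqn{\mu(x) = x^T\beta} and \eqn{\sigma^2(x) = e^{x^T\alpha}}.
#'
#' @param x numeric vector of length p+1, or an n x (p+1) matrix of rows.
#' @param params an [mpr_params()], a list with `beta`/`alpha`, or a fitted
#'   `"sic_fit"` (raw estimates are used).
#' @return List with numeric `mean` and `variance` (vectors if `x` is a
#'   matrix).
#' @export
conditional_moments <- function(x, params) {
  p <- params_of(params)
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != length(p$beta))
    stop("dimension mismatch between 'x' and the coefficients",
         call. = FALSE)
  etaa <- pmin(pmax(drop(X %*% p$alpha), -LP_CLAMP), LP_CLAMP)
  list(mean = drop(X %*% p$beta), variance = exp(etaa))
}

# z = 1.96 exactly at 95% (conventional rounding); exact normal quantile
# otherwise
z_quantile <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm((1 + level) / 2)
}

#' Gaussian prediction intervals
#'
#' Builds the nominal `level` prediction interval
#' \eqn{x^T\hat\beta \pm z \sqrt{e^{x^T\hat\alpha}}} for each covariate row;
#' at the default 95% level, z = 1.96 exactly.
#'
#' @inheritParams conditional_moments
#' @param level coverage level in (0, 1).
#' @return Data frame with columns `center`, `half_width`, `lower`, `upper`;
#'   attribute `"level"`.
#' @export
prediction_interval <- function(x, params, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  cm <- conditional_moments(x, params)
  hw <- z_quantile(level) * sqrt(cm$variance)
  structure(
    data.frame(center = cm$mean, half_width = hw,
               lower = cm$mean - hw, upper = cm$mean + hw),
    level = level)
}

#' Wald confidence intervals for the active coefficients
#'
#' Point estimates with sandwich standard errors and `estimate +/- z * SE`
#' intervals, reported for the active (selected) coefficients only, the
#' intercepts included.
#'
#' @param result a fitted `"sic_fit"`.
#' @param level confidence level (z = 1.96 exactly at 0.95).
#' @return Data frame with columns `component`, `term`, `index` (predictor
#'   index, 0 = intercept), `estimate`, `se`, `lower`, `upper`.
#' @export
wald_cis <- function(result, level = 0.95) {
  z <- z_quantile(level)
  nm <- coef_names(result)
  se_all <- sqrt(pmax(diag(result$cov_hat), 0))
  k <- length(result$params_hat$beta)
  rows <- function(active, est, se, comp)
    data.frame(component = comp, term = nm[active], index = active - 1L,
               estimate = est[active], se = se[active],
               lower = est[active] - z * se[active],
               upper = est[active] + z * se[active])
  rbind(
    rows(result$active_beta, result$params_hat$beta, se_all[seq_len(k)],
         "location"),
    rows(result$active_alpha, result$params_hat$alpha, se_all[k + seq_len(k)],
         "dispersion"))
}

#' @export
confint.sic_fit <- function(object, parm, level = 0.95, ...) {
  tab <- wald_cis(object, level = level)
  ci <- as.matrix(tab[, c("lower", "upper")])
  rownames(ci) <- paste0(ifelse(tab$component == "location", "b.", "a."),
                         tab$term)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2)),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Prediction coverage probability
#'
#' Fraction of new responses falling inside their nominal prediction
#' intervals, overall and (when the true per-observation SDs are supplied)
#' within low / medium / high variability strata defined by `thresholds`:
#' low \eqn{\sigma_i \le t_1}, medium \eqn{t_1 < \sigma_i \le t_2}, high
#' \eqn{\sigma_i > t_2}. The defaults (1, 2.2) are the tertiles of the true
#' SD distribution in the bundled simulation design.
#'
#' @param intervals output of [prediction_interval()] (or any data frame with
#'   `lower` and `upper` columns).
#' @param y_new numeric vector of new responses, same length.
#' @param sigma_true optional true per-observation SDs for stratification.
#' @param thresholds length-2 increasing numeric cutpoints.
#' @return List with `overall`, `by_level` (named vector low/medium/high,
#'   `NA` for empty strata) and `n` (stratum counts). Without `sigma_true`
#'   only `overall` is returned.
#' @export
pcp <- function(intervals, y_new, sigma_true = NULL, thresholds = c(1, 2.2)) {
  if (nrow(intervals) != length(y_new))
    stop("'intervals' and 'y_new' must have equal length", call. = FALSE)
  inside <- y_new >= intervals$lower & y_new <= intervals$upper
  out <- list(overall = mean(inside))
  if (!is.null(sigma_true)) {
    if (length(sigma_true) != length(y_new))
      stop("'sigma_true' must match 'y_new' in length", call. = FALSE)
    if (length(thresholds) != 2L || diff(thresholds) <= 0)
      stop("'thresholds' must be two increasing values", call. = FALSE)
    lev <- cut(sigma_true, c(-Inf, thresholds, Inf),
               labels = c("low", "medium", "high"))
    by_level <- vapply(levels(lev), function(l) {
      idx <- lev == l
      if (!any(idx)) NA_real_ else mean(inside[idx])
    }, numeric(1))
    out$by_level <- by_level
    out$n <- table(lev)
  }
  out
}
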