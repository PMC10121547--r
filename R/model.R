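#' Coefficient pair for the location-scale normal model
#'
#' The model has two linear predictors: the mean \eqn{\mu_i = x_i^T\beta} and
#' the log-variance \eqn{\log \sigma^2_i = x_i^T\alpha}. `mpr_params()`
#' bundles the two coefficient vectors (each of length p+1, intercept first).
#'
#' @param beta numeric vector of location coefficients.
#' @param alpha numeric vector of log-dispersion coefficients, same length.
#' @return An object of class `"mpr_params"`, a list with `beta` and `alpha`.
#' @export
mpr_params <- function(beta, alpha) {
  beta <- as.numeric(beta)
  alpha <- as.numeric(alpha)
  if (length(beta) != length(alpha) || length(beta) < 1L)
    stop("'beta' and 'alpha' must have identical length >= 1", call. = FALSE)
  structure(list(beta = beta, alpha = alpha), class = "mpr_params")
}

# linear-predictor clamp for the log-variance; exp(+-30) brackets any variance
# representable at double precision in realistic data
LP_CLAMP <- 30

# Shared pieces of the likelihood at (beta, alpha): clamped log-variance
# linear predictor etaa, precision weights w = exp(-etaa), raw residuals, and
# the number of clamped observations.
mpr_core <- function(y, Xb, Xa, beta, alpha) {
  etab <- drop(Xb %*% beta)
  etaa <- drop(Xa %*% alpha)
  clips <- sum(etaa < -LP_CLAMP | etaa > LP_CLAMP)
  if (clips > 0) etaa <- pmin(pmax(etaa, -LP_CLAMP), LP_CLAMP)
  w <- exp(-etaa)
  list(etaa = etaa, w = w, res = y - etab, clips = clips)
}

ll_value <- function(core, n) {
  -0.5 * n * log(2 * pi) - 0.5 * sum(core$etaa) -
    0.5 * sum(core$w * core$res^2)
}

# penalty term (lambda/2) * [sum phi(beta_pen) + sum phi(alpha_pen) + 2];
# pb/pa are logical masks marking the penalized coefficients (never the
# intercepts)
pen_value <- function(beta, alpha, eps, lambda, pb, pa) {
  (lambda / 2) * (sum(smooth_l0(beta[pb], eps)) +
                    sum(smooth_l0(alpha[pa], eps)) + 2)
}

obj_value <- function(y, Xb, Xa, beta, alpha, eps, lambda, pb, pa) {
  core <- mpr_core(y, Xb, Xa, beta, alpha)
  ll_value(core, length(y)) - pen_value(beta, alpha, eps, lambda, pb, pa)
}

# penalized score: (X_b' z_beta - (lambda/2) nu_beta, X_a' z_alpha -
# (lambda/2) nu_alpha)
score_blocks <- function(y, Xb, Xa, beta, alpha, eps, lambda, pb, pa,
                         core = mpr_core(y, Xb, Xa, beta, alpha)) {
  zb <- core$w * core$res
  za <- (core$w * core$res^2 - 1) / 2
  nub <- numeric(length(beta))
  nua <- numeric(length(alpha))
  nub[pb] <- smooth_l0_grad(beta[pb], eps)
  nua[pa] <- smooth_l0_grad(alpha[pa], eps)
  list(g_beta  = drop(crossprod(Xb, zb)) - (lambda / 2) * nub,
       g_alpha = drop(crossprod(Xa, za)) - (lambda / 2) * nua,
       z_beta = zb, z_alpha = za, nu_beta = nub, nu_alpha = nua)
}

# diagonal information blocks of the RS Newton system (cross-block dropped),
# returned with their penalty-free parts so safeguards can rebuild them
info_blocks <- function(y, Xb, Xa, beta, alpha, eps, lambda, pb, pa,
                        core = mpr_core(y, Xb, Xa, beta, alpha)) {
  Wb <- core$w
  Wa <- core$w * core$res^2 / 2
  Sb <- numeric(length(beta))
  Sa <- numeric(length(alpha))
  Sb[pb] <- smooth_l0_hess(beta[pb], eps)
  Sa[pa] <- smooth_l0_hess(alpha[pa], eps)
  list(XtWbX = crossprod(Xb * Wb, Xb), XtWaX = crossprod(Xa * Wa, Xa),
       Sigma_beta = Sb, Sigma_alpha = Sa, W_beta = Wb, W_alpha = Wa,
       W_alphabeta = core$w * core$res)
}

params_of <- function(params) {
  if (inherits(params, "sic_fit"))
    return(list(beta = params$params_hat$beta, alpha = params$params_hat$alpha))
  if (!is.list(params) || is.null(params$beta) || is.null(params$alpha))
    stop("'params' must be an mpr_params-like list with beta and alpha",
         call. = FALSE)
  list(beta = as.numeric(params$beta), alpha = as.numeric(params$alpha))
}

data_of <- function(data) {
  if (!is.list(data) || is.null(data$y) || is.null(data$X))
    stop("'data' must be an mpr_data-like list with y and X", call. = FALSE)
  X <- as.matrix(data$X)
  if (any(X[, 1L] != 1))
    stop("first column of the design must be an intercept of ones",
         call. = FALSE)
  list(y = as.numeric(data$y), X = X)
}

pen_mask <- function(k) c(FALSE, rep(TRUE, k - 1L))

#' Log-likelihood of the location-scale normal model
#'
#' Evaluates
#' \deqn{\ell(\theta) = -\frac n2 \log(2\pi) - \frac12 \sum_i x_i^T\alpha
#'   - \frac12 \sum_i e^{-x_i^T\alpha} (y_i - x_i^T\beta)^2,}
#' the sum of normal log-densities with mean \eqn{x_i^T\beta} and variance
#' \eqn{e^{x_i^T\alpha}}. The log-variance linear predictor is clamped to
#' [-30, 30] before exponentiation; the number of clamped observations is
#' attached as attribute `"n_clips"`.
#'
#' @param params an [mpr_params()] (or any list with `beta`, `alpha`).
#' @param data an [mpr_data()] (or any list with `y` and design `X` whose
#'   first column is the intercept).
#' @return The log-likelihood (scalar) with attribute `n_clips`.
#' @export
mpr_loglik <- function(params, data) {
  p <- params_of(params); d <- data_of(data)
  stopifnot(length(p$beta) == ncol(d$X))
  core <- mpr_core(d$y, d$X, d$X, p$beta, p$alpha)
  ll <- ll_value(core, length(d$y))
  if (!is.finite(ll)) stop("non-finite log-likelihood", call. = FALSE)
  structure(ll, n_clips = core$clips)
}

#' Smooth information criterion objective
#'
#' The penalized log-likelihood that the estimator maximizes,
#' \deqn{\ell^{SIC}(\theta) = \ell(\theta) - \frac\lambda2\left[
#'   \sum_{j\ge1}\phi_\epsilon(\beta_j) + \sum_{j\ge1}\phi_\epsilon(\alpha_j)
#'   + 2\right],}
#' where \eqn{\lambda} is `penalty_weight` (log(n) for a BIC-type criterion,
#' 2 for AIC-type) and the intercepts are unpenalized; the constant "+2"
#' accounts for the always-estimated intercepts so reported values are on the
#' usual information-criterion scale.
#'
#' @inheritParams mpr_loglik
#' @param eps positive smoothing parameter.
#' @param penalty_weight penalty multiplier \eqn{\lambda}; default `log(n)`.
#' @return Scalar objective value (larger is better).
#' @export
sic_objective <- function(params, data, eps,
                          penalty_weight = log(length(data$y))) {
  p <- params_of(params); d <- data_of(data)
  check_eps(eps)
  k <- ncol(d$X)
  obj_value(d$y, d$X, d$X, p$beta, p$alpha, eps, penalty_weight,
            pen_mask(k), pen_mask(k))
}

#' Gradient of the smooth-IC objective
#'
#' Returns the two blocks of \eqn{\partial \ell^{SIC}/\partial\theta}:
#' \eqn{X^T z_\beta - (\lambda/2)\nu_\beta} and
#' \eqn{X^T z_\alpha - (\lambda/2)\nu_\alpha}, where
#' \eqn{z_{\beta,i} = e^{-x_i^T\alpha}(y_i - x_i^T\beta)},
#' \eqn{z_{\alpha,i} = (e^{-x_i^T\alpha}(y_i - x_i^T\beta)^2 - 1)/2} and the
#' \eqn{\nu} vectors hold \eqn{\phi'_\epsilon} of the penalized coefficients
#' (0 in the intercept position).
#'
#' @inheritParams sic_objective
#' @return List with `g_beta` and `g_alpha`, each of length p+1.
#' @export
penalized_score <- function(params, data, eps,
                            penalty_weight = log(length(data$y))) {
  p <- params_of(params); d <- data_of(data)
  check_eps(eps)
  k <- ncol(d$X)
  s <- score_blocks(d$y, d$X, d$X, p$beta, p$alpha, eps, penalty_weight,
                    pen_mask(k), pen_mask(k))
  s[c("g_beta", "g_alpha")]
}

#' Diagonal information blocks of the RS Newton system
#'
#' Returns the two penalized curvature blocks
#' \eqn{X^T W_\beta X + (\lambda/2)\Sigma_\beta} and
#' \eqn{X^T W_\alpha X + (\lambda/2)\Sigma_\alpha} used by the block
#' Newton-Raphson update, in which the cross-derivative block between the
#' location and dispersion parameters is set to zero (the "RS" scheme).
#' \eqn{W_\beta = \mathrm{diag}(e^{-x_i^T\alpha})},
#' \eqn{W_\alpha = \mathrm{diag}(e^{-x_i^T\alpha}(y_i - x_i^T\beta)^2/2)} and
#' the \eqn{\Sigma} diagonals hold \eqn{\phi''_\epsilon} of the penalized
#' coefficients (0 for intercepts).
#'
#' @inheritParams sic_objective
#' @return List with matrices `A_beta` and `A_alpha`, each (p+1) x (p+1).
#' @export
penalized_information <- function(params, data, eps,
                                  penalty_weight = log(length(data$y))) {
  p <- params_of(params); d <- data_of(data)
  check_eps(eps)
  k <- ncol(d$X)
  b <- info_blocks(d$y, d$X, d$X, p$beta, p$alpha, eps, penalty_weight,
                   pen_mask(k), pen_mask(k))
  list(A_beta  = b$XtWbX + (penalty_weight / 2) * diag(b$Sigma_beta, k),
       A_alpha = b$XtWaX + (penalty_weight / 2) * diag(b$Sigma_alpha, k))
}

#' Full penalized and unpenalized information matrices
#'
#' The (2p+2) x (2p+2) matrix of negative second derivatives of the smooth-IC
#' objective, including the cross block \eqn{X^T W_{\alpha\beta} X} with
#' \eqn{W_{\alpha\beta} = \mathrm{diag}(e^{-x_i^T\alpha}(y_i - x_i^T\beta))},
#' together with its penalty-free counterpart \eqn{I_0(\theta)} (the observed
#' information of the plain likelihood). Both are needed for the sandwich
#' covariance \eqn{I^{-1} I_0 I^{-1}}; see [sandwich_cov()].
#'
#' @inheritParams sic_objective
#' @return List with `I` (penalized) and `I0` (unpenalized) matrices, ordered
#'   (beta, alpha).
#' @export
full_information <- function(params, data, eps,
                             penalty_weight = log(length(data$y))) {
  p <- params_of(params); d <- data_of(data)
  check_eps(eps)
  k <- ncol(d$X)
  full_information_xx(d$y, d$X, d$X, p$beta, p$alpha, eps, penalty_weight,
                      pen_mask(k), pen_mask(k))
}

full_information_xx <- function(y, Xb, Xa, beta, alpha, eps, lambda, pb, pa) {
  b <- info_blocks(y, Xb, Xa, beta, alpha, eps, lambda, pb, pa)
  C <- crossprod(Xb * b$W_alphabeta, Xa)
  I0 <- rbind(cbind(b$XtWbX, C), cbind(t(C), b$XtWaX))
  pen <- c((lambda / 2) * b$Sigma_beta, (lambda / 2) * b$Sigma_alpha)
  list(I = I0 + diag(pen, nrow(I0)), I0 = I0)
}
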