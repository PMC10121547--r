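#' Smooth L0 norm approximation
#'
#' The cardinality ("L0") penalty used by information criteria such as the BIC
#' is non-differentiable at zero. `smooth_l0()` evaluates the differentiable
#' surrogate
#' \deqn{\phi_\epsilon(x) = \frac{x^2}{x^2 + \epsilon^2},}
#' which lies in \eqn{[0, 1)}, is even in `x`, and converges pointwise to the
#' 0/1 indicator of \eqn{x \neq 0} as \eqn{\epsilon \downarrow 0}.
#' `smooth_l0_grad()` and `smooth_l0_hess()` give its first two derivatives in
#' `x`, used by the Newton-Raphson fitting routines:
#' \deqn{\phi'_\epsilon(x) = \frac{2 x \epsilon^2}{(x^2+\epsilon^2)^2}, \qquad
#'       \phi''_\epsilon(x) = \frac{2\epsilon^2(\epsilon^2 - 3x^2)}
#'                                  {(x^2+\epsilon^2)^3}.}
#'
#' Note that \eqn{\phi''_\epsilon} is negative for \eqn{|x| > \epsilon/\sqrt 3},
#' so penalized Newton blocks can be indefinite; the estimator guards against
#' this (see [fit_mpr_sic()]).
#'
#' @param x numeric vector of coefficient values.
#' @param eps positive scalar smoothing parameter \eqn{\epsilon}.
#' @return Numeric vector the length of `x`.
#' @seealso [make_schedule()] for the decreasing sequence of `eps` values used
#'   during fitting.
#' @examples
#' smooth_l0(c(0, 1, 2), eps = 1)     # 0, 0.5, 0.8
#' smooth_l0_grad(1, 1)               # 0.5
#' smooth_l0_hess(0, 2)               # 2/eps^2 = 0.5
#' @export
smooth_l0 <- function(x, eps) {
  check_eps(eps)
  x2 <- x * x
  x2 / (x2 + eps * eps)
}

#' @rdname smooth_l0
#' @export
smooth_l0_grad <- function(x, eps) {
  check_eps(eps)
  d <- x * x + eps * eps
  2 * x * eps * eps / (d * d)
}

#' @rdname smooth_l0
#' @export
smooth_l0_hess <- function(x, eps) {
  check_eps(eps)
  e2 <- eps * eps
  d <- x * x + e2
  2 * e2 * (e2 - 3 * x * x) / (d * d * d)
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a single positive number", call. = FALSE)
  invisible(eps)
}

#' Geometric epsilon-telescope schedule
#'
#' Builds the decreasing sequence of smoothing values
#' \eqn{\epsilon_t = \epsilon_1 r^{t-1}}, \eqn{t = 1, \dots, T}, through which
#' the smooth-IC objective is "telescoped": each optimization problem is
#' warm-started from the solution of the previous, slightly smoother one.  The
#' decay rate is determined by the endpoints,
#' \eqn{r = (\epsilon_T/\epsilon_1)^{1/(T-1)}}.  The defaults (10 down to
#' 1e-5 in 100 steps, giving r = 0.87) squeeze truly null coefficients to
#' magnitudes around 1e-9 while leaving genuine effects essentially untouched.
#'
#' @param eps_start first (largest) epsilon value \eqn{\epsilon_1}.
#' @param eps_end last (smallest) epsilon value \eqn{\epsilon_T}.
#' @param n_steps number of telescope steps \eqn{T \ge 1}.
#' @return An object of class `"eps_telescope"`: a list with elements
#'   `eps_start`, `eps_end`, `n_steps`, `decay_rate` and `values` (the full
#'   sequence, length `n_steps`).
#' @examples
#' sch <- make_schedule(10, 1e-5, 100)
#' round(sch$decay_rate, 2)  # 0.87
#' @export
make_schedule <- function(eps_start = 10, eps_end = 1e-5, n_steps = 100L) {
  check_eps(eps_start)
  check_eps(eps_end)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps))
    stop("'n_steps' must be a single integer >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (eps_end > eps_start)
    stop("'eps_end' must not exceed 'eps_start'", call. = FALSE)
  if (n_steps == 1L) {
    if (abs(eps_start - eps_end) > 1e-12 * eps_start)
      stop("with 'n_steps' = 1, 'eps_start' and 'eps_end' must be equal",
           call. = FALSE)
    r <- 1
  } else {
    r <- (eps_end / eps_start)^(1 / (n_steps - 1))
  }
  structure(
    list(eps_start = eps_start, eps_end = eps_end, n_steps = n_steps,
         decay_rate = r, values = eps_start * r^(seq_len(n_steps) - 1)),
    class = "eps_telescope")
}

#' @export
print.eps_telescope <- function(x, ...) {
  cat(sprintf(
    "epsilon telescope: %d steps from %g to %g (decay rate r = %.4f)\n",
    x$n_steps, x$eps_start, x$eps_end, x$decay_rate))
  invisible(x)
}
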