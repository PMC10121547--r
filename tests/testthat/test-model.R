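test_that("log-likelihood equals the sum of normal log-densities", {
  # single standard-normal observation
  d1 <- list(y = 0, X = matrix(1, 1, 1))
  expect_equal(as.numeric(mpr_loglik(mpr_params(0, 0), d1)),
               -0.5 * log(2 * pi))
  # constant unit variance reduces to the homoscedastic log-likelihood
  td <- toy_data(n = 30, p = 2, seed = 2)
  pr <- mpr_params(c(0.5, 1, -1), c(0, 0, 0))
  mu <- drop(td$X %*% pr$beta)
  expect_equal(as.numeric(mpr_loglik(pr, td)),
               sum(dnorm(td$y, mu, 1, log = TRUE)))
  # general case against the per-observation density-sum oracle
  set.seed(9)
  td <- toy_data(n = 50, p = 3, seed = 9)
  pr <- mpr_params(rnorm(4), rnorm(4, sd = 0.4))
  sd_i <- exp(drop(td$X %*% pr$alpha) / 2)
  expect_equal(as.numeric(mpr_loglik(pr, td)),
               sum(dnorm(td$y, drop(td$X %*% pr$beta), sd_i, log = TRUE)),
               tolerance = 1e-10)
})

test_that("log-likelihood clamps extreme log-variance predictors and counts clips", {
  td <- toy_data(n = 20, p = 1, seed = 3)
  pr <- mpr_params(c(0, 0), c(100, 0))  # log-variance 100 -> clamped to 30
  ll <- mpr_loglik(pr, td)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "n_clips"), 20L)
  # perturbing y away from the fitted mean (variance fixed) lowers it
  d1 <- list(y = 0.5, X = matrix(1, 1, 1))
  expect_lt(as.numeric(mpr_loglik(mpr_params(0, 0), d1)),
            as.numeric(mpr_loglik(mpr_params(0.5, 0), d1)))
})

test_that("smooth-IC objective assembles likelihood and penalty correctly", {
  td <- toy_data(n = 60, p = 3, seed = 4)
  n <- length(td$y)
  lam <- log(n)
  # all non-intercept coefficients zero: objective = ll - lambda
  pr0 <- mpr_params(c(0.7, 0, 0, 0), c(0.2, 0, 0, 0))
  expect_equal(sic_objective(pr0, td, eps = 0.5),
               as.numeric(mpr_loglik(pr0, td)) - lam)
  # tiny eps with all |coef| >= 1: penalty ~ (lambda/2)(2p + 2)
  pr1 <- mpr_params(c(0, 1, -1.5, 2), c(0, 1, 1, -1))
  expect_equal(sic_objective(pr1, td, eps = 1e-12),
               as.numeric(mpr_loglik(pr1, td)) - (lam / 2) * (2 * 3 + 2),
               tolerance = 1e-10)
  # invariant to permuting predictors together with their coefficients
  perm <- c(3, 1, 2)
  td_p <- list(y = td$y, X = td$X[, c(1, perm + 1)])
  pr_p <- mpr_params(pr1$beta[c(1, perm + 1)], pr1$alpha[c(1, perm + 1)])
  expect_equal(sic_objective(pr1, td, 0.3), sic_objective(pr_p, td_p, 0.3))
})

test_that("penalized score matches finite differences and normal equations", {
  td <- toy_data(n = 50, p = 3, seed = 5)
  k <- 4
  pr <- mpr_params(c(0.4, 0.9, -0.2, 0.05), c(0.1, 0.3, -0.4, 0.6))
  for (eps in c(1, 0.05)) {
    s <- penalized_score(pr, td, eps)
    f <- function(th) sic_objective(mpr_params(th[1:k], th[k + 1:k]), td, eps)
    g_fd <- fd_grad(f, c(pr$beta, pr$alpha))
    expect_equal(c(s$g_beta, s$g_alpha), g_fd, tolerance = 1e-5)
  }
  # beta block vanishes at OLS when the penalty is off and alpha is constant
  bols <- qr.coef(qr(td$X), td$y)
  s0 <- penalized_score(mpr_params(unname(bols), c(0.3, 0, 0, 0)), td,
                        eps = 0.5, penalty_weight = 0)
  expect_lt(max(abs(s0$g_beta)), 1e-8)
  # intercept entry is never penalized
  s1 <- penalized_score(pr, td, eps = 0.05)
  s2 <- penalized_score(pr, td, eps = 0.05, penalty_weight = 0)
  expect_equal(s1$g_beta[1], s2$g_beta[1])
  expect_equal(s1$g_alpha[1], s2$g_alpha[1])
})

test_that("information blocks match finite-difference curvature", {
  td <- toy_data(n = 40, p = 2, seed = 6)
  k <- 3
  pr <- mpr_params(c(0.2, 0.8, -0.3), c(0.1, 0.5, -0.2))
  eps <- 0.3
  blocks <- penalized_information(pr, td, eps)
  expect_equal(blocks$A_beta, t(blocks$A_beta), tolerance = 1e-12)
  expect_equal(blocks$A_alpha, t(blocks$A_alpha), tolerance = 1e-12)
  # beta block = negative Hessian of the objective in beta (alpha fixed)
  fb <- function(b) sic_objective(mpr_params(b, pr$alpha), td, eps)
  expect_equal(blocks$A_beta, -fd_hess(fb, pr$beta), tolerance = 1e-4)
  # penalty off + constant alpha: exp(-alpha0) X'X exactly
  b0 <- penalized_information(mpr_params(pr$beta, c(0.4, 0, 0)), td, eps,
                              penalty_weight = 0)
  expect_equal(b0$A_beta, exp(-0.4) * crossprod(td$X), tolerance = 1e-12)
})

test_that("full information includes cross blocks and matches the objective Hessian", {
  td <- toy_data(n = 40, p = 2, seed = 7)
  k <- 3
  pr <- mpr_params(c(0.2, 0.8, -0.3), c(0.1, 0.5, -0.2))
  eps <- 0.4
  inf <- full_information(pr, td, eps)
  # penalty off: penalized equals unpenalized
  inf0 <- full_information(pr, td, eps, penalty_weight = 0)
  expect_equal(inf0$I, inf0$I0)
  # negative Hessian of the full objective
  f <- function(th) sic_objective(mpr_params(th[1:k], th[k + 1:k]), td, eps)
  H <- fd_hess(f, c(pr$beta, pr$alpha))
  expect_equal(inf$I, -H, tolerance = 1e-4)
  # unpenalized information is positive definite at the truth on larger data
  big <- toy_data(n = 2000, p = 2, seed = 8,
                  beta = c(0.5, 1, 1), alpha = c(0.2, 0.4, 0.4))
  infb <- full_information(mpr_params(c(0.5, 1, 1), c(0.2, 0.4, 0.4)),
                           big, eps = 1e-5)
  expect_gt(min(eigen(infb$I0 / 2000, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})
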