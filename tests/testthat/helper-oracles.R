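# Shared fixtures and independent oracles for the test suite.

# central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hess <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ei <- replace(numeric(k), i, h)
    ej <- replace(numeric(k), j, h)
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h * h)
  }
  H
}

# small random heteroscedastic dataset (already unit-scaled predictors)
toy_data <- function(n = 40, p = 3, seed = 1,
                     beta = c(0.5, rep(1, p)), alpha = c(0.2, rep(0.4, p))) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  X <- cbind(1, x)
  y <- drop(X %*% beta) + rnorm(n, sd = exp(drop(X %*% alpha) / 2))
  list(y = y, X = X)
}

# dataset with a known sparse truth, for selection tests
sparse_data <- function(n = 500, p = 2, seed = 1,
                        beta_idx = 1, alpha_idx = 2,
                        beta_val = 1, alpha_val = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  beta <- c(0.3, replace(numeric(p), beta_idx, beta_val))
  alpha <- c(0.1, replace(numeric(p), alpha_idx, alpha_val))
  X <- cbind(1, x)
  y <- drop(X %*% beta) + rnorm(n, sd = exp(drop(X %*% alpha) / 2))
  list(y = y, X = X, beta = beta, alpha = alpha)
}

# direct unpenalized MLE of the location-scale normal model by quasi-Newton
# on the raw log-likelihood (independent of the package's Newton scheme)
direct_mle <- function(y, X) {
  k <- ncol(X)
  negll <- function(th) {
    b <- th[1:k]; a <- th[k + 1:k]
    ea <- drop(X %*% a)
    0.5 * length(y) * log(2 * pi) + 0.5 * sum(ea) +
      0.5 * sum(exp(-ea) * (y - drop(X %*% b))^2)
  }
  b0 <- qr.coef(qr(X), y)
  s2 <- sum((y - drop(X %*% b0))^2) / (length(y) - k + 1)
  th0 <- c(b0, log(s2), rep(0, k - 1))
  op <- optim(th0, negll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  list(beta = op$par[1:k], alpha = op$par[k + 1:k], loglik = -op$value)
}

# exhaustive best-subset BIC oracle: fit the unpenalized model restricted to
# every support pattern over the p predictors in each component, and return
# the minimum-BIC pattern (ties broken towards the smaller support)
subset_oracle <- function(y, X, lambda = log(length(y))) {
  p <- ncol(X) - 1L
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  sizes <- lengths(subsets)
  ord <- order(sizes)
  subsets <- subsets[ord]
  best <- NULL
  sch1 <- sicreg::make_schedule(1, 1, 1)
  for (sb in subsets) for (sa in subsets) {
    Xb <- X[, c(1L, sb + 1L), drop = FALSE]
    Xa <- X[, c(1L, sa + 1L), drop = FALSE]
    mle <- direct_mle_xx(y, Xb, Xa)
    bic <- -2 * mle$loglik + lambda * (length(sb) + length(sa) + 2)
    if (is.null(best) || bic < best$bic - 1e-9)
      best <- list(bic = bic, support_beta = sb, support_alpha = sa)
  }
  best
}

# restricted unpenalized MLE with distinct designs per component
direct_mle_xx <- function(y, Xb, Xa) {
  kb <- ncol(Xb); ka <- ncol(Xa)
  negll <- function(th) {
    b <- th[1:kb]; a <- th[kb + 1:ka]
    ea <- drop(Xa %*% a)
    0.5 * length(y) * log(2 * pi) + 0.5 * sum(ea) +
      0.5 * sum(exp(-ea) * (y - drop(Xb %*% b))^2)
  }
  b0 <- qr.coef(qr(Xb), y)
  s2 <- sum((y - drop(Xb %*% b0))^2) / length(y)
  th0 <- c(b0, log(s2), rep(0, ka - 1))
  op <- optim(th0, negll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  list(beta = op$par[1:kb], alpha = op$par[kb + 1:ka], loglik = -op$value)
}
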