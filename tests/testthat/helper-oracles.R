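# Independent brute-force oracles. These deliberately share no code path
# with the package: dense per-group covariance matrices, explicit loops,
# grid search + simplex polish over the raw variance components.

# Marginal Gaussian log-likelihood of the random-intercept model at raw
# variance components (v1 = level-1, v2 = level-2), with beta profiled by
# dense GLS.
oracle_lmm_loglik <- function(v1, v2, y, X, groups) {
  idx_by_g <- split(seq_along(y), groups)
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  for (idx in idx_by_g) {
    V <- diag(v1, length(idx)) + v2
    Vi <- solve(V)
    Xg <- X[idx, , drop = FALSE]
    XtVX <- XtVX + t(Xg) %*% Vi %*% Xg
    XtVy <- XtVy + t(Xg) %*% Vi %*% y[idx]
  }
  beta <- solve(XtVX, XtVy)
  ll <- 0
  for (idx in idx_by_g) {
    V <- diag(v1, length(idx)) + v2
    r <- y[idx] - X[idx, , drop = FALSE] %*% beta
    ll <- ll - 0.5 * (as.numeric(determinant(V)$modulus) +
                        as.numeric(t(r) %*% solve(V, r)) +
                        length(idx) * log(2 * pi))
  }
  list(loglik = ll, beta = as.numeric(beta))
}

# Maximize the explicit marginal likelihood by dense grid + Nelder-Mead
# polish over (log v1, log(v2 + tiny)).
oracle_lmm_ml <- function(y, X, groups) {
  vy <- stats::var(y)
  grid1 <- vy * exp(seq(log(0.02), log(2), length.out = 18))
  grid2 <- c(0, vy * exp(seq(log(1e-3), log(2), length.out = 17)))
  best <- list(loglik = -Inf)
  for (v1 in grid1) for (v2 in grid2) {
    cand <- oracle_lmm_loglik(v1, v2, y, X, groups)
    if (cand$loglik > best$loglik) best <- c(cand, list(v1 = v1, v2 = v2))
  }
  eps <- 1e-10
  polish <- stats::optim(
    log(c(best$v1, best$v2 + eps)),
    function(t) -oracle_lmm_loglik(exp(t[1]), max(exp(t[2]) - eps, 0),
                                   y, X, groups)$loglik,
    method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000))
  v1 <- exp(polish$par[1])
  v2 <- max(exp(polish$par[2]) - eps, 0)
  out <- oracle_lmm_loglik(v1, v2, y, X, groups)
  list(loglik = out$loglik, beta = out$beta, v1 = v1, v2 = v2)
}

# Two-pass, loop-based within/between decomposition (population divisors).
oracle_decompose <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]
  g <- as.character(g[ok])
  ids <- unique(g)
  means <- sapply(ids, function(i) mean(x[g == i]))
  dev <- unlist(lapply(ids, function(i) x[g == i] - means[[i]]))
  list(mean = mean(x),
       sd_total = sqrt(sum((x - mean(x))^2) / length(x)),
       sd_within = sqrt(sum(dev^2) / length(x)),
       sd_between = sqrt(sum((means - mean(means))^2) / length(means)))
}

# Standard-normal upper tail through numeric integration of the density
# (independent of pnorm).
oracle_two_sided_p <- function(z) {
  upper <- stats::integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi),
                            abs(z), Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
  2 * upper
}
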