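# Maximum-likelihood estimation of linear models with random intercepts.
#
# The single-intercept model is y = X b + gamma_g + e with
# Var(y_g) = s2 (I + lambda J), lambda = var_level2/var_level1. For fixed
# lambda the GLS coefficients and s2 have closed forms through the
# compound-symmetry inverse (I - lambda/(1 + n lambda) J), so estimation is a
# 1-D derivative-free search over log(lambda) with the lambda = 0 boundary
# (ordinary least squares) always admitted. The nested two-intercept variant
# (outer group + inner subgroup, used by the pooled two-site stack) applies
# the same profiling with a second Woodbury step.

bm_check_design <- function(y, X, groups) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, length(groups) == n)
  if (anyNA(y) || anyNA(X)) {
    stop("fit_random_intercept expects complete cases; drop nulls first")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design error: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

# Profiled quantities at a fixed variance ratio for the single-intercept
# model. Returns the GLS normal-equation pieces and the profile loglik.
bm_profile1 <- function(lambda, y, X, gidx, ng, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  Sx <- rowsum(X, gidx, reorder = TRUE)
  Sy <- rowsum(y, gidx, reorder = TRUE)[, 1]
  cg <- lambda / (1 + ng * lambda)
  A <- crossprod(X) - crossprod(Sx * sqrt(cg))
  b <- crossprod(X, y) - crossprod(Sx, cg * Sy)
  q <- sum(y^2) - sum(cg * Sy^2)
  beta <- solve(A, b)
  rss <- max(q - sum(b * beta), 1e-300)
  ldet <- sum(log1p(ng * lambda))
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldet +
                    determinant(A, logarithm = TRUE)$modulus[1])
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + ldet)
  }
  list(loglik = as.numeric(ll), beta = beta[, 1], A = A, s2 = s2,
       lambda = lambda)
}

#' Fit a linear model with one random intercept by maximum likelihood
#'
#' Gaussian marginal likelihood maximized by profiling: at each value of the
#' variance ratio `lambda = var_level2 / var_level1` the fixed effects and
#' the level-1 variance have closed-form GLS/ML solutions; `lambda` itself is
#' found by a deterministic 1-D search over `log(lambda)` on
#' `[1e-8, 1e8]`, with the boundary `lambda = 0` always evaluated and
#' admitted. Groups observed once are retained (they inform the fixed
#' effects and the level-1 variance). Fixed-effect covariance is the inverse
#' GLS information at the optimum (large-sample z inference; no small-sample
#' correction).
#'
#' @param y Response vector (complete cases only).
#' @param X Design matrix including the intercept column.
#' @param groups Level-2 labels aligned with `y`.
#' @param reml Use REML instead of ML (default `FALSE`; ML matches the
#'   large-sample structural-equation convention).
#' @return A `bm_lmm`: `coefficients`, `vcov`, `var_level1`, `var_level2`,
#'   `lambda`, `loglik`, `n_obs`, `n_groups`, `converged`.
#' @export
fit_random_intercept <- function(y, X, groups, reml = FALSE) {
  X <- bm_check_design(y, X, groups)
  # canonical value-based row order: results are bitwise permutation-invariant
  ord <- do.call(order, c(list(as.character(groups), y),
                          lapply(seq_len(ncol(X)), function(j) X[, j])))
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  groups <- groups[ord]
  gidx <- factor(groups)
  ng <- as.numeric(table(gidx))
  f <- function(theta) bm_profile1(exp(theta), y, X, gidx, ng, reml)$loglik
  at0 <- bm_profile1(0, y, X, gidx, ng, reml)
  opt <- stats::optimize(f, interval = log(c(1e-8, 1e8)), maximum = TRUE,
                         tol = 1e-10)
  best <- bm_profile1(exp(opt$maximum), y, X, gidx, ng, reml)
  # prefer the boundary on (numerical) ties: lambda is unidentified when
  # every group is observed once, and parsimony then pins it at zero
  if (at0$loglik >= best$loglik - 1e-7 * (1 + abs(best$loglik))) best <- at0
  bm_lmm_result(best, y, X, groups, reml,
                n_groups = nlevels(gidx), lambda2 = NULL)
}

bm_lmm_result <- function(best, y, X, groups, reml, n_groups, lambda2,
                          subgroups = NULL, ldet_extra = 0) {
  vc <- best$s2 * solve(best$A)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(best$beta, colnames(X)),
    vcov = vc,
    var_level1 = best$s2,
    var_level2 = best$lambda * best$s2,
    var_session = if (is.null(lambda2)) NULL else lambda2 * best$s2,
    lambda = best$lambda,
    lambda_session = lambda2,
    loglik = best$loglik,
    n_obs = length(y),
    n_groups = n_groups,
    reml = reml,
    converged = is.finite(best$loglik),
    y = y, X = X, groups = groups, subgroups = subgroups
  ), class = "bm_lmm")
}

#' @export
print.bm_lmm <- function(x, ...) {
  cat("<bm_lmm> ", if (x$reml) "REML" else "ML", " fit: ", x$n_obs,
      " obs in ", x$n_groups, " groups; loglik ", format(x$loglik),
      "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se))
  cat("var_level1 ", format(x$var_level1), ", var_level2 ",
      format(x$var_level2),
      if (!is.null(x$var_session)) paste0(", var_session ",
                                          format(x$var_session)),
      "\n", sep = "")
  invisible(x)
}

# Profiled quantities for the nested two-intercept model:
# Var(y_g)/s2 = I + l1 J_g + l2 blockdiag(J_subgroup). Double Woodbury.
bm_profile2 <- function(l1, l2, y, X, gidx, sidx, s_of_g, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  Ss <- rowsum(X, sidx, reorder = TRUE)
  Sys <- rowsum(y, sidx, reorder = TRUE)[, 1]
  ms <- as.numeric(table(sidx))
  cs <- l2 / (1 + l2 * ms)
  XDX <- crossprod(X) - crossprod(Ss * sqrt(cs))
  XDy <- crossprod(X, y) - crossprod(Ss, cs * Sys)
  yDy <- sum(y^2) - sum(cs * Sys^2)
  # per-outer-group aggregates of D^{-1} 1
  wsub <- 1 / (1 + l2 * ms)
  Tg <- rowsum(Ss * wsub, s_of_g, reorder = TRUE)          # G x p
  ug <- rowsum(Sys * wsub, s_of_g, reorder = TRUE)[, 1]
  hg <- rowsum(ms * wsub, s_of_g, reorder = TRUE)[, 1]
  cg <- l1 / (1 + l1 * hg)
  A <- XDX - crossprod(Tg * sqrt(cg))
  b <- XDy - crossprod(Tg, cg * ug)
  q <- yDy - sum(cg * ug^2)
  beta <- solve(A, b)
  rss <- max(q - sum(b * beta), 1e-300)
  ldet <- sum(log1p(l2 * ms)) + sum(log1p(l1 * hg))
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldet +
                    determinant(A, logarithm = TRUE)$modulus[1])
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + ldet)
  }
  list(loglik = as.numeric(ll), beta = beta[, 1], A = A, s2 = s2,
       lambda = l1, lambda2 = l2)
}

#' Fit a linear model with nested random intercepts (outer + inner)
#'
#' Extension of [fit_random_intercept()] with a second, inner random
#' intercept nested in the outer one (participant and participant-session in
#' the pooled two-site stack; the shared session intercept induces an
#' exchangeable cross-outcome correlation within a session). Profiled ML over
#' the two variance ratios: boundaries (either or both ratios zero) are
#' evaluated through the single-intercept profile, the interior by a
#' deterministic Nelder-Mead polish on the log-ratio scale started from the
#' best boundary solution.
#'
#' @param y,X,reml As in [fit_random_intercept()].
#' @param groups Outer (level-2) labels.
#' @param subgroups Inner labels, nested in `groups`.
#' @return A `bm_lmm` with the additional components `var_session` and
#'   `lambda_session`.
#' @export
fit_nested_intercepts <- function(y, X, groups, subgroups, reml = FALSE) {
  X <- bm_check_design(y, X, groups)
  ord <- do.call(order, c(list(as.character(groups), as.character(subgroups),
                               y),
                          lapply(seq_len(ncol(X)), function(j) X[, j])))
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  groups <- groups[ord]
  subgroups <- subgroups[ord]
  gidx <- factor(groups)
  sidx <- factor(paste(groups, subgroups, sep = "\r"))
  # outer group of each subgroup level
  s_of_g <- factor(vapply(strsplit(levels(sidx), "\r", fixed = TRUE),
                          `[[`, character(1), 1),
                   levels = levels(gidx))
  ng <- as.numeric(table(gidx))
  prof <- function(l1, l2) bm_profile2(l1, l2, y, X, gidx, sidx, s_of_g, reml)
  # boundary candidates
  cand <- list(prof(0, 0))
  o1 <- stats::optimize(function(t) prof(exp(t), 0)$loglik,
                        log(c(1e-8, 1e8)), maximum = TRUE, tol = 1e-10)
  cand <- c(cand, list(prof(exp(o1$maximum), 0)))
  o2 <- stats::optimize(function(t) prof(0, exp(t))$loglik,
                        log(c(1e-8, 1e8)), maximum = TRUE, tol = 1e-10)
  cand <- c(cand, list(prof(0, exp(o2$maximum))))
  # interior polish
  start <- log(pmax(c(exp(o1$maximum), exp(o2$maximum)), 1e-6))
  oi <- stats::optim(start, function(t) -prof(exp(t[1]), exp(t[2]))$loglik,
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 1000))
  cand <- c(cand, list(prof(exp(oi$par[1]), exp(oi$par[2]))))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
  bm_lmm_result(best, y, X, groups, reml, n_groups = nlevels(gidx),
                lambda2 = best$lambda2, subgroups = subgroups)
}

#' Wald z statistic and two-sided normal p-value
#'
#' Large-sample inference on a single coefficient: `z = estimate/se`,
#' `p = 2 * (1 - Phi(|z|))`.
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return `list(z = , p = )`.
#' @export
#' @examples
#' wald_z(1.96, 1)$p  # ~0.05
wald_z <- function(estimate, se) {
  if (any(se <= 0)) stop("se must be positive")
  z <- estimate / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
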