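sim_lmm_data <- function(seed = 1, G = 40, n_per = 3, beta = c(1, 0.5, -0.3),
                         sd2 = 0.8, sd1 = 0.6) {
  set.seed(seed)
  g <- rep(seq_len(G), each = n_per)
  N <- length(g)
  X <- cbind("(intercept)" = 1, x1 = rnorm(N), x2 = rnorm(N))
  y <- as.numeric(X %*% beta) + rnorm(G, 0, sd2)[g] + rnorm(N, 0, sd1)
  list(y = y, X = X, g = g)
}

test_that("fit collapses to ordinary least squares when groups are uninformative", {
  set.seed(3)
  # one observation per group: level-2 variance is unidentified, lambda -> 0
  N <- 80
  X <- cbind("(intercept)" = 1, x = rnorm(N))
  y <- 2 + 0.7 * X[, "x"] + rnorm(N)
  fit <- fit_random_intercept(y, X, seq_len(N))
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_lt(fit$var_level2, 1e-6)
  # nesting: optimum can never fall below the lambda = 0 profile
  expect_gte(fit$loglik,
             bonemed:::bm_profile1(0, y, X, factor(seq_len(N)),
                                   rep(1, N))$loglik - 1e-10)
})

test_that("ML optimum matches the dense grid + polish oracle on the tiny fixture", {
  tiny <- zstandardize(make_fixture("tiny", seed = 1), bm_test_vars)
  eq <- default_model_spec("radial")$bone_equation
  d <- equation_design(tiny, eq)
  fit <- fit_random_intercept(d$y, d$X, d$groups)
  oracle <- oracle_lmm_ml(d$y, d$X, d$groups)
  expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-7)
  expect_equal(fit$var_level1, oracle$v1, tolerance = 1e-3)
  expect_equal(fit$var_level2, oracle$v2, tolerance = 1e-3)
})

test_that("ML and REML agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- sim_lmm_data(seed = 9, G = 50)
  df <- data.frame(y = d$y, x1 = d$X[, "x1"], x2 = d$X[, "x2"], g = d$g)
  for (reml in c(FALSE, TRUE)) {
    fit <- fit_random_intercept(d$y, d$X, d$g, reml = reml)
    ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = df, REML = reml)
    expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(ref))$vcov
    expect_equal(fit$var_level2, vc[1], tolerance = 1e-5)
    expect_equal(fit$var_level1, vc[2], tolerance = 1e-5)
    expect_equal(unname(sqrt(diag(fit$vcov))),
                 unname(coef(summary(ref))[, "Std. Error"]), tolerance = 1e-5)
  }
})

test_that("nested two-intercept ML matches lme4 on crossed-free data", {
  skip_if_not_installed("lme4")
  set.seed(21)
  G <- 40
  g <- rep(seq_len(G), each = 6)
  s <- rep(seq_len(3 * G), each = 2)          # 3 sessions x 2 rows
  N <- length(g)
  x <- rnorm(N)
  X <- cbind("(intercept)" = 1, x = x)
  y <- 0.4 * x + rnorm(G, 0, 0.7)[g] + rnorm(3 * G, 0, 0.5)[s] +
    rnorm(N, 0, 0.4)
  fit <- fit_nested_intercepts(y, X, g, s)
  ref <- lme4::lmer(y ~ x + (1 | g) + (1 | s), REML = FALSE)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$var_session, vc$vcov[vc$grp == "s"], tolerance = 1e-4)
  expect_equal(fit$var_level2, vc$vcov[vc$grp == "g"], tolerance = 1e-4)
})

test_that("estimates are affine-equivariant and permutation-invariant", {
  d <- sim_lmm_data(seed = 5)
  fit <- fit_random_intercept(d$y, d$X, d$g)
  # scaling the response scales coefficients and SD components
  fit_sc <- fit_random_intercept(3 * d$y, d$X, d$g)
  expect_equal(fit_sc$coefficients, 3 * fit$coefficients, tolerance = 1e-6)
  expect_equal(fit_sc$var_level1, 9 * fit$var_level1, tolerance = 1e-4)
  expect_equal(fit_sc$var_level2, 9 * fit$var_level2, tolerance = 1e-4)
  # shifting the response moves only the intercept
  fit_sh <- fit_random_intercept(d$y + 10, d$X, d$g)
  expect_equal(fit_sh$coefficients[["(intercept)"]],
               fit$coefficients[["(intercept)"]] + 10, tolerance = 1e-6)
  expect_equal(fit_sh$coefficients[-1], fit$coefficients[-1],
               tolerance = 1e-8)
  # permuting rows changes nothing
  set.seed(8)
  perm <- sample(length(d$y))
  fit_p <- fit_random_intercept(d$y[perm], d$X[perm, ], d$g[perm])
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-10)
  expect_equal(fit_p$var_level2, fit$var_level2, tolerance = 1e-8)
})

test_that("intraclass correlation is recovered on generator-style data", {
  # 120 groups x 3, true ICC = 0.64/(0.64+0.36) = 0.64
  d <- sim_lmm_data(seed = 13, G = 120, n_per = 3, sd2 = 0.8, sd1 = 0.6)
  fit <- fit_random_intercept(d$y, d$X, d$g)
  icc <- fit$var_level2 / (fit$var_level1 + fit$var_level2)
  expect_equal(icc, 0.64, tolerance = 0.12)
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  d <- sim_lmm_data(seed = 2)
  X <- cbind(d$X, dup = d$X[, "x1"])
  expect_error(fit_random_intercept(d$y, X, d$g), "dup")
  expect_error(fit_random_intercept(c(d$y[-1], NA), d$X, d$g),
               "complete cases")
})

test_that("wald_z matches an independent normal-tail computation", {
  expect_equal(wald_z(0, 1), list(z = 0, p = 1))
  expect_equal(wald_z(1.96, 1)$p, 0.05, tolerance = 1e-3)
  expect_error(wald_z(1, 0), "positive")
  set.seed(4)
  for (i in 1:10) {
    est <- rnorm(1)
    se <- stats::runif(1, 0.1, 2)
    expect_equal(wald_z(est, se)$p, oracle_two_sided_p(est / se),
                 tolerance = 1e-8)
  }
})
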