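test_that("system fit composes the two engine fits on their own complete cases", {
  tiny <- zstandardize(make_fixture("tiny", seed = 1), bm_test_vars)
  spec <- default_model_spec("radial")
  sem <- fit_mediated_system(tiny, spec)
  for (part in c("bone", "muscle")) {
    eq <- if (part == "bone") spec$bone_equation else spec$muscle_equation
    d <- equation_design(tiny, eq)
    direct <- fit_random_intercept(d$y, d$X, d$groups)
    fit <- if (part == "bone") sem$bone_fit else sem$muscle_fit
    expect_equal(fit$coefficients, direct$coefficients, tolerance = 1e-12)
    expect_equal(fit$loglik, direct$loglik, tolerance = 1e-12)
  }
})

test_that("effect decomposition identities hold exactly in every fit", {
  for (site in c("radial", "tibial", "pooled")) {
    sem <- fit_mediated_system(std_cohort(seed = 4),
                               default_model_spec(site))
    ef <- sem$effects
    med <- sem$spec$bone_equation$mediator
    b <- ef$estimate[ef$modulator == med & ef$kind == "direct_on_bone"]
    for (v in sem$spec$muscle_equation$covariates) {
      a <- ef$estimate[ef$modulator == v & ef$kind == "effect_on_muscle"]
      ind <- ef$estimate[ef$modulator == v & ef$kind == "indirect_on_bone"]
      tot <- ef$estimate[ef$modulator == v & ef$kind == "total_on_bone"]
      dir <- ef$estimate[ef$modulator == v & ef$kind == "direct_on_bone"]
      if (length(dir) == 0) dir <- 0
      expect_equal(ind, a * b, tolerance = 1e-12)       # product rule
      expect_equal(tot, dir + ind, tolerance = 1e-12)   # additivity
    }
    # every declared covariate appears exactly once per applicable kind
    expect_equal(sum(ef$kind == "effect_on_muscle"),
                 length(sem$spec$muscle_equation$covariates))
    expect_equal(sum(ef$kind == "direct_on_bone"),
                 1 + length(sem$spec$bone_equation$covariates))
    # stars follow the footnote mapping
    expect_identical(ef$stars, bonemed:::bm_stars(ef$p))
  }
})

test_that("closed-form effect operations reproduce their defining arithmetic", {
  # null muscle path: estimate 0, se = |b| * sd_a
  e <- indirect_effect(0, 0.4, 0.01, 0.5)
  expect_equal(e$estimate, 0)
  expect_equal(e$se, 0.4 * 0.1)
  # degenerate total: all variances zero
  ind0 <- indirect_effect(0, 0, 0, 0)
  tot0 <- total_effect(0, ind0, 0)
  expect_equal(tot0$estimate, 0)
  expect_equal(tot0$se, 0)
  # the covariance term enters the total-effect variance linearly
  ind <- indirect_effect(0.5, 0.3, 0.04, 0.01)
  tot <- total_effect(0.2, ind, 0.09, cov_direct_mediator = -0.005, a = 0.5)
  expect_equal(tot$se^2, 0.09 + ind$se^2 + 2 * 0.5 * (-0.005),
               tolerance = 1e-12)
})

test_that("with all muscle paths zero, indirect effects centre on zero", {
  cf <- bm_default_coefficients()
  cf$muscle[] <- 0
  inds <- t(vapply(1:25, function(s) {
    std <- std_cohort(seed = 300 + s,
                      config = cohort_config(structural_coefficients = cf,
                                             seed = 300 + s))
    sem <- fit_mediated_system(std, default_model_spec("radial"))
    ef <- sem$effects
    ef$estimate[ef$kind == "indirect_on_bone"]
  }, numeric(5)))
  m <- colMeans(inds)
  mc_se <- apply(inds, 2, stats::sd) / sqrt(nrow(inds))
  expect_true(all(abs(m) < 3 * mc_se + 1e-4))
})

test_that("indirect-effect test keeps its size under the null-path fixture", {
  # all structural paths zero: the Sobel test may be conservative but must
  # not exceed the nominal level (plus binomial noise)
  R <- 120
  rej <- vapply(1:R, function(s) {
    std <- zstandardize(make_fixture("null_effects", seed = 500 + s),
                        bm_test_vars)
    sem <- fit_mediated_system(std, default_model_spec("radial"))
    ef <- sem$effects
    any(ef$p[ef$kind == "indirect_on_bone" &
               ef$modulator == "bone_age"] < 0.05)
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / R))
})

test_that("mediation patterns are classified from the effect signature", {
  fake_sem <- function(rows) {
    structure(list(effects = do.call(rbind, rows)), class = "bm_sem")
  }
  row <- function(mod, kind, p) {
    data.frame(modulator = mod, kind = kind, estimate = 0.1, se = 0.05,
               z = 2, p = p, stars = "", stringsAsFactors = FALSE)
  }
  # no direct path, significant indirect: full mediation
  expect_identical(classify_mediation(fake_sem(list(
    row("bone_age", "indirect_on_bone", 1e-4))), "bone_age"), "full")
  # both paths significant: partial
  expect_identical(classify_mediation(fake_sem(list(
    row("maturity_offset", "direct_on_bone", 1e-4),
    row("maturity_offset", "indirect_on_bone", 1e-3))),
    "maturity_offset"), "partial")
  # insignificant direct path with significant indirect: full
  expect_identical(classify_mediation(fake_sem(list(
    row("bmi", "direct_on_bone", 0.4),
    row("bmi", "indirect_on_bone", 0.01))), "bmi"), "full")
  # insignificant indirect: none
  expect_identical(classify_mediation(fake_sem(list(
    row("energy_intake", "indirect_on_bone", 0.2))),
    "energy_intake"), "none")
})

test_that("pooled stack pools the site information coherently", {
  std <- std_cohort(seed = 11)
  sem_p <- fit_mediated_system(std, default_model_spec("pooled"))
  sem_r <- fit_mediated_system(std, default_model_spec("radial"))
  sem_t <- fit_mediated_system(std, default_model_spec("tibial"))
  truth <- bm_default_coefficients()$bone
  for (v in c("mediator", "ntx", "maturity_offset", "bmi")) {
    term <- function(sem) {
      nm <- if (v == "mediator") sem$spec$bone_equation$mediator else v
      c(sem$bone_fit$coefficients[[nm]], sqrt(sem$bone_fit$vcov[nm, nm]))
    }
    p <- term(sem_p); r <- term(sem_r); t <- term(sem_t)
    # pooled estimate sits in the site range (up to one pooled SE; GLS
    # pooling is not coefficient-wise convex) and near the truth
    expect_gte(p[1], min(r[1], t[1]) - p[2])
    expect_lte(p[1], max(r[1], t[1]) + p[2])
    expect_lt(abs(p[1] - truth[[v]]), 2 * p[2])
    # pooling two sites should not be less precise than either site alone
    expect_lt(p[2], max(r[2], t[2]))
  }
  # shared residual structure shows up as positive cross-outcome correlation
  expect_gt(sem_p$residual_cross_correlation, 0)
})

test_that("delta and bootstrap indirect SEs agree where the paths are identified", {
  # same protocol as the small-sample acceptance check, at a size where the
  # first-order approximation is accurate (100 participants x 2 sessions)
  cfg <- cohort_config(
    n_participants = 100, session_count_distribution = c(0, 1, 0, 0),
    missingness = list(grip = 0, ntx = 0, energy = 0),
    exclusion_counts = c(diabetes_t1 = 0, fracture = 0, sos_undetected = 0,
                         missed_visit = 0),
    seed = 1)
  std <- zstandardize(generate_cohort(cfg)$table, bm_test_vars)
  sem <- fit_mediated_system(std, default_model_spec("radial"))
  draws <- bootstrap_indirect(sem, n_boot = 400, seed = 1)
  ef <- sem$effects
  for (v in colnames(draws)) {
    delta <- ef$se[ef$modulator == v & ef$kind == "indirect_on_bone"]
    expect_lt(abs(delta / stats::sd(draws[, v]) - 1), 0.15, label = v)
  }
})

test_that("spec errors are caught before fitting", {
  std <- std_cohort(seed = 2)
  spec <- default_model_spec("radial")
  no_grip <- std
  no_grip$grip_strength <- NULL
  expect_error(fit_mediated_system(no_grip, spec), "grip_strength")
  few <- std[std$participant_id %in% unique(std$participant_id)[1:2], ]
  expect_error(fit_mediated_system(few, spec), "insufficient data")
})
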