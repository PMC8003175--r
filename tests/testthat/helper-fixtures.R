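# Shared fixtures built in code.

bm_test_vars <- c("radial_sos", "tibial_sos", "grip_strength",
                  "knee_extension", "ntx", "paqc", "maturity_offset", "bmi",
                  "bone_age", "waeq", "energy_intake")

# Post-exclusion, z-standardized study-scale cohort.
std_cohort <- function(seed = 1, config = cohort_config(seed = seed)) {
  tab <- apply_exclusions(generate_cohort(config, seed = seed)$table)$table
  zstandardize(tab, bm_test_vars)
}

# Complete-case design for one equation (mirrors the internal frame builder
# so engine-level tests do not depend on it).
equation_design <- function(table, eq, grouping = "participant_id") {
  d <- as.data.frame(table)
  needed <- c(eq$outcome, eq$mediator, eq$covariates)
  d <- d[stats::complete.cases(d[, needed, drop = FALSE]), , drop = FALSE]
  X <- cbind("(intercept)" = 1,
             as.matrix(d[, c(eq$mediator, eq$covariates), drop = FALSE]))
  list(y = d[[eq$outcome]], X = X, groups = d[[grouping]])
}

# A small hand-made cohort data.frame for I/O and preprocessing tests.
toy_cohort_df <- function() {
  data.frame(
    participant_id = c("a", "a", "b", "b", "c"),
    session_index = c(1L, 2L, 1L, 2L, 1L),
    season = "spring", year = c(2010L, 2011L, 2010L, 2011L, 2012L),
    sex = c("male", "male", "female", "female", "male"),
    age = c(10, 11, 12, 13, 9),
    maturity_offset = c(-2, -1, 0.5, 1.5, -3),
    bone_age = c(10.5, 11.4, 12.2, 13.1, 9.2),
    bmi = c(17, 17.5, 21, 21.3, 16),
    radial_sos = c(3700, 3750, 3900, 3920, 3650),
    tibial_sos = c(3600, 3640, 3780, 3800, 3550),
    grip_strength = c(15, 17, 30, 32, NA),
    knee_extension = c(80, 95, 190, 200, 70),
    ntx_raw = c(1200, 1000, 600, 550, 1500),
    creatinine = c(2, 2.5, 1.5, 1.1, 3),
    ntx = c(600, 400, 400, 500, 500),
    paqc = c(0.2, 0.3, -0.1, 0.1, 0.4),
    waeq = c(60, 70, 90, 100, 40),
    energy_intake = c(1500, 1600, 1900, 2000, 1300),
    exclusion_flags = "",
    stringsAsFactors = FALSE
  )
}
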