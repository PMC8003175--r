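test_that("exclusion cascade removes flagged rows with a balanced, ordered log", {
  df <- toy_cohort_df()
  df$exclusion_flags <- c("", "fracture", "diabetes_t1;fracture", "", "")
  tab <- bonemed:::new_cohort(df, source = "test")
  out <- apply_exclusions(tab)
  expect_equal(nrow(out$table), 3)
  # double-flagged row is removed once, attributed to the first cascade reason
  expect_equal(unname(out$log$removed),
               c(1L, 1L, 0L, 0L))
  expect_equal(out$log$initial - sum(out$log$removed), out$log$final)
  # idempotent
  again <- apply_exclusions(out$table)
  expect_equal(nrow(again$table), 3)
  expect_true(all(again$log$removed == 0))
  # identity on an unflagged table
  clean <- apply_exclusions(bonemed:::new_cohort(toy_cohort_df()))
  expect_equal(nrow(clean$table), 5)
  expect_true(all(clean$log$removed == 0))
})

test_that("NTX correction is the creatinine ratio with null propagation", {
  expect_equal(correct_ntx(100, 2), 50)
  expect_equal(correct_ntx(539.8, 1), 539.8)
  expect_true(is.na(correct_ntx(NA, 2)))
  expect_true(is.na(correct_ntx(100, NA)))
  expect_error(correct_ntx(100, 0), "positive")
  set.seed(1)
  raw <- stats::runif(50, 10, 2000)
  cr <- stats::runif(50, 0.5, 20)
  expect_equal(correct_ntx(raw, cr), raw / cr)
})

test_that("WAeq is the MET-weighted frequency sum", {
  expect_equal(compute_waeq(0, 0, 0), 0)
  expect_equal(compute_waeq(2, 1, 1), 20)
  expect_equal(compute_waeq(2, 1, 1, met_weights = c(9, 5, 3)),
               compute_waeq(1, 1, 2))   # permute weights with frequencies
  expect_error(compute_waeq(-1, 0, 0), ">= 0")
})

test_that("z-standardization is exact, invertible and idempotent", {
  df <- toy_cohort_df()
  tab <- bonemed:::new_cohort(df)
  vars <- c("radial_sos", "bmi", "grip_strength")
  std <- zstandardize(tab, vars)
  for (v in vars) {
    x <- std[[v]]
    expect_lt(abs(mean(x, na.rm = TRUE)), 1e-10)
    expect_lt(abs(sqrt(mean((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE)) - 1),
              1e-10)
  }
  # {-1, +1} is a fixed point of population-SD scaling
  two <- bonemed:::new_cohort(data.frame(
    participant_id = c("a", "b"), session_index = 1L, season = "spring",
    sex = "male", bmi = c(-1, 1)))
  expect_equal(zstandardize(two, "bmi")$bmi, c(-1, 1))
  # nulls stay null
  expect_identical(is.na(std$grip_strength), is.na(tab$grip_strength))
  # round trip
  back <- back_transform(std)
  for (v in vars) expect_equal(back[[v]], tab[[v]], tolerance = 1e-10)
  # idempotent
  std2 <- zstandardize(std, vars)
  for (v in vars) expect_equal(std2[[v]], std[[v]], tolerance = 1e-10)
  # degenerate column
  const <- bonemed:::new_cohort(data.frame(
    participant_id = c("a", "b"), session_index = 1L, season = "spring",
    sex = "male", bmi = c(2, 2)))
  expect_error(zstandardize(const, "bmi"), "degenerate")
})

test_that("variance decomposition matches the explicit two-pass oracle", {
  set.seed(42)
  n_per <- sample(1:4, 25, replace = TRUE)
  g <- rep(sprintf("p%02d", 1:25), n_per)
  df <- data.frame(participant_id = g, session_index = sequence(n_per),
                   season = "spring", sex = "male",
                   bmi = rnorm(length(g), 19, 3),
                   waeq = rnorm(length(g), 70, 30))
  df$waeq[c(3, 10)] <- NA
  tab <- bonemed:::new_cohort(df)
  dec <- variance_decomposition(tab, c("bmi", "waeq"))
  for (v in c("bmi", "waeq")) {
    o <- oracle_decompose(tab[[v]], tab$participant_id)
    row <- dec[dec$variable == v, ]
    expect_equal(row$mean, o$mean, tolerance = 1e-12)
    expect_equal(row$sd_total, o$sd_total, tolerance = 1e-12)
    expect_equal(row$sd_within, o$sd_within, tolerance = 1e-12)
    expect_equal(row$sd_between, o$sd_between, tolerance = 1e-12)
  }
})

test_that("decomposition limits: single observations and equal means", {
  # one observation per participant: no within variation
  df <- data.frame(participant_id = letters[1:6], session_index = 1L,
                   season = "spring", sex = "male", bmi = c(15, 17, 19, 21, 23, 25))
  dec <- variance_decomposition(bonemed:::new_cohort(df), "bmi")
  expect_equal(dec$sd_within, 0)
  expect_equal(dec$sd_between, dec$sd_total, tolerance = 1e-12)
  # identical participant means: between collapses
  df2 <- data.frame(participant_id = rep(c("a", "b"), each = 2),
                    session_index = rep(1:2, 2), season = "spring",
                    sex = "male", bmi = c(18, 22, 19, 21))
  dec2 <- variance_decomposition(bonemed:::new_cohort(df2), "bmi")
  expect_equal(dec2$sd_between, 0)
})
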