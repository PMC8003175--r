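# Coefficient-equality testing between strata (e.g. boys vs girls).
#
# The classical pooled-F Chow test has no single residual sum of squares in
# the mixed-model setting; its standard generalization for independently
# fitted strata is the Wald chi-square on the coefficient-difference vector
# with variance equal to the sum of the stratum covariances.

bm_pull_fit <- function(x, equation) {
  if (inherits(x, "bm_lmm")) return(x)
  if (inherits(x, "bm_sem")) {
    return(switch(equation, bone = x$bone_fit, muscle = x$muscle_fit,
                  stop("equation must be 'bone' or 'muscle'")))
  }
  stop("expected a bm_sem or bm_lmm")
}

#' Chow-type Wald test of coefficient equality between two strata
#'
#' Both strata must be fitted with the same specification on the same
#' (whole-cohort) standardization scale; re-standardizing within stratum
#' would invalidate the comparison. Per coefficient the difference
#' `d = beta_a - beta_b` has variance `var_a + var_b` (independent strata);
#' the joint statistic `d' V^{-1} d` is referred to a chi-square with one
#' degree of freedom per tested coefficient.
#'
#' @param fit_a,fit_b `bm_sem` (or `bm_lmm`) fits of the two strata.
#' @param equation `"bone"` (default, the bone-property coefficients) or
#'   `"muscle"`; ignored when `bm_lmm`s are passed.
#' @param coefficients Optional subset of coefficient names to test
#'   (default: all shared coefficients except the intercept).
#' @param exclude Optional names to drop from the tested set (e.g. `"bmi"`,
#'   to test equality of all bone coefficients except BMI).
#' @return A `bm_chow`: `tested_coefficients`, `statistic`, `df`, `p`, and a
#'   `per_coefficient` data.frame (difference, SE, z, p per name).
#' @export
chow_test <- function(fit_a, fit_b, equation = c("bone", "muscle"),
                      coefficients = NULL, exclude = NULL) {
  equation <- match.arg(equation)
  la <- bm_pull_fit(fit_a, equation)
  lb <- bm_pull_fit(fit_b, equation)
  if (is.null(coefficients)) {
    coefficients <- setdiff(names(la$coefficients), "(intercept)")
  }
  coefficients <- setdiff(coefficients, exclude)
  if (!all(coefficients %in% names(la$coefficients)) ||
      !all(coefficients %in% names(lb$coefficients))) {
    stop("spec error: non-conformable coefficient sets")
  }
  d <- la$coefficients[coefficients] - lb$coefficients[coefficients]
  V <- la$vcov[coefficients, coefficients, drop = FALSE] +
    lb$vcov[coefficients, coefficients, drop = FALSE]
  stat <- as.numeric(t(d) %*% solve(V, d))
  df <- length(coefficients)
  se <- sqrt(diag(V))
  wz <- wald_z(d, se)
  structure(list(
    tested_coefficients = coefficients,
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE),
    per_coefficient = data.frame(
      coefficient = coefficients, difference = as.numeric(d), se = se,
      z = wz$z, p = wz$p, row.names = NULL, stringsAsFactors = FALSE)
  ), class = "bm_chow")
}

#' @export
print.bm_chow <- function(x, ...) {
  cat("<bm_chow> Wald chi-square = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format.pval(x$p), "\n", sep = "")
  print(x$per_coefficient, row.names = FALSE)
  invisible(x)
}

#' Difference in an effect between two strata
#'
#' For two effect rows of the same modulator and kind (typically the total
#' effects from independently fitted strata): difference, SE
#' `sqrt(se_a^2 + se_b^2)`, and two-sided normal p.
#'
#' @param effect_a,effect_b One-row effect data.frames (see the `effects`
#'   component of a `bm_sem`, or [indirect_effect()]/[total_effect()]).
#' @return One-row data.frame: `modulator`, `kind`, `difference`, `se`, `z`,
#'   `p`.
#' @export
total_effect_difference <- function(effect_a, effect_b) {
  stopifnot(nrow(effect_a) == 1, nrow(effect_b) == 1)
  if (!identical(effect_a$kind, effect_b$kind) ||
      !identical(effect_a$modulator, effect_b$modulator)) {
    stop("effects must share modulator and kind")
  }
  d <- effect_a$estimate - effect_b$estimate
  se <- sqrt(effect_a$se^2 + effect_b$se^2)
  if (se == 0) {
    z <- NA_real_
    p <- if (d == 0) 1 else NA_real_
  } else {
    wz <- wald_z(d, se)
    z <- wz$z
    p <- wz$p
  }
  data.frame(modulator = effect_a$modulator, kind = effect_a$kind,
             difference = d, se = se, z = z, p = p,
             stringsAsFactors = FALSE)
}
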