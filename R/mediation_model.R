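# Two-equation mediated system: muscle strength regressed on its modulators
# (W), bone SOS regressed on muscle strength and its modulators (Z), each
# with a participant random intercept; direct, indirect and total effects
# with first-order delta-method (Sobel) standard errors.
#
# The system is recursive (the bone equation conditions on the observed
# mediator and cross-equation errors are independent), so the joint
# likelihood factorizes and the two equations are fitted separately on their
# own complete cases.

bm_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

bm_effect_row <- function(modulator, kind, estimate, se) {
  if (is.na(se) || se <= 0) {
    z <- NA_real_
    p <- NA_real_
  } else {
    wz <- wald_z(estimate, se)
    z <- wz$z
    p <- wz$p
  }
  data.frame(modulator = modulator, kind = kind, estimate = estimate,
             se = se, z = z, p = p, stars = bm_stars(p),
             stringsAsFactors = FALSE)
}

#' Indirect (mediated) effect of a modulator on bone SOS
#'
#' Product of the modulator-to-muscle path `a` and the muscle-to-bone path
#' `b`, with the first-order delta-method (Sobel) standard error
#' `sqrt(b^2 var_a + a^2 var_b)`; z and p from the standard normal.
#'
#' @param a Muscle-equation coefficient of the modulator.
#' @param b Bone-equation coefficient of the mediator.
#' @param var_a,var_b Sampling variances of `a` and `b` (>= 0).
#' @param modulator Modulator name carried into the result.
#' @return One-row effect data.frame (`kind = "indirect_on_bone"`).
#' @export
#' @examples
#' indirect_effect(0.480, 0.288, 0.038^2, 0.061^2)$estimate  # ~0.138
indirect_effect <- function(a, b, var_a, var_b, modulator = "") {
  stopifnot(var_a >= 0, var_b >= 0)
  bm_effect_row(modulator, "indirect_on_bone", a * b,
                sqrt(b^2 * var_a + a^2 * var_b))
}

#' Total effect of a modulator on bone SOS
#'
#' `total = direct + indirect` exactly; its delta-method variance is
#' `var_direct + se_indirect^2 + 2 a cov(direct, b)`, where the covariance
#' between the modulator's direct coefficient and the mediator coefficient
#' comes from the bone-equation coefficient covariance and cross-equation
#' covariances are zero (the equations are fitted on distinct complete-case
#' sets).
#'
#' @param direct Bone-equation coefficient of the modulator (0 if the
#'   modulator is absent from the bone equation).
#' @param indirect One-row effect as returned by [indirect_effect()].
#' @param var_direct Sampling variance of `direct`.
#' @param cov_direct_mediator Covariance between `direct` and the mediator
#'   coefficient (0 when the modulator is absent from the bone equation).
#' @param a Muscle-equation coefficient of the modulator.
#' @return One-row effect data.frame (`kind = "total_on_bone"`).
#' @export
#' @examples
#' ind <- indirect_effect(0.213, 0.288, 0.037^2, 0.061^2, "maturity_offset")
#' total_effect(0.241, ind, 0.052^2, 0, 0.213)$estimate  # ~0.302
total_effect <- function(direct, indirect, var_direct,
                         cov_direct_mediator = 0, a = 0) {
  stopifnot(var_direct >= 0)
  v <- var_direct + indirect$se^2 + 2 * a * cov_direct_mediator
  bm_effect_row(indirect$modulator, "total_on_bone",
                direct + indirect$estimate, sqrt(max(v, 0)))
}

# Build complete-case response/design for one equation.
bm_equation_frame <- function(table, eq, grouping, session = NULL) {
  needed <- c(eq$outcome, eq$mediator, eq$covariates)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("spec error: column(s) absent from table: ",
         paste(missing_cols, collapse = ", "))
  }
  ok <- stats::complete.cases(table[, needed, drop = FALSE])
  d <- table[ok, , drop = FALSE]
  terms <- c(if (eq$intercept) "(intercept)", eq$mediator, eq$covariates)
  X <- cbind(if (eq$intercept) rep(1, nrow(d)),
             as.matrix(d[, c(eq$mediator, eq$covariates), drop = FALSE]))
  colnames(X) <- terms
  if (nrow(d) < ncol(X) + 3) {
    stop("insufficient data: equation for '", eq$outcome, "' has ",
         nrow(d), " complete cases for ", ncol(X), " coefficients")
  }
  list(y = d[[eq$outcome]], X = X, groups = d[[grouping]],
       session = if (!is.null(session)) d[[session]],
       data = d)
}

# Pooled two-site stack: two rows per participant-session, outcome-matched
# mediator, shared coefficients.
bm_stack_sites <- function(table) {
  base_cols <- setdiff(names(table),
                       c("radial_sos", "tibial_sos", "grip_strength",
                         "knee_extension"))
  mk <- function(site, sos, med) {
    d <- as.data.frame(table)[, base_cols]
    d$bone_site <- site
    d$bone_sos <- table[[sos]]
    d$muscle_strength <- table[[med]]
    d
  }
  out <- rbind(mk("radial", "radial_sos", "grip_strength"),
               mk("tibial", "tibial_sos", "knee_extension"))
  out$session_id <- paste(out$participant_id, out$session_index, sep = ":")
  out
}

#' Fit the mediated two-equation system
#'
#' Fits the muscle equation and the bone equation of `spec`, each by
#' maximum likelihood with a participant random intercept on its own
#' complete cases, then derives every modulator's direct, muscle-path,
#' indirect and total effect. For `site = "pooled"` the radial and tibial
#' rows are stacked (two rows per session with the site-matched mediator,
#' shared coefficients) and a session-level random intercept is added, which
#' induces an exchangeable cross-outcome correlation within a session; the
#' realized within-participant cross-outcome residual correlation is also
#' reported descriptively.
#'
#' The table is expected to be standardized ([zstandardize()]) so that
#' coefficients are on the comparable z-score scale.
#'
#' @param table A standardized `bm_cohort`.
#' @param spec A `bm_model_spec`, e.g. [default_model_spec()].
#' @param stratum Label stored in the effect table (default `"all"`).
#' @param reml Use REML in both equations (default ML).
#' @param se `"delta"` (default) or `"bootstrap"`: with `"bootstrap"` the
#'   indirect-effect SEs are replaced by parametric-bootstrap SDs
#'   ([bootstrap_indirect()]).
#' @param n_boot,boot_seed Bootstrap replicates and seed (bootstrap only).
#' @return A `bm_sem`: `bone_fit`, `muscle_fit`, `effects` (long
#'   data.frame), `spec`, `n_bone`, `n_muscle`, and (pooled only)
#'   `residual_cross_correlation`.
#' @export
fit_mediated_system <- function(table, spec, stratum = "all", reml = FALSE,
                                se = c("delta", "bootstrap"), n_boot = 500,
                                boot_seed = 1L) {
  se <- match.arg(se)
  stopifnot(inherits(spec, "bm_model_spec"))
  site <- if (!is.null(spec$site)) spec$site else "custom"
  pooled <- identical(site, "pooled")
  dat <- if (pooled) bm_stack_sites(table) else as.data.frame(table)
  if (!spec$bone_equation$mediator %in% names(dat)) {
    stop("spec error: mediator '", spec$bone_equation$mediator,
         "' absent from table")
  }
  fit_eq <- function(eq) {
    fr <- bm_equation_frame(dat, eq, spec$grouping,
                            session = if (pooled) "session_id")
    fit <- if (pooled) {
      fit_nested_intercepts(fr$y, fr$X, fr$groups, fr$session, reml = reml)
    } else {
      fit_random_intercept(fr$y, fr$X, fr$groups, reml = reml)
    }
    fit$frame <- fr
    fit
  }
  muscle_fit <- fit_eq(spec$muscle_equation)
  bone_fit <- fit_eq(spec$bone_equation)

  med <- spec$bone_equation$mediator
  b <- bone_fit$coefficients[[med]]
  var_b <- bone_fit$vcov[med, med]
  zcov <- spec$bone_equation$covariates
  wcov <- spec$muscle_equation$covariates

  eff <- list()
  eff[[length(eff) + 1]] <- bm_effect_row(med, "direct_on_bone", b,
                                          sqrt(var_b))
  for (v in zcov) {
    eff[[length(eff) + 1]] <- bm_effect_row(
      v, "direct_on_bone", bone_fit$coefficients[[v]],
      sqrt(bone_fit$vcov[v, v]))
  }
  for (v in wcov) {
    a <- muscle_fit$coefficients[[v]]
    var_a <- muscle_fit$vcov[v, v]
    eff[[length(eff) + 1]] <- bm_effect_row(v, "effect_on_muscle", a,
                                            sqrt(var_a))
    ind <- indirect_effect(a, b, var_a, var_b, modulator = v)
    eff[[length(eff) + 1]] <- ind
    if (v %in% zcov) {
      eff[[length(eff) + 1]] <- total_effect(
        bone_fit$coefficients[[v]], ind, bone_fit$vcov[v, v],
        cov_direct_mediator = bone_fit$vcov[v, med], a = a)
    } else {
      tot <- ind
      tot$kind <- "total_on_bone"
      eff[[length(eff) + 1]] <- tot
    }
  }
  effects <- do.call(rbind, eff)
  effects <- cbind(data.frame(site = site, stratum = stratum,
                              stringsAsFactors = FALSE), effects)

  res <- structure(list(
    bone_fit = bone_fit, muscle_fit = muscle_fit, effects = effects,
    spec = spec, site = site, stratum = stratum,
    n_bone = bone_fit$n_obs, n_muscle = muscle_fit$n_obs,
    residual_cross_correlation = if (pooled) {
      bm_cross_outcome_correlation(bone_fit)
    }
  ), class = "bm_sem")

  if (se == "bootstrap") {
    draws <- bootstrap_indirect(res, n_boot = n_boot, seed = boot_seed)
    for (v in colnames(draws)) {
      sdv <- stats::sd(draws[, v])
      i <- which(effects$modulator == v & effects$kind == "indirect_on_bone")
      wz <- wald_z(effects$estimate[i], sdv)
      effects[i, c("se", "z", "p")] <- list(sdv, wz$z, wz$p)
      effects$stars[i] <- bm_stars(wz$p)
    }
    res$effects <- effects
  }
  res
}

# Descriptive within-participant cross-outcome residual correlation for the
# pooled stack: marginal residuals, centred within participant x site (so
# site-specific participant effects cancel), paired radial/tibial by session.
bm_cross_outcome_correlation <- function(bone_fit) {
  fr <- bone_fit$frame
  r <- fr$y - as.numeric(fr$X %*% bone_fit$coefficients)
  rc <- r - stats::ave(r, paste(fr$groups, fr$data$bone_site))
  d <- data.frame(session = fr$session, site = fr$data$bone_site, rc = rc)
  wide <- merge(d[d$site == "radial", c("session", "rc")],
                d[d$site == "tibial", c("session", "rc")], by = "session")
  if (nrow(wide) < 3) return(NA_real_)
  stats::cor(wide$rc.x, wide$rc.y)
}

#' @export
print.bm_sem <- function(x, ...) {
  cat("<bm_sem> site ", x$site, ", stratum ", x$stratum, ": n_bone ",
      x$n_bone, ", n_muscle ", x$n_muscle, "\n", sep = "")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Parametric bootstrap of the indirect effects
#'
#' Keeps both fitted designs fixed, resimulates each equation's response
#' from its fitted fixed effects and variance components (new random
#' intercepts and level-1 noise), refits both equations, and records the
#' product `a * b` per muscle-equation modulator. The SD of the draws is a
#' simulation-based alternative to the Sobel SE.
#'
#' @param sem A `bm_sem`.
#' @param n_boot Number of refits (default 500).
#' @param seed Seed for the simulation.
#' @return `n_boot x n_modulator` matrix of indirect-effect draws.
#' @export
bootstrap_indirect <- function(sem, n_boot = 500, seed = 1L) {
  set.seed(seed)
  med <- sem$spec$bone_equation$mediator
  wcov <- sem$spec$muscle_equation$covariates
  sim_refit <- function(fit) {
    n <- fit$n_obs
    g <- factor(fit$groups)
    mu <- as.numeric(fit$X %*% fit$coefficients)
    y <- mu + stats::rnorm(nlevels(g), 0, sqrt(fit$var_level2))[g] +
      stats::rnorm(n, 0, sqrt(fit$var_level1))
    if (!is.null(fit$subgroups)) {
      s <- factor(paste(fit$groups, fit$subgroups))
      y <- y + stats::rnorm(nlevels(s), 0, sqrt(fit$var_session))[s]
      fit_nested_intercepts(y, fit$X, fit$groups, fit$subgroups,
                            reml = fit$reml)
    } else {
      fit_random_intercept(y, fit$X, fit$groups, reml = fit$reml)
    }
  }
  draws <- matrix(NA_real_, n_boot, length(wcov),
                  dimnames = list(NULL, wcov))
  for (r in seq_len(n_boot)) {
    mfit <- sim_refit(sem$muscle_fit)
    bfit <- sim_refit(sem$bone_fit)
    draws[r, ] <- mfit$coefficients[wcov] * bfit$coefficients[[med]]
  }
  draws
}

#' Classify the mediation pattern of one modulator
#'
#' * `full` — the indirect effect is significant (p < 0.05) and the
#'   modulator has no significant direct bone-equation path (or none at all);
#' * `partial` — both direct and indirect effects are significant;
#' * `none` — the indirect effect is not significant.
#'
#' @param sem A `bm_sem`.
#' @param modulator Modulator name (must appear in the muscle equation).
#' @param alpha Significance level (default 0.05).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_mediation <- function(sem, modulator, alpha = 0.05) {
  ef <- sem$effects
  ind <- ef[ef$modulator == modulator & ef$kind == "indirect_on_bone", ]
  if (nrow(ind) != 1) stop("modulator '", modulator, "' has no indirect effect")
  dir <- ef[ef$modulator == modulator & ef$kind == "direct_on_bone", ]
  if (is.na(ind$p) || ind$p >= alpha) return("none")
  if (nrow(dir) == 1 && !is.na(dir$p) && dir$p < alpha) return("partial")
  "full"
}
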