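# Mixed-longitudinal synthetic cohort generator.
#
# Values are generated on the standardized scale through a shared-factor
# construction (participant-level and session-level unit-normal factors plus
# a deterministic annual trend for maturity-like variables), then mapped
# affinely to natural units. Muscle strength follows the muscle structural
# equation and bone SOS the bone structural equation, so the generator's
# truth is exactly the model the estimation modules fit. Residual variance
# components are solved so that the *realized* within/between variance
# decomposition (population divisors, per availability mask) matches the
# configured summary-table targets in expectation.

#' Default per-variable calibration (means, within/between SDs)
#'
#' Means and within/between-participant standard deviations of the measured
#' variables in a peri-pubertal mixed-longitudinal cohort (ages 8-16, annual
#' sessions). PAQ-C is treated as an arbitrary-scale score.
#'
#' @return data.frame with columns `variable`, `mean`, `sd_within`,
#'   `sd_between`.
#' @export
bm_default_calibration <- function() {
  data.frame(
    variable = c("age", "maturity_offset", "radial_sos", "tibial_sos",
                 "grip_strength", "knee_extension", "ntx", "energy_intake",
                 "waeq", "paqc", "bmi", "bone_age"),
    mean = c(11.8, -0.9, 3816.1, 3687.4, 23.4, 131.5, 539.8, 1593.4,
             73.8, 0.1, 19.5, 12.0),
    sd_within = c(1.0, 0.9, 51.4, 49.8, 3.2, 22.3, 169.9, 297.6,
                  24.8, 0.2, 1.2, 1.1),
    sd_between = c(1.5, 1.9, 86.0, 96.7, 7.0, 56.6, 213.7, 370.0,
                   32.9, 0.2, 3.6, 2.2),
    stringsAsFactors = FALSE
  )
}

#' Default true structural coefficients (standardized scale)
#'
#' Point estimates of the total-cohort mediated system used as generator
#' truth: the bone equation regresses bone SOS on muscle strength
#' (`mediator`), NTX, PAQ-C, maturity offset and BMI; the muscle equation
#' regresses muscle strength on maturity offset, BMI, bone age, WAeq and
#' energy intake.
#'
#' @return list with named numeric vectors `bone` and `muscle`.
#' @export
bm_default_coefficients <- function() {
  list(
    bone = c(mediator = 0.288, ntx = -0.184, paqc = 0.056,
             maturity_offset = 0.241, bmi = -0.178),
    muscle = c(maturity_offset = 0.213, bmi = 0.188, bone_age = 0.480,
               waeq = 0.047, energy_intake = 0.032)
  )
}

# Variables generated through the factor construction, in draw order.
bm_gen_vars <- function() {
  c("maturity_offset", "age", "bone_age", "bmi", "paqc", "waeq",
    "energy_intake", "ntx", "grip_strength", "knee_extension",
    "radial_sos", "tibial_sos")
}

#' Configure the synthetic cohort generator
#'
#' @param n_participants Number of participants (default 180).
#' @param session_count_distribution Probability vector over 1-4 annual
#'   sessions; default proportional to 36/53/72/19 participants.
#' @param sex_ratio Fraction of male participants (default 92/180).
#' @param spring_fraction Fraction of participants measured in spring
#'   sessions (default 94/180); four-session participants are necessarily
#'   spring-cohort (four spring collection years vs three fall years).
#' @param calibration Per-variable `mean`, `sd_within`, `sd_between` targets;
#'   see [bm_default_calibration()].
#' @param structural_coefficients Standardized-scale true coefficients,
#'   `list(bone = ..., muscle = ...)`; see [bm_default_coefficients()].
#' @param sex_coefficients Optional `list(male = , female = )`, each shaped
#'   like `structural_coefficients`, to generate sex-specific structural
#'   paths (used e.g. to study between-strata coefficient tests).
#' @param maturity_loading Named vector of standardized loadings of exogenous
#'   variables on maturity offset (default: bone age 0.8, the only
#'   cross-correlation the generator builds in; all other covariates are
#'   independent given maturity).
#' @param age_correlation Participant-level correlation between chronological
#'   age and maturity offset baselines (default 0.9; cosmetic, age enters no
#'   equation).
#' @param cross_site_share Fractions of the bone (and muscle) residual
#'   variance shared between the radial and tibial sites of one child, at
#'   level 2 (`level2`, participant) and level 1 (`level1`, session).
#'   Defaults `c(level2 = 0.5, level1 = 0.25)`: the two sites of the same
#'   skeleton share unmeasured participant factors, which is what the pooled
#'   two-site model's shared participant and session intercepts represent.
#' @param residual_sds Optional override of the solved residual SDs, a list
#'   `list(muscle = c(level1 = , level2 = ), bone = c(level1 = , level2 = ))`
#'   on the standardized scale. Default `NULL`: components are solved from
#'   the calibration targets.
#' @param missingness `list(grip = , ntx = , energy = )`: `grip` is either
#'   the string `"fall2010"` (all sessions of that season-year lack grip
#'   strength) or a Bernoulli rate; `ntx` and `energy` are Bernoulli
#'   per-session rates (defaults 29/434 and 0).
#' @param exclusion_counts Named counts of observations flagged for removal,
#'   in cascade order `diabetes_t1`, `fracture`, `sos_undetected`,
#'   `missed_visit` (defaults 6/8/11/3, i.e. 434 generated rows yield 406
#'   analysis rows at the default design).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `bm_cohort_config`.
#' @export
cohort_config <- function(n_participants = 180,
                          session_count_distribution = c(36, 53, 72, 19) / 180,
                          sex_ratio = 92 / 180,
                          spring_fraction = 94 / 180,
                          calibration = bm_default_calibration(),
                          structural_coefficients = bm_default_coefficients(),
                          sex_coefficients = NULL,
                          maturity_loading = c(bone_age = 0.8),
                          age_correlation = 0.9,
                          cross_site_share = c(level2 = 0.5, level1 = 0.25),
                          residual_sds = NULL,
                          missingness = list(grip = "fall2010",
                                             ntx = 29 / 434, energy = 0),
                          exclusion_counts = c(diabetes_t1 = 6, fracture = 8,
                                               sos_undetected = 11,
                                               missed_visit = 3),
                          seed = 1L) {
  p <- session_count_distribution
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("session_count_distribution must be 4 non-negative probabilities summing to 1")
  }
  if (any(calibration$sd_within < 0) || any(calibration$sd_between < 0)) {
    stop("all calibration SDs must be >= 0")
  }
  all_cf <- c(unlist(structural_coefficients), unlist(sex_coefficients))
  if (any(!is.finite(all_cf))) {
    stop("config error: structural coefficients imply non-finite variance")
  }
  rates <- c(if (is.numeric(missingness$grip)) missingness$grip,
             missingness$ntx, missingness$energy)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  if (any(abs(maturity_loading) > 1)) stop("maturity loadings must be in [-1, 1]")
  if (any(cross_site_share < 0 | cross_site_share > 1)) {
    stop("cross_site_share fractions must be in [0, 1]")
  }
  stopifnot(n_participants >= 1, sex_ratio >= 0, sex_ratio <= 1)
  structure(list(
    n_participants = as.integer(n_participants),
    session_count_distribution = p,
    sex_ratio = sex_ratio,
    spring_fraction = spring_fraction,
    calibration = calibration,
    structural_coefficients = structural_coefficients,
    sex_coefficients = sex_coefficients,
    maturity_loading = maturity_loading,
    age_correlation = age_correlation,
    cross_site_share = cross_site_share,
    residual_sds = residual_sds,
    missingness = missingness,
    exclusion_counts = exclusion_counts,
    seed = as.integer(seed)
  ), class = "bm_cohort_config")
}

# Largest-remainder allocation of n participants over the 4 session counts.
bm_allocate_counts <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# Session layout: participant-level design (sex, session count, cohort
# season, start year), one observation row per session with its centred
# trend deviation, exclusion flags, and per-variable availability masks.
bm_session_layout <- function(config) {
  n <- config$n_participants
  counts <- bm_allocate_counts(config$session_count_distribution, n)
  k <- sample(rep(1:4, counts))
  n_male <- round(config$sex_ratio * n)
  sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  spring_years <- 2010:2013
  fall_years <- 2010:2012
  season <- ifelse(stats::runif(n) < config$spring_fraction, "spring", "fall")
  season[k == 4] <- "spring"   # only the spring series has four years
  start <- integer(n)
  for (i in seq_len(n)) {
    yrs <- if (season[i] == "spring") spring_years else fall_years
    feas <- yrs[yrs <= max(yrs) - k[i] + 1]
    start[i] <- feas[if (length(feas) == 1) 1L else sample.int(length(feas), 1)]
  }
  pid <- sprintf("P%03d", seq_len(n))
  obs <- data.frame(
    pid = rep(pid, k),
    sex = rep(sex, k),
    season = rep(season, k),
    k = rep(k, k),
    session_index = sequence(k),
    stringsAsFactors = FALSE
  )
  obs$year <- rep(start, k) + obs$session_index - 1L
  obs$dev <- obs$session_index - (obs$k + 1) / 2   # centred annual trend
  N <- nrow(obs)
  # exclusion flags, cascade order, assigned before values are drawn so the
  # calibration statistics can target the analysis (post-exclusion) rows
  flag <- rep("", N)
  exc <- config$exclusion_counts
  n_flag <- sum(exc)
  if (n_flag > 0) {
    if (n_flag >= N) stop("exclusion counts exceed the number of observations")
    rows <- sample.int(N, n_flag)
    flag[rows] <- rep(bm_exclusion_reasons(), exc[bm_exclusion_reasons()])
  }
  obs$flag <- flag
  obs$retained <- flag == ""
  # missingness (MCAR within its stratum)
  mg <- config$missingness$grip
  obs$miss_grip <- if (identical(mg, "fall2010")) {
    obs$season == "fall" & obs$year == 2010
  } else {
    stats::rbinom(N, 1, mg) == 1
  }
  obs$miss_ntx <- stats::rbinom(N, 1, config$missingness$ntx) == 1
  obs$miss_energy <- stats::rbinom(N, 1, config$missingness$energy) == 1
  obs
}

# Moments of the decomposition estimators under a row mask: observation and
# participant counts, the within-pool inflation factor, mean reciprocal group
# size, and the exact contribution of the deterministic trend to the measured
# within (TSw) and between (TSb) variances.
bm_mask_stats <- function(obs, mask) {
  o <- obs[mask, , drop = FALSE]
  Ns <- nrow(o)
  if (Ns == 0) return(list(Ns = 0, Gs = 0, wf = 0, inv_n = 0, TSw = 0, TSb = 0))
  ng <- table(o$pid)
  Gs <- length(ng)
  wf <- if (Ns > Gs) Ns / (Ns - Gs) else 0
  inv_n <- mean(1 / as.numeric(ng))
  deva <- o$dev - stats::ave(o$dev, o$pid)
  md <- tapply(o$dev, o$pid, mean)
  list(Ns = Ns, Gs = Gs, wf = wf, inv_n = inv_n,
       TSw = mean(deva^2),
       TSb = mean(md^2) - mean(md)^2,
       dev_mean = mean(o$dev),
       gfac = if (Gs > 1) Gs / (Gs - 1) else 1)
}

# Solve the own-factor (residual) between/within variances of a standardized
# variable so the expected realized decomposition hits (tB, tW), given the
# variance already inherited from base factors and the trend coefficient.
bm_solve_resid <- function(tB, tW, tau, VBbase, VWbase, st, floor = 1e-4) {
  clamped <- character(0)
  VW <- if (st$wf > 0) (tW - tau^2 * st$TSw) * st$wf - VWbase else 0
  if (VW < 0) { clamped <- "within"; VW <- 0 }
  VB <- (tB - tau^2 * st$TSb) * st$gfac - (VWbase + VW) * st$inv_n - VBbase
  if (VB < floor) { clamped <- c(clamped, "between"); VB <- floor }
  list(VB = VB, VW = VW, clamped = clamped)
}

# Build the factor representation (between coefs, within coefs, trend coef,
# all on the variable's standardized scale) of every generated variable for
# one structural coefficient set.
bm_factor_reps <- function(config, stats_by_var, coefs) {
  calib <- config$calibration
  rownames(calib) <- calib$variable
  vars <- bm_gen_vars()
  bn <- c(paste0("u.", vars), "u.muscle_shared", "u.bone_shared")
  wn <- c(paste0("w.", vars), "w.muscle_shared", "w.bone_shared")
  zero_rep <- function() list(b = stats::setNames(numeric(length(bn)), bn),
                              w = stats::setNames(numeric(length(wn)), wn),
                              tau = 0)
  scale_rep <- function(r, a) list(b = r$b * a, w = r$w * a, tau = r$tau * a)
  add_rep <- function(r1, r2) list(b = r1$b + r2$b, w = r1$w + r2$w,
                                   tau = r1$tau + r2$tau)
  targets <- function(v) {
    s2 <- calib[v, "sd_between"]^2 + calib[v, "sd_within"]^2
    list(s = sqrt(s2), tB = calib[v, "sd_between"]^2 / s2,
         tW = calib[v, "sd_within"]^2 / s2)
  }
  reps <- list()
  clamped <- character(0)
  note_clamp <- function(v, cl) {
    if (length(cl)) clamped <<- c(clamped, paste0(v, ":", cl))
  }

  # maturity offset: annual trend of one year per session plus jitter
  # (a zero within-SD target means no within-participant variation at all,
  # so the trend is disabled too)
  tg <- targets("maturity_offset")
  r <- zero_rep()
  r$tau <- if (calib["maturity_offset", "sd_within"] > 0) 1 / tg$s else 0
  sol <- bm_solve_resid(tg$tB, tg$tW, r$tau, 0, 0,
                        stats_by_var[["maturity_offset"]])
  note_clamp("maturity_offset", sol$clamped)
  r$b["u.maturity_offset"] <- sqrt(sol$VB)
  r$w["w.maturity_offset"] <- sqrt(sol$VW)
  reps$maturity_offset <- r

  # chronological age: own annual trend, participant baseline correlated
  # with the maturity baseline
  tg <- targets("age")
  r <- zero_rep()
  r$tau <- if (calib["age", "sd_within"] > 0) 1 / tg$s else 0
  sol <- bm_solve_resid(tg$tB, tg$tW, r$tau, 0, 0, stats_by_var[["age"]])
  note_clamp("age", sol$clamped)
  rho <- config$age_correlation
  r$b["u.maturity_offset"] <- rho * sqrt(sol$VB)
  r$b["u.age"] <- sqrt(1 - rho^2) * sqrt(sol$VB)
  r$w["w.age"] <- sqrt(sol$VW)
  reps$age <- r

  # remaining exogenous variables: optional loading on maturity offset,
  # otherwise mutually independent
  for (v in c("bone_age", "bmi", "paqc", "waeq", "energy_intake", "ntx")) {
    tg <- targets(v)
    rho <- if (v %in% names(config$maturity_loading)) {
      config$maturity_loading[[v]]
    } else 0
    r <- scale_rep(reps$maturity_offset, rho)
    sol <- bm_solve_resid(tg$tB, tg$tW, r$tau,
                          sum(r$b^2), sum(r$w^2), stats_by_var[[v]])
    note_clamp(v, sol$clamped)
    r$b[paste0("u.", v)] <- sqrt(sol$VB)
    r$w[paste0("w.", v)] <- sqrt(sol$VW)
    reps[[v]] <- r
  }

  resid <- list()
  sh2 <- config$cross_site_share[["level2"]]
  sh1 <- config$cross_site_share[["level1"]]
  # mediators from the muscle structural equation; residuals partially
  # shared between the two muscles of one child (the Psi-style dependence)
  om <- coefs$muscle
  for (m in c("grip_strength", "knee_extension")) {
    tg <- targets(m)
    r <- zero_rep()
    for (v in names(om)) r <- add_rep(r, scale_rep(reps[[v]], om[[v]]))
    if (!is.null(config$residual_sds)) {
      sol <- list(VB = config$residual_sds$muscle[["level2"]]^2,
                  VW = config$residual_sds$muscle[["level1"]]^2,
                  clamped = character(0))
    } else {
      sol <- bm_solve_resid(tg$tB, tg$tW, r$tau,
                            sum(r$b^2), sum(r$w^2), stats_by_var[[m]])
    }
    note_clamp(m, sol$clamped)
    r$b["u.muscle_shared"] <- sqrt(sh2 * sol$VB)
    r$b[paste0("u.", m)] <- sqrt((1 - sh2) * sol$VB)
    r$w["w.muscle_shared"] <- sqrt(sh1 * sol$VW)
    r$w[paste0("w.", m)] <- sqrt((1 - sh1) * sol$VW)
    reps[[m]] <- r
    resid[[m]] <- c(level2 = sol$VB, level1 = sol$VW)
  }

  # bone SOS from the bone structural equation (site-matched mediator);
  # residuals partially shared between sites (the Sigma-style dependence)
  th <- coefs$bone
  zcov <- setdiff(names(th), "mediator")
  for (site in c("radial_sos", "tibial_sos")) {
    med <- if (site == "radial_sos") "grip_strength" else "knee_extension"
    tg <- targets(site)
    r <- scale_rep(reps[[med]], th[["mediator"]])
    for (v in zcov) r <- add_rep(r, scale_rep(reps[[v]], th[[v]]))
    if (!is.null(config$residual_sds)) {
      sol <- list(VB = config$residual_sds$bone[["level2"]]^2,
                  VW = config$residual_sds$bone[["level1"]]^2,
                  clamped = character(0))
    } else {
      sol <- bm_solve_resid(tg$tB, tg$tW, r$tau,
                            sum(r$b^2), sum(r$w^2), stats_by_var[[site]])
    }
    note_clamp(site, sol$clamped)
    r$b["u.bone_shared"] <- sqrt(sh2 * sol$VB)
    r$b[paste0("u.", site)] <- sqrt((1 - sh2) * sol$VB)
    r$w["w.bone_shared"] <- sqrt(sh1 * sol$VW)
    r$w[paste0("w.", site)] <- sqrt((1 - sh1) * sol$VW)
    reps[[site]] <- r
    resid[[site]] <- c(level2 = sol$VB, level1 = sol$VW)
  }
  list(reps = reps, clamped = clamped, resid = resid)
}

#' Generate a synthetic mixed-longitudinal cohort
#'
#' Draws a full cohort table (one row per participant-session) whose
#' statistical structure matches the configured calibration: participant
#' baselines with the configured between-SDs, session deviations with the
#' configured within-SDs (maturity-like variables advance one year per
#' annual session), muscle strength generated from the muscle structural
#' equation and bone SOS from the bone structural equation, exclusion flags
#' and missingness applied last. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return `list(table = , report = )`: the `bm_cohort` (flags still
#'   attached; apply [apply_exclusions()] to obtain the analysis rows) and a
#'   `bm_generation_report` with realized moments (computed by
#'   [variance_decomposition()] on the post-exclusion rows), realized missing
#'   counts and the seed.
#' @export
#' @examples
#' out <- generate_cohort(cohort_config(n_participants = 20, seed = 7))
#' nrow(out$table)
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "bm_cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  obs <- bm_session_layout(config)
  N <- nrow(obs)
  vars <- bm_gen_vars()
  mask_of <- function(v) {
    m <- obs$retained
    if (v == "grip_strength") m <- m & !obs$miss_grip
    if (v == "ntx") m <- m & !obs$miss_ntx
    if (v == "energy_intake") m <- m & !obs$miss_energy
    m
  }
  stats_by_var <- lapply(stats::setNames(vars, vars),
                         function(v) bm_mask_stats(obs, mask_of(v)))

  coef_sets <- if (is.null(config$sex_coefficients)) {
    list(all = config$structural_coefficients)
  } else {
    config$sex_coefficients
  }
  frs <- lapply(coef_sets, function(cf) bm_factor_reps(config, stats_by_var, cf))

  pid_levels <- unique(obs$pid)
  G <- length(pid_levels)
  pidx <- match(obs$pid, pid_levels)
  bn <- c(paste0("u.", vars), "u.muscle_shared", "u.bone_shared")
  wn <- c(paste0("w.", vars), "w.muscle_shared", "w.bone_shared")
  U <- matrix(stats::rnorm(G * length(bn)), G, length(bn),
              dimnames = list(NULL, bn))
  E <- matrix(stats::rnorm(N * length(wn)), N, length(wn),
              dimnames = list(NULL, wn))
  creatinine <- exp(stats::rnorm(N, log(9), 0.25))   # mmol, plausible urine

  calib <- config$calibration
  rownames(calib) <- calib$variable
  Z <- matrix(NA_real_, N, length(vars), dimnames = list(NULL, vars))
  for (set_name in names(frs)) {
    rows <- if (set_name == "all") rep(TRUE, N) else obs$sex == set_name
    reps <- frs[[set_name]]$reps
    for (v in vars) {
      r <- reps[[v]]
      # recentre by the mean trend deviation of the variable's availability
      # mask: missingness tied to the calendar (e.g. grip in fall 2010)
      # removes predominantly early sessions, and the mean target describes
      # the available observations
      Z[rows, v] <- (U[pidx, , drop = FALSE] %*% r$b)[rows] +
        (E %*% r$w)[rows] +
        r$tau * (obs$dev[rows] - stats_by_var[[v]]$dev_mean)
    }
  }

  df <- data.frame(
    participant_id = obs$pid,
    session_index = obs$session_index,
    season = obs$season,
    year = obs$year,
    sex = obs$sex,
    stringsAsFactors = FALSE
  )
  for (v in vars) {
    s <- sqrt(calib[v, "sd_between"]^2 + calib[v, "sd_within"]^2)
    df[[v]] <- calib[v, "mean"] + s * Z[, v]
  }
  df$creatinine <- creatinine
  df$ntx_raw <- df$ntx * df$creatinine
  df$exclusion_flags <- obs$flag
  # flag-driven nulls: undetectable SOS / incomplete second visit
  df$radial_sos[obs$flag == "sos_undetected"] <- NA
  df$radial_sos[obs$flag == "missed_visit"] <- NA
  df$tibial_sos[obs$flag == "missed_visit"] <- NA
  # missingness
  df$grip_strength[obs$miss_grip] <- NA
  df$ntx[obs$miss_ntx] <- NA
  df$ntx_raw[obs$miss_ntx] <- NA
  df$creatinine[obs$miss_ntx] <- NA
  df$energy_intake[obs$miss_energy] <- NA

  table <- new_cohort(df, source = "synthetic", seed = config$seed,
                      config_hash = bm_config_hash(config))
  analysis <- apply_exclusions(table)
  report <- structure(list(
    seed = config$seed,
    n_participants = G,
    n_obs = N,
    n_analysis = nrow(analysis$table),
    calibration = variance_decomposition(analysis$table, vars),
    missing_counts = c(
      grip_strength = sum(obs$miss_grip[obs$retained]),
      ntx = sum(obs$miss_ntx[obs$retained]),
      energy_intake = sum(obs$miss_energy[obs$retained])
    ),
    residuals = lapply(frs, `[[`, "resid"),
    clamped = unique(unlist(lapply(frs, `[[`, "clamped")))
  ), class = "bm_generation_report")
  list(table = table, report = report)
}

#' @export
print.bm_generation_report <- function(x, ...) {
  cat("<bm_generation_report> seed ", x$seed, ": ", x$n_obs,
      " observations (", x$n_analysis, " analysis rows), ",
      x$n_participants, " participants\n", sep = "")
  cat("missing:", paste(names(x$missing_counts), x$missing_counts,
                        sep = "=", collapse = ", "), "\n")
  print(x$calibration)
  invisible(x)
}

#' Named reference fixtures
#'
#' * `tiny` — 8 participants x 2 sessions, no exclusions or missingness;
#'   small enough for brute-force oracles.
#' * `study_scale` — the default 180-participant design.
#' * `null_effects` — default design with every structural path set to zero.
#'
#' @param name Fixture name.
#' @param seed Integer seed (default 1).
#' @return A `bm_cohort`.
#' @export
make_fixture <- function(name = c("tiny", "study_scale", "null_effects"),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    tiny = cohort_config(
      n_participants = 8,
      session_count_distribution = c(0, 1, 0, 0),
      missingness = list(grip = 0, ntx = 0, energy = 0),
      exclusion_counts = c(diabetes_t1 = 0, fracture = 0,
                           sos_undetected = 0, missed_visit = 0),
      seed = seed
    ),
    study_scale = cohort_config(seed = seed),
    null_effects = {
      cf <- bm_default_coefficients()
      cf$bone[] <- 0
      cf$muscle[] <- 0
      cohort_config(structural_coefficients = cf, seed = seed)
    }
  )
  generate_cohort(cfg)$table
}

# Content hash of a config (provenance metadata).
bm_config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}
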