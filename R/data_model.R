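# Longitudinal data contract: canonical variable registry, cohort table I/O,
# and the declarative two-equation model specification.

#' Canonical variable registry
#'
#' One row per canonical variable: its snake-case name (the only names the
#' model layer ever sees), a human-readable label used in rendered tables,
#' the measurement unit, and whether the column is an identifier, a measured
#' quantity, or bookkeeping. External CSV headers are mapped onto these names
#' through the `schema` argument of [read_cohort()], so file dialects never
#' leak into the models.
#'
#' @return A data.frame with columns `name`, `label`, `unit`, `role`
#'   (`id`, `measure`, `meta`) and `positive` (must non-null values be
#'   strictly positive? enforced only for scale-pinned quantities; scores
#'   and high-coefficient-of-variation markers are not enforced because
#'   calibrated synthetic values can legitimately cross zero in the tail).
#' @export
#' @examples
#' bm_variables()
bm_variables <- function() {
  data.frame(
    name = c(
      "participant_id", "session_index", "season", "year", "sex",
      "age", "maturity_offset", "bone_age", "bmi",
      "radial_sos", "tibial_sos", "grip_strength", "knee_extension",
      "ntx_raw", "creatinine", "ntx",
      "paqc", "waeq", "energy_intake", "exclusion_flags"
    ),
    label = c(
      "Participant", "Session", "Season", "Year", "Sex",
      "Age (years)", "Maturity offset (years from aPHV)", "Bone age (years)",
      "BMI (kg/m2)",
      "Radial SOS (m/s)", "Tibial SOS (m/s)", "Grip strength (kg)",
      "Knee extension (kg)",
      "NTX raw (nmol BCE)", "Creatinine (mmol)",
      "NTX (nmol BCE/mmol creatinine)",
      "PAQ-C (score)", "WAeq (MET)", "Energy intake (kcal/day)",
      "Exclusion flags"
    ),
    unit = c(
      "", "", "", "", "",
      "years", "years", "years", "kg/m2",
      "m/s", "m/s", "kg", "peak torque as recorded",
      "nmol BCE", "mmol", "nmol BCE/mmol creatinine",
      "score", "MET", "kcal/day", ""
    ),
    role = c(
      "id", "id", "id", "id", "id",
      rep("measure", 14), "meta"
    ),
    positive = c(
      rep(FALSE, 5),
      TRUE, FALSE, TRUE, TRUE,      # maturity offset may be negative
      TRUE, TRUE, FALSE, FALSE,
      FALSE, TRUE, FALSE,
      FALSE, FALSE, FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

#' The four exclusion reasons, in cascade order
#' @return Character vector of flag names.
#' @export
bm_exclusion_reasons <- function() {
  c("diabetes_t1", "fracture", "sos_undetected", "missed_visit")
}

bm_measure_names <- function() {
  reg <- bm_variables()
  reg$name[reg$role == "measure"]
}

# Construct a bm_cohort from a plain data.frame, filling absent optional
# columns with NA and attaching provenance metadata.
new_cohort <- function(df, source = "file", seed = NA_integer_,
                       config_hash = NA_character_) {
  reg <- bm_variables()
  for (v in reg$name) {
    if (!v %in% names(df)) {
      df[[v]] <- if (v == "exclusion_flags") "" else NA
    }
  }
  df <- df[, reg$name]
  df$participant_id <- as.character(df$participant_id)
  df$session_index <- as.integer(df$session_index)
  df$season <- tolower(as.character(df$season))
  df$sex <- tolower(as.character(df$sex))
  df$exclusion_flags <- ifelse(is.na(df$exclusion_flags), "",
                               as.character(df$exclusion_flags))
  for (v in bm_measure_names()) df[[v]] <- as.numeric(df[[v]])
  df$year <- as.integer(df$year)
  structure(df,
            class = c("bm_cohort", "data.frame"),
            metadata = list(source = source, seed = seed,
                            config_hash = config_hash))
}

#' Read a cohort table from CSV
#'
#' Reads a tidy participant-session table (RFC-4180 CSV, header row, UTF-8)
#' and maps its columns onto the canonical variable names of
#' [bm_variables()]. Cells that cannot be parsed as numbers become `NA` and
#' their count is reported via `message()`; missingness is first-class
#' throughout the package, never a sentinel value.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector or list mapping canonical
#'   names to the file's header names, e.g.
#'   `c(participant_id = "subj", radial_sos = "SOS_rad")`. Unmapped canonical
#'   names are looked up verbatim. A JSON file path is also accepted.
#' @return A `bm_cohort` data.frame (one row per participant-session).
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  reg <- bm_variables()
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (v in reg$name) {
    src <- if (!is.null(schema) && v %in% names(schema)) schema[[v]] else v
    if (src %in% names(raw)) out[[v]] <- raw[[src]]
  }
  if (!all(c("participant_id", "session_index") %in% names(out))) {
    stop("schema error: mandatory identifier columns ",
         "(participant_id, session_index) not found in ", path)
  }
  n_bad <- 0L
  for (v in intersect(bm_measure_names(), names(out))) {
    x <- out[[v]]
    num <- suppressWarnings(as.numeric(x))
    n_bad <- n_bad + sum(is.na(num) & !is.na(x) & trimws(as.character(x)) != "")
    out[[v]] <- num
  }
  if (n_bad > 0) message("read_cohort: ", n_bad, " unparseable cell(s) set to NA")
  key <- paste(out$participant_id, out$session_index)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (participant, session) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  new_cohort(out, source = "file")
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: canonical headers, empty cells for `NA`,
#' full double precision so a round trip is stable at the written precision.
#'
#' @param table A `bm_cohort` (or coercible data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table)
  for (v in names(df)) {
    if (is.numeric(df[[v]]) && !is.integer(df[[v]])) {
      df[[v]] <- ifelse(is.na(df[[v]]), NA,
                        format(df[[v]], digits = 17, trim = TRUE,
                               scientific = FALSE))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.bm_cohort <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("<bm_cohort> ", nrow(x), " participant-session rows, ",
      length(unique(x$participant_id)), " participants (source: ",
      md$source, ")\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Declare one structural equation
#'
#' An equation is described by its outcome, an optional mediator column (the
#' bone equations regress SOS on muscle strength; the muscle equation has
#' none), and its covariates. The fitted model always adds a participant
#' random intercept; `intercept` controls the fixed constant.
#'
#' @param outcome Canonical name of the response variable.
#' @param covariates Non-empty character vector of covariate names.
#' @param mediator Canonical name of the mediator column, or `NULL`.
#' @param intercept Include a fixed intercept? Default `TRUE`.
#' @return An object of class `bm_equation`.
#' @export
equation_spec <- function(outcome, covariates, mediator = NULL,
                          intercept = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  if (length(covariates) == 0) stop("covariates must be non-empty")
  if (!is.null(mediator) && mediator %in% covariates) {
    stop("mediator must not also be listed in covariates")
  }
  structure(list(outcome = outcome, mediator = mediator,
                 covariates = covariates, intercept = isTRUE(intercept)),
            class = "bm_equation")
}

#' Declare the two-equation mediated system
#'
#' @param bone_equation `bm_equation` for bone SOS (must name a mediator).
#' @param muscle_equation `bm_equation` whose outcome is that mediator.
#' @param grouping Level-2 unit column; default `"participant_id"`.
#' @param stratify_by Optional stratification column (e.g. `"sex"`).
#' @return An object of class `bm_model_spec`.
#' @export
model_spec <- function(bone_equation, muscle_equation,
                       grouping = "participant_id", stratify_by = NULL) {
  stopifnot(inherits(bone_equation, "bm_equation"),
            inherits(muscle_equation, "bm_equation"))
  if (is.null(bone_equation$mediator) ||
      !identical(bone_equation$mediator, muscle_equation$outcome)) {
    stop("bone equation mediator must equal the muscle equation outcome")
  }
  structure(list(bone_equation = bone_equation,
                 muscle_equation = muscle_equation,
                 grouping = grouping, stratify_by = stratify_by),
            class = "bm_model_spec")
}

#' Default model specification for a bone site
#'
#' Bone-equation covariates are NTX, PAQ-C score, maturity offset and BMI;
#' muscle-equation covariates are maturity offset, BMI, bone age, WAeq score
#' and energy intake. The mediator is grip strength for the radial model,
#' knee-extension strength for the tibial model, and the site-matched stack
#' (`muscle_strength`) for the pooled two-site model. PAQ-C carries physical
#' activity in the bone equation and WAeq in the muscle equation because the
#' two instruments capture different aspects of activity and the same column
#' cannot appear in both equations.
#'
#' @param site `"radial"`, `"tibial"` or `"pooled"`.
#' @return A `bm_model_spec`.
#' @export
#' @examples
#' default_model_spec("radial")$bone_equation$mediator  # "grip_strength"
default_model_spec <- function(site = c("radial", "tibial", "pooled")) {
  site <- match.arg(site)
  outcome <- switch(site, radial = "radial_sos", tibial = "tibial_sos",
                    pooled = "bone_sos")
  mediator <- switch(site, radial = "grip_strength",
                     tibial = "knee_extension", pooled = "muscle_strength")
  bone <- equation_spec(
    outcome = outcome, mediator = mediator,
    covariates = c("ntx", "paqc", "maturity_offset", "bmi")
  )
  muscle <- equation_spec(
    outcome = mediator,
    covariates = c("maturity_offset", "bmi", "bone_age", "waeq",
                   "energy_intake")
  )
  spec <- model_spec(bone, muscle)
  spec$site <- site
  spec
}

#' Validate a cohort table against the data contract
#'
#' Checks: unique (participant, session) pairs; strictly positive non-null
#' physical quantities (maturity offset exempt); `ntx == ntx_raw/creatinine`
#' wherever both inputs are non-null; every participant has at least one row.
#'
#' @param table A `bm_cohort`.
#' @param tol Relative tolerance for the NTX consistency check.
#' @return Invisibly `TRUE`; otherwise stops with an informative error.
#' @export
validate_cohort <- function(table, tol = 1e-6) {
  key <- paste(table$participant_id, table$session_index)
  if (anyDuplicated(key)) stop("duplicate (participant, session) pairs")
  reg <- bm_variables()
  for (v in reg$name[reg$positive]) {
    x <- table[[v]]
    if (any(!is.na(x) & x <= 0)) {
      stop("non-positive values in strictly positive column: ", v)
    }
  }
  ok <- !is.na(table$ntx_raw) & !is.na(table$creatinine) & !is.na(table$ntx)
  if (any(ok)) {
    expect <- table$ntx_raw[ok] / table$creatinine[ok]
    if (any(abs(expect - table$ntx[ok]) > tol * pmax(1, abs(expect)))) {
      stop("ntx is not ntx_raw/creatinine for some rows")
    }
  }
  invisible(TRUE)
}
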