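# Pipeline orchestration and publication-shaped output tables.

# Half-away-from-zero rounding (report presentation; base round() is
# half-even).
bm_round <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

bm_format_cell <- function(estimate, se, stars) {
  ifelse(is.na(estimate), "",
         sprintf("%.3f %s(%.3f)", bm_round(estimate, 3), stars,
                 bm_round(se, 3)))
}

#' Render a publication-shaped wide effects table
#'
#' Cells are `estimate stars(se)` at three decimals (half-away-from-zero);
#' blank where a modulator has no path of that kind (e.g. the direct bone
#' column of a muscle-only modulator).
#'
#' * `table2` — one fit (typically pooled site, whole cohort): columns for
#'   the bone equation, muscle equation, indirect and total effects.
#' * `table3` — two strata of one site (e.g. boys/girls): two column blocks.
#' * `table4` — two sites, one stratum (radial | tibial blocks).
#'
#' @param fits A `bm_sem` or list of `bm_sem` (2 for table3/table4).
#' @param layout `"table2"`, `"table3"` or `"table4"`.
#' @return data.frame with a `modulator` label column and formatted cells.
#' @export
render_table <- function(fits, layout = c("table2", "table3", "table4")) {
  layout <- match.arg(layout)
  if (inherits(fits, "bm_sem")) fits <- list(fits)
  if (layout == "table2" && length(fits) != 1) {
    stop("table2 layout needs exactly one fit")
  }
  if (layout %in% c("table3", "table4") && length(fits) != 2) {
    stop(layout, " layout needs exactly two fits")
  }
  labels <- stats::setNames(bm_variables()$label, bm_variables()$name)
  block <- function(sem) {
    ef <- sem$effects
    spec <- sem$spec
    med <- spec$bone_equation$mediator
    mods <- c(med, spec$bone_equation$covariates,
              setdiff(spec$muscle_equation$covariates,
                      spec$bone_equation$covariates))
    cell <- function(m, kind) {
      r <- ef[ef$modulator == m & ef$kind == kind, ]
      if (nrow(r) != 1) return("")
      bm_format_cell(r$estimate, r$se, r$stars)
    }
    out <- data.frame(
      modulator = ifelse(mods %in% names(labels), labels[mods], mods),
      bone = vapply(mods, cell, character(1), kind = "direct_on_bone"),
      muscle = vapply(mods, cell, character(1), kind = "effect_on_muscle"),
      indirect = vapply(mods, cell, character(1), kind = "indirect_on_bone"),
      total = vapply(mods, cell, character(1), kind = "total_on_bone"),
      stringsAsFactors = FALSE, row.names = NULL
    )
    # the mediator's own row carries only its direct bone path
    out
  }
  if (layout == "table2") return(block(fits[[1]]))
  b1 <- block(fits[[1]])
  b2 <- block(fits[[2]])
  tag <- function(sem) {
    if (layout == "table3") sem$stratum else sem$site
  }
  names(b1)[-1] <- paste(tag(fits[[1]]), names(b1)[-1], sep = ".")
  names(b2)[-1] <- paste(tag(fits[[2]]), names(b2)[-1], sep = ".")
  if (layout == "table4") {
    # sites have different mediators: align on row order, union of labels
    n <- max(nrow(b1), nrow(b2))
    merge(b1, b2, by = "modulator", all = TRUE, sort = FALSE)
  } else {
    cbind(b1, b2[match(b1$modulator, b2$modulator), -1, drop = FALSE],
          row.names = NULL)
  }
}

#' Configure a pipeline run
#'
#' @param input Path to a cohort CSV, or a [cohort_config()] (the cohort is
#'   then generated).
#' @param sites Bone sites to fit (subset of radial/tibial/pooled).
#' @param by_sex Also fit the pooled site per sex and run the Chow test?
#' @param reml Use REML in all fits.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for any stochastic step (mandatory; default 1).
#' @param schema Optional schema for [read_cohort()].
#' @return An object of class `bm_run_config`.
#' @export
run_config <- function(input, sites = c("radial", "tibial", "pooled"),
                       by_sex = TRUE, reml = FALSE, out_dir = "bonemed-out",
                       seed = 1L, schema = NULL) {
  sites <- match.arg(sites, several.ok = TRUE)
  structure(list(input = input, sites = sites, by_sex = by_sex, reml = reml,
                 out_dir = out_dir, seed = as.integer(seed), schema = schema),
            class = "bm_run_config")
}

#' Run the whole analysis pipeline
#'
#' Read or generate the cohort; apply the exclusion cascade; z-standardize
#' the analysis variables; fit the requested site models (and, optionally,
#' the pooled model per sex with a Chow test of the bone coefficients,
#' excluding none by default); write all artifacts to `out_dir`:
#' `table1.csv` (summary moments), `effects_<site>_<stratum>.csv`,
#' `table2.csv`/`table3.csv`/`table4.csv` where the needed fits exist,
#' `exclusions.json`, `chow.json`, and `manifest.json` (config echo, seed,
#' package version, input hash, per-file md5). Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, `list(fits = , chow = , exclusion_log = , table1 = ,
#'   files = )`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bm_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, json = FALSE) {
    path <- file.path(config$out_dir, name)
    if (json) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      utils::write.csv(obj, path, row.names = FALSE)
    }
    written <<- c(written, path)
    path
  }

  if (inherits(config$input, "bm_cohort_config")) {
    gen <- generate_cohort(config$input, seed = config$seed)
    table <- gen$table
    input_id <- paste0("synthetic:", attr(table, "metadata")$config_hash)
  } else {
    table <- read_cohort(config$input, schema = config$schema)
    input_id <- paste0("file:", unname(tools::md5sum(config$input)))
  }

  exc <- apply_exclusions(table)
  emit(list(initial = exc$log$initial, removed = as.list(exc$log$removed),
            final = exc$log$final), "exclusions.json", json = TRUE)

  analysis_vars <- intersect(
    c("radial_sos", "tibial_sos", "grip_strength", "knee_extension", "ntx",
      "paqc", "maturity_offset", "bmi", "bone_age", "waeq", "energy_intake"),
    names(exc$table))
  table1 <- variance_decomposition(exc$table, analysis_vars)
  emit(table1, "table1.csv")
  std <- zstandardize(exc$table, analysis_vars)

  fits <- list()
  for (site in config$sites) {
    spec <- default_model_spec(site)
    sem <- fit_mediated_system(std, spec, reml = config$reml)
    fits[[site]] <- sem
    emit(sem$effects, sprintf("effects_%s_all.csv", site))
  }
  chow <- NULL
  if (isTRUE(config$by_sex)) {
    site <- if ("pooled" %in% config$sites) "pooled" else config$sites[1]
    spec <- default_model_spec(site)
    by_sex <- lapply(c(male = "male", female = "female"), function(sx) {
      sem <- fit_mediated_system(std[std$sex == sx, , drop = FALSE], spec,
                                 stratum = sx, reml = config$reml)
      emit(sem$effects, sprintf("effects_%s_%s.csv", site, sx))
      sem
    })
    fits$male <- by_sex$male
    fits$female <- by_sex$female
    chow <- chow_test(by_sex$male, by_sex$female, equation = "bone")
    emit(list(tested_coefficients = chow$tested_coefficients,
              statistic = chow$statistic, df = chow$df, p = chow$p,
              per_coefficient = chow$per_coefficient),
         "chow.json", json = TRUE)
  }

  if ("pooled" %in% names(fits)) {
    emit(render_table(fits$pooled, "table2"), "table2.csv")
  }
  if (all(c("male", "female") %in% names(fits))) {
    emit(render_table(list(fits$male, fits$female), "table3"), "table3.csv")
  }
  if (all(c("radial", "tibial") %in% names(fits))) {
    emit(render_table(list(fits$radial, fits$tibial), "table4"), "table4.csv")
  }

  manifest <- list(
    package = "bonemed",
    version = as.character(utils::packageVersion("bonemed")),
    seed = config$seed,
    input = input_id,
    sites = config$sites,
    by_sex = config$by_sex,
    reml = config$reml,
    files = lapply(stats::setNames(written, basename(written)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, chow = chow, exclusion_log = exc$log,
                 table1 = table1,
                 files = c(written, file.path(config$out_dir,
                                              "manifest.json"))))
}
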