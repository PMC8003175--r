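# Exclusion cascade, derived variables, z-standardization and the
# within/between variance decomposition of the hierarchical data.

#' Apply the exclusion cascade
#'
#' Removes every record carrying an exclusion flag. A record carrying more
#' than one flag is removed once and attributed to the first applicable
#' reason in the fixed cascade order (type-1 diabetes, fracture,
#' undetectable SOS, missed second visit), so the log is deterministic and
#' always balances. Idempotent.
#'
#' @param table A `bm_cohort`.
#' @return `list(table = , log = )` where `log` is a `bm_exclusion_log` with
#'   `initial`, `removed` (named counts in cascade order) and `final`.
#' @export
apply_exclusions <- function(table) {
  reasons <- bm_exclusion_reasons()
  flags <- strsplit(ifelse(is.na(table$exclusion_flags), "",
                           table$exclusion_flags), "[;,[:space:]]+")
  first_reason <- vapply(flags, function(f) {
    f <- f[f %in% reasons]
    if (length(f) == 0) "" else reasons[min(match(f, reasons))]
  }, character(1))
  removed <- vapply(reasons, function(r) sum(first_reason == r), integer(1))
  keep <- first_reason == ""
  out <- table[keep, , drop = FALSE]
  out$exclusion_flags <- ""
  attr(out, "metadata") <- attr(table, "metadata")
  class(out) <- class(table)
  log <- structure(list(initial = nrow(table), removed = removed,
                        final = nrow(out)),
                   class = "bm_exclusion_log")
  stopifnot(log$initial - sum(log$removed) == log$final)
  list(table = out, log = log)
}

#' @export
print.bm_exclusion_log <- function(x, ...) {
  cat("<bm_exclusion_log> ", x$initial, " -> ", x$final, " rows (",
      paste(names(x$removed), x$removed, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Creatinine-correct NTX
#'
#' Bone-resorption marker corrected for urine concentration:
#' `ntx_raw / creatinine`, reported as nmol BCE per mmol creatinine.
#' Null-propagating; vectorized.
#'
#' @param ntx_raw NTX in nmol BCE.
#' @param creatinine Urinary creatinine in mmol; must be positive where
#'   non-null.
#' @return Corrected NTX.
#' @export
#' @examples
#' correct_ntx(100, 2)  # 50
correct_ntx <- function(ntx_raw, creatinine) {
  if (any(!is.na(creatinine) & creatinine <= 0)) {
    stop("creatinine must be positive")
  }
  ntx_raw / creatinine
}

#' Weekly leisure-time activity MET score
#'
#' Weighted sum of weekly mild/moderate/strenuous activity frequencies.
#' The default weights 3/5/9 are the Godin-Shephard instrument convention
#' and are configurable.
#'
#' @param mild,moderate,strenuous Times per week (non-negative).
#' @param met_weights Length-3 MET weights for (mild, moderate, strenuous).
#' @return MET-weighted weekly score.
#' @export
#' @examples
#' compute_waeq(2, 1, 1)  # 2*3 + 1*5 + 1*9 = 20
compute_waeq <- function(mild, moderate, strenuous, met_weights = c(3, 5, 9)) {
  stopifnot(length(met_weights) == 3)
  freq <- cbind(mild, moderate, strenuous)
  if (any(!is.na(freq) & freq < 0)) stop("activity frequencies must be >= 0")
  as.numeric(freq %*% met_weights)
}

# Population (divisor n) standard deviation.
bm_pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Z-standardize analysis variables
#'
#' Per variable: subtract the pooled mean and divide by the pooled
#' *population* SD (divisor n), computed over all non-null observations of
#' the table (standardize after exclusions, once for the whole analysis, so
#' stratum fits stay on a common scale). Nulls stay null. The affine
#' parameters are attached as `attr(, "bm_scaling")` for back-transformation.
#'
#' @param table A `bm_cohort`.
#' @param variables Character vector of columns to standardize.
#' @return The table with standardized columns and a `bm_scaling` attribute
#'   (data.frame `variable`, `mean`, `sd`).
#' @export
zstandardize <- function(table, variables) {
  scaling <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(variables)) {
    v <- variables[i]
    x <- table[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      stop("degenerate scale: column '", v,
           "' has fewer than 2 distinct non-null values")
    }
    m <- mean(x[ok])
    s <- bm_pop_sd(x)
    scaling$mean[i] <- m
    scaling$sd[i] <- s
    table[[v]] <- (x - m) / s
  }
  attr(table, "bm_scaling") <- scaling
  table
}

#' Invert [zstandardize()]
#'
#' @param table A table produced by [zstandardize()] (its `bm_scaling`
#'   attribute is used unless `scaling` is supplied).
#' @param scaling Optional scaling data.frame.
#' @return The table on the original measurement scales.
#' @export
back_transform <- function(table, scaling = attr(table, "bm_scaling")) {
  if (is.null(scaling)) stop("no scaling attached; pass `scaling`")
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    table[[v]] <- table[[v]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(table, "bm_scaling") <- NULL
  table
}

#' Within/between variance decomposition
#'
#' For each variable, over its non-null observations: the mean; the total
#' population SD; the between-participant SD (population SD of participant
#' means); and the within-participant SD (population SD, over all
#' observations, of deviations from the participant's own mean — a
#' participant observed once contributes a zero deviation). Population
#' divisors are used throughout for internal consistency with
#' [zstandardize()].
#'
#' @param table A `bm_cohort` (or data.frame with `participant_id`).
#' @param variables Columns to decompose.
#' @return A `bm_variance_decomposition` data.frame with columns `variable`,
#'   `n`, `mean`, `sd_total`, `sd_within`, `sd_between`.
#' @export
variance_decomposition <- function(table, variables) {
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    if (!any(ok)) {
      return(data.frame(variable = v, n = 0L, mean = NA_real_,
                        sd_total = NA_real_, sd_within = NA_real_,
                        sd_between = NA_real_))
    }
    x <- x[ok]
    g <- table$participant_id[ok]
    means <- tapply(x, g, mean)
    dev <- x - stats::ave(x, g)
    data.frame(
      variable = v, n = sum(ok), mean = mean(x),
      sd_total = bm_pop_sd(x),
      sd_within = sqrt(mean(dev^2)),
      sd_between = bm_pop_sd(as.numeric(means)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bm_variance_decomposition", "data.frame")
  out
}
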