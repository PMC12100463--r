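.obs_definitions <- c("reference", "noncontact_included", "intercourse_only",
                      "before_16", "before_12")
.obs_modes <- c("face_to_face", "confidential")

.obs_columns <- c("source_id", "location_id", "year", "sex", "age_start",
                  "age_end", "mean", "se", "sample_size", "definition",
                  "mode", "population_based", "representative",
                  "self_report", "extrapolated", "variance_inflation")

#' Construct a table of source-level prevalence observations
#'
#' One row per source-level datapoint: a lifetime prevalence `mean`
#' with natural-scale standard error `se` for a location, survey-period
#' midpoint `year`, `sex`, and a (possibly multi-group) age span
#' \[`age_start`, `age_end`). `definition` tags the case definition the
#' source used (`"reference"` or one of the alternative definitions
#' that the crosswalk maps onto the reference); `mode` records whether
#' the interview was face-to-face or a confidential self-report.
#'
#' Boundary means of exactly 0 or 1 are offset inward via
#' [squeeze_boundary()] so that the logit is finite.
#'
#' @param df data frame carrying the columns listed above plus the
#'   inclusion flags `population_based`, `representative`,
#'   `self_report`; missing `extrapolated` / `variance_inflation`
#'   columns default to `FALSE` / 1.
#' @return validated data frame classed `"svac_obs"`.
#' @export
observations <- function(df) {
  if (!("extrapolated" %in% names(df))) df$extrapolated <- FALSE
  if (!("variance_inflation" %in% names(df))) df$variance_inflation <- 1
  missing_cols <- setdiff(.obs_columns, names(df))
  if (length(missing_cols)) {
    stop("observation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, union(.obs_columns, names(df)), drop = FALSE]
  num <- c("year", "age_start", "age_end", "mean", "se", "variance_inflation")
  for (cl in num) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
      stop("column '", cl, "' not numeric/finite at row ", bad, call. = FALSE)
    }
  }
  bad_mean <- which(df$mean < 0 | df$mean > 1)
  if (length(bad_mean)) {
    stop("mean outside [0, 1] at row ", bad_mean[1], call. = FALSE)
  }
  df$mean <- squeeze_boundary(df$mean, df$sample_size)
  if (any(df$se <= 0)) {
    stop("se must be > 0 (row ", which(df$se <= 0)[1], ")", call. = FALSE)
  }
  if (any(df$age_end <= df$age_start)) {
    stop("age_end must exceed age_start (row ",
         which(df$age_end <= df$age_start)[1], ")", call. = FALSE)
  }
  bad_def <- setdiff(unique(df$definition), .obs_definitions)
  if (length(bad_def)) stop("unknown definition tag: ", bad_def[1], call. = FALSE)
  bad_mode <- setdiff(unique(df$mode), .obs_modes)
  if (length(bad_mode)) stop("unknown survey mode: ", bad_mode[1], call. = FALSE)
  bad_sex <- setdiff(unique(df$sex), c("female", "male"))
  if (length(bad_sex)) stop("unknown sex: ", bad_sex[1], call. = FALSE)
  if (any(df$variance_inflation < 1)) {
    stop("variance_inflation must be >= 1", call. = FALSE)
  }
  for (fl in c("population_based", "representative", "self_report", "extrapolated")) {
    df[[fl]] <- as.logical(df[[fl]])
    if (anyNA(df[[fl]])) stop("flag column '", fl, "' has NA", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("svac_obs", "data.frame")
  df
}

#' Read / write source-level observations
#'
#' CSV with columns exactly matching the observation schema
#' (snake_case, UTF-8, '.' decimal separator). `sample_size` may be
#' empty (absent).
#'
#' @param path CSV file path.
#' @param obs an observation table from [observations()].
#' @return `read_observations` returns a validated `svac_obs` table;
#'   `write_observations` returns `path` invisibly. The round trip is
#'   field-identical.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observations(df)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Source-inclusion filter
#'
#' Keeps observations that are population-based, drawn from a sample
#' representative of a national or subnational population, and based on
#' self-reported experience. Applied before any adjustment; idempotent.
#'
#' @param obs observation table.
#' @return list with `kept` (an `svac_obs` table) and `dropped` (the
#'   excluded rows with a `reason` column naming the first failed
#'   criterion).
#' @export
filter_inclusion <- function(obs) {
  reason <- rep(NA_character_, nrow(obs))
  reason[!obs$self_report] <- "self_report"
  reason[!obs$representative] <- "representative"
  reason[!obs$population_based] <- "population_based"
  keep <- is.na(reason)
  dropped <- as.data.frame(obs)[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  kept <- obs[keep, , drop = FALSE]
  class(kept) <- c("svac_obs", "data.frame")
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}

# per-observation variance on the logit scale, including the
# extrapolation inflation (delta-method SE times the inflation factor,
# squared)
obs_logit_variance <- function(obs) {
  (se_logit(obs$mean, obs$se) * obs$variance_inflation)^2
}
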