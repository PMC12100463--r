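#' Filter age-at-first-experience records
#'
#' Keeps respondents who ever experienced sexual violence, reported a
#' plausible age at first experience (present, non-negative, and not
#' greater than their current age — equality is plausible and kept),
#' and fall inside the analysis age window for their survey series
#' (DHS females 15-24 in the main analysis; VACS 13-24). The report
#' counts every exclusion reason.
#'
#' @param records microdata data frame (see [make_microdata()]).
#' @param dhs_window,vacs_window respondent-age windows per series.
#' @return list with `kept` and `report` (named exclusion counts:
#'   `never_experienced`, `missing`, `implausible`, `age_window`).
#' @export
filter_records <- function(records, dhs_window = c(15, 24),
                           vacs_window = c(13, 24)) {
  win_lo <- ifelse(records$series == "DHS", dhs_window[1], vacs_window[1])
  win_hi <- ifelse(records$series == "DHS", dhs_window[2], vacs_window[2])
  reason <- rep(NA_character_, nrow(records))
  reason[records$respondent_age < win_lo | records$respondent_age > win_hi] <-
    "age_window"
  reason[is.na(reason) & !records$ever_experienced] <- "never_experienced"
  reason[is.na(reason) & records$ever_experienced & is.na(records$age_first)] <-
    "missing"
  implaus <- !is.na(records$age_first) &
    (records$age_first < 0 | records$age_first > records$respondent_age)
  reason[is.na(reason) & implaus] <- "implausible"
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = table(factor(reason[!is.na(reason)],
                             levels = c("age_window", "never_experienced",
                                        "missing", "implausible"))))
}

#' Exclude DHS modules with high missingness
#'
#' DHS modules where strictly more than `cutoff` of ever-exposed
#' respondents are missing the age at first experience are dropped
#' entirely (missingness exactly at the cutoff retains the module).
#' VACS modules are never dropped by this rule.
#'
#' @param records microdata data frame (pre-filtering: missingness is
#'   assessed among all ever-exposed respondents of each module).
#' @param cutoff missing-fraction threshold (default 0.5).
#' @return list with `kept` (records from retained modules), `dropped`
#'   (survey ids removed) and `report` (per-module missing fractions).
#' @export
exclude_high_missingness_modules <- function(records, cutoff = 0.5) {
  ever <- records[records$ever_experienced, , drop = FALSE]
  mods <- unique(records[, c("survey_id", "series")])
  frac <- vapply(mods$survey_id, function(id) {
    e <- ever[ever$survey_id == id, , drop = FALSE]
    if (nrow(e) == 0) return(0)
    mean(is.na(e$age_first))
  }, numeric(1))
  report <- data.frame(survey_id = mods$survey_id, series = mods$series,
                       missing_fraction = frac, stringsAsFactors = FALSE)
  drop <- report$survey_id[report$series == "DHS" &
                             report$missing_fraction > cutoff]
  kept <- records[!(records$survey_id %in% drop), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = drop, report = report)
}

#' Threshold-CDF distribution of age at first experience
#'
#' For each group (sex crossed with survey series and its pooled
#' aggregate, crossed with region and the all-data aggregate), the
#' unweighted percentage of first experiences that occurred strictly
#' before ages 12, 16 and 18.
#'
#' @param records filtered microdata (see [filter_records()]).
#' @param thresholds integer age thresholds.
#' @return data frame with `sex`, `series` (including `"aggregate"`),
#'   `region` (including `"all"`), `n`, and one `pct_before_<t>`
#'   column per threshold; percentages are `NA` where `n = 0`.
#'   Monotone non-decreasing across thresholds in every row.
#' @export
compute_distribution <- function(records, thresholds = c(12, 16, 18)) {
  out <- list()
  for (sx in unique(records$sex)) {
    for (ser in c(unique(records$series[records$sex == sx]), "aggregate")) {
      for (reg in c(unique(records$region[records$sex == sx]), "all")) {
        r <- records[records$sex == sx, , drop = FALSE]
        if (ser != "aggregate") r <- r[r$series == ser, , drop = FALSE]
        if (reg != "all") r <- r[r$region == reg, , drop = FALSE]
        n <- nrow(r)
        pct <- vapply(thresholds, function(a) {
          if (n == 0) NA_real_ else 100 * sum(r$age_first < a) / n
        }, numeric(1))
        row <- data.frame(sex = sx, series = ser, region = as.character(reg),
                          n = n, stringsAsFactors = FALSE)
        row[paste0("pct_before_", thresholds)] <- as.list(pct)
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Microdata diagnostics
#'
#' Pearson correlation between respondent age and reported age at
#' first experience (per sex and series), and comparisons of
#' missing-response vs non-missing respondents among the ever exposed:
#' difference in mean respondent age, differences in the proportions
#' completing primary education and living in urban areas, and the
#' male-female difference in missingness, each with a standard error.
#' Values are reported without any decision rule.
#'
#' @param records microdata data frame (pre-filtering).
#' @return list with `correlations` (data frame: sex, series, n, r)
#'   and `missingness` (data frame: quantity, estimate, se).
#' @export
aafe_diagnostics <- function(records) {
  ever <- records[records$ever_experienced, , drop = FALSE]
  plaus <- ever[!is.na(ever$age_first) & ever$age_first >= 0 &
                  ever$age_first <= ever$respondent_age, , drop = FALSE]
  cors <- list()
  for (sx in unique(plaus$sex)) {
    for (ser in unique(plaus$series[plaus$sex == sx])) {
      p <- plaus[plaus$sex == sx & plaus$series == ser, , drop = FALSE]
      r <- if (nrow(p) >= 3 && stats::sd(p$respondent_age) > 0 &&
               stats::sd(p$age_first) > 0) {
        stats::cor(p$respondent_age, p$age_first)
      } else NA_real_
      cors[[length(cors) + 1]] <- data.frame(sex = sx, series = ser,
                                             n = nrow(p), r = r,
                                             stringsAsFactors = FALSE)
    }
  }
  miss <- is.na(ever$age_first)
  diff_mean <- function(x) {
    a <- x[miss]; b <- x[!miss]
    c(est = mean(a) - mean(b),
      se = sqrt(stats::var(a) / length(a) + stats::var(b) / length(b)))
  }
  diff_prop <- function(x) {
    a <- x[miss]; b <- x[!miss]
    pa <- mean(a); pb <- mean(b)
    c(est = pa - pb,
      se = sqrt(pa * (1 - pa) / length(a) + pb * (1 - pb) / length(b)))
  }
  male <- ever$sex == "male"
  pm <- mean(is.na(ever$age_first[male]))
  pf <- mean(is.na(ever$age_first[!male]))
  sexdiff <- c(est = pm - pf,
               se = sqrt(pm * (1 - pm) / sum(male) +
                           pf * (1 - pf) / sum(!male)))
  md <- rbind(
    data.frame(quantity = "age_missing_minus_nonmissing",
               t(diff_mean(ever$respondent_age))),
    data.frame(quantity = "primary_completed_diff",
               t(diff_prop(as.numeric(ever$completed_primary)))),
    data.frame(quantity = "urban_diff",
               t(diff_prop(as.numeric(ever$urban)))),
    data.frame(quantity = "male_minus_female_missingness", t(sexdiff)))
  names(md) <- c("quantity", "estimate", "se")
  list(correlations = do.call(rbind, cors), missingness = md)
}
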