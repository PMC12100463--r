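#' Estimate the observed age pattern of prevalence
#'
#' From observations covering a single canonical age group, computes a
#' per-sex relative-prevalence multiplier per group: the
#' inverse-variance-weighted mean prevalence in the group divided by
#' the grand weighted mean, renormalised to mean 1. Groups without data
#' are imputed at 1. Used only to apportion wide age bins, so only the
#' shape matters, not the level.
#'
#' @param obs observation table (multi-group rows are ignored).
#' @param groups canonical group table.
#' @return object of class `"svac_age_pattern"`: a data frame with
#'   `sex`, `age_start`, `rel` (positive, mean 1 per sex).
#' @export
estimate_age_pattern <- function(obs, groups = canonical_age_groups()) {
  single <- obs[(obs$age_end - obs$age_start) <= 5, , drop = FALSE]
  out <- list()
  for (sx in c("female", "male")) {
    o <- single[single$sex == sx, , drop = FALSE]
    rel <- rep(1, nrow(groups))
    if (nrow(o) >= 1 && length(unique(o$age_start)) >= 3) {
      w <- 1 / o$se^2
      grand <- sum(w * o$mean) / sum(w)
      for (g in seq_len(nrow(groups))) {
        i <- o$age_start == groups$age_start[g]
        if (any(i)) rel[g] <- (sum(w[i] * o$mean[i]) / sum(w[i])) / grand
      }
      rel <- rel / mean(rel)
    } else {
      warning("too few single-group observations for sex '", sx,
              "'; using a flat age pattern")
    }
    out[[sx]] <- data.frame(sex = sx, age_start = groups$age_start,
                            rel = rel, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("svac_age_pattern", "data.frame"))
}

#' Split a multi-group observation into canonical age groups
#'
#' A datapoint spanning several five-year groups is apportioned using
#' the estimated age pattern: `mean_g = mean_obs * rel_g / sum_G(w_g *
#' rel_g)` with population weights `w_g`. The population-weighted mean
#' of the children equals the parent mean exactly (to machine
#' precision). Each child's SE is `se_obs * sqrt(mean_g / mean_obs)`,
#' floored at `se_obs / sqrt(|G|)`, keeping roughly the parent's
#' information content.
#'
#' @param obs observation table; rows covering >= 2 canonical groups
#'   are split, others pass through.
#' @param pattern from [estimate_age_pattern()].
#' @param population a `svac_population`.
#' @param groups canonical group table.
#' @return observation table with every row on a single canonical
#'   group; split rows carry `split = TRUE`.
#' @export
age_split <- function(obs, pattern, population,
                      groups = canonical_age_groups()) {
  out <- list()
  obs$split <- FALSE
  for (i in seq_len(nrow(obs))) {
    row <- obs[i, , drop = FALSE]
    cov <- covered_age_groups(row$age_start, row$age_end, groups)
    if (nrow(cov) < 2) {
      out[[length(out) + 1]] <- row
      next
    }
    w <- vapply(cov$age_start, function(a) {
      pop_lookup(population, row$location_id, row$year, row$sex, a)
    }, numeric(1))
    w <- w / sum(w)
    rel <- pattern$rel[pattern$sex == row$sex][
      match(cov$age_start, pattern$age_start[pattern$sex == row$sex])]
    denom <- sum(w * rel)
    for (g in seq_len(nrow(cov))) {
      child <- row
      child$age_start <- cov$age_start[g]
      child$age_end <- cov$age_end[g]
      child$mean <- row$mean * rel[g] / denom
      child$se <- max(row$se * sqrt(rel[g] / denom),
                      row$se / sqrt(nrow(cov)))
      child$split <- TRUE
      out[[length(out) + 1]] <- child
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("svac_obs", "data.frame")
  res
}

#' Cohort extrapolation of lifetime prevalence
#'
#' Because the childhood exposure window closes at age 18, an adult age
#' group's reported lifetime prevalence is also an estimate for the
#' same birth cohort at other adult ages: an observation at ages 25-29
#' in 2015 is carried to ages 20-24 in 2010 and to ages 30-34 in 2020,
#' and so on in 5-year steps while the shifted year stays inside the
#' estimation window and the shifted age group inside \[20,25) ..
#' \[95,125). Copies keep the observed mean; their standard error is
#' multiplied by `se_factor` (default 2, the published inflation
#' factor), carried as `variance_inflation` so the regression stage
#' down-weights them. Observations below age 20 (or previously split
#' rows) are never extrapolated.
#'
#' @param obs observation table with single canonical-group rows.
#' @param window integer years `c(first, last)` of the estimation
#'   window.
#' @param se_factor uncertainty inflation on extrapolated copies.
#' @param max_age_start oldest age-group start eligible (default 95).
#' @return observation table containing every original row plus its
#'   extrapolated copies (`extrapolated = TRUE`).
#' @export
cohort_extrapolate <- function(obs, window = c(1990, 2023), se_factor = 2,
                               max_age_start = 95) {
  out <- list(obs)
  for (i in seq_len(nrow(obs))) {
    row <- obs[i, , drop = FALSE]
    if (row$age_start < 20) next
    if (!is.null(row$split) && isTRUE(row$split)) next
    single_group <- (row$age_end - row$age_start) == 5 ||
      (row$age_start == 95 && row$age_end == 125)   # terminal group
    if (!single_group) next
    for (k in setdiff(seq(-30, 30), 0)) {
      year <- row$year + 5 * k
      age <- row$age_start + 5 * k
      if (year < window[1] || year > window[2]) next
      if (age < 20 || age > max_age_start) next
      copy <- row
      copy$year <- year
      copy$age_start <- age
      copy$age_end <- if (age == 95) 125 else age + 5
      copy$extrapolated <- TRUE
      copy$variance_inflation <- se_factor
      out[[length(out) + 1]] <- copy
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("svac_obs", "data.frame")
  res
}
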