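# within-study pairs observed under both survey modes (same source,
# cell and definition) -> logit pairs for the disclosure model
pair_modes_within_study <- function(obs) {
  key <- interaction(obs$source_id, obs$location_id, obs$year, obs$sex,
                     obs$age_start, obs$age_end, obs$definition, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    grp <- obs[key == k, , drop = FALSE]
    ftf <- grp[grp$mode == "face_to_face", , drop = FALSE]
    conf <- grp[grp$mode == "confidential", , drop = FALSE]
    if (nrow(ftf) && nrow(conf)) {
      out[[length(out) + 1]] <- data.frame(
        logit_ftf = logit(ftf$mean[1]), logit_conf = logit(conf$mean[1]))
    }
  }
  if (!length(out)) {
    return(data.frame(logit_ftf = numeric(), logit_conf = numeric()))
  }
  do.call(rbind, out)
}

#' Run the full estimation pipeline
#'
#' Orchestrates every stage in order: source-inclusion filtering,
#' case-definition crosswalk, survey-mode disclosure correction,
#' age-splitting of wide bins, cohort extrapolation, the three ST-GPR
#' stages with posterior draws, Holt damped-trend smoothing of
#' data-sparse series, age-standardisation, aggregation up the
#' hierarchy, and (when microdata are supplied) the age-at-first-
#' experience analysis. Identical inputs and seed give identical
#' results.
#'
#' @param obs observation table ([observations()]).
#' @param hierarchy a `svac_hierarchy`.
#' @param population a `svac_population` (country level).
#' @param microdata optional microdata data frame for the
#'   age-at-first-experience analysis.
#' @param standard standard-population weights.
#' @param window estimation years `c(first, last)`.
#' @param config ST-GPR configuration ([stgpr_config()]).
#' @param crosswalk_prior named fallback offsets for definition tags
#'   with too few within-study pairs.
#' @param trim_fraction crosswalk trimming fraction.
#' @param extrapolation_se_factor SE inflation on extrapolated copies.
#' @param holt list(alpha, beta, phi, anchor) for sparse-series
#'   smoothing.
#' @param sparse_threshold flagging threshold ([flag_sparse()]).
#' @param seed integer root seed for the GP draws.
#' @param out_dir optional directory; when given, `results.csv` and
#'   `manifest.csv` are written there.
#' @return object of class `"svac_result"`: `results` (summaries per
#'   location/year/sex/age, including `age_standardised_20plus` rows
#'   for every hierarchy level), `draws`, `std_draws`, `crosswalk`,
#'   `disclosure`, `age_pattern`, `flags`, `change_20_24`, `aafe`,
#'   `manifest`.
#' @export
svac_run <- function(obs, hierarchy, population, microdata = NULL,
                     standard = read_standard_population(),
                     window = c(1990, 2023), config = stgpr_config(),
                     crosswalk_prior = NULL, trim_fraction = 0.1,
                     extrapolation_se_factor = 2,
                     holt = list(alpha = 0.3, beta = 0.1, phi = 0.9,
                                 anchor = 0),
                     sparse_threshold = 1, seed = 1, out_dir = NULL) {
  manifest <- list()
  note <- function(stage, rows) {
    manifest[[length(manifest) + 1]] <<- data.frame(stage = stage,
                                                    rows = rows)
  }
  note("input", nrow(obs))

  flt <- filter_inclusion(obs)
  obs <- flt$kept
  note("inclusion_filter", nrow(obs))

  pairs <- pair_within_study(obs)
  xwalk <- fit_crosswalk(pairs, trim_fraction = trim_fraction,
                         prior_offsets = crosswalk_prior)
  obs <- apply_crosswalk(obs, xwalk)
  note("crosswalk", nrow(obs))

  mode_pairs <- pair_modes_within_study(obs)
  disc <- fit_disclosure(mode_pairs)
  obs <- apply_disclosure(obs, disc)
  note("disclosure", nrow(obs))

  grid_ages <- sort(unique(pmin(population$age_start[population$age_start >= 15],
                                95)))
  ages <- canonical_age_groups(min(grid_ages), max(grid_ages))
  pattern <- estimate_age_pattern(obs, ages)
  obs <- age_split(obs, pattern, population, ages)
  note("age_split", nrow(obs))

  obs <- cohort_extrapolate(obs, window = window,
                            se_factor = extrapolation_se_factor,
                            max_age_start = max(ages$age_start))
  note("cohort_extrapolate", nrow(obs))

  cn <- countries(hierarchy)
  grid <- expand.grid(location_id = cn$location_id,
                      year = window[1]:window[2],
                      age_start = ages$age_start,
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s1 <- stage1_fit(obs, hierarchy, grid, config)
  s2 <- stage2_smooth(s1, obs, hierarchy, config)
  draws <- gpr_fit(s2, obs, config, seed = seed)
  note("gpr_draws", nrow(draws$grid))

  flags <- flag_sparse(obs, hierarchy, threshold = sparse_threshold)
  draws <- smooth_draws(draws, flags, alpha = holt$alpha, beta = holt$beta,
                        phi = holt$phi, anchor = holt$anchor)
  note("holt_smoothing", nrow(flags))

  std <- age_standardise(draws, standard)
  std_agg <- aggregate_locations(std, hierarchy, population)
  note("age_standardised", nrow(std_agg$grid))

  res_age <- summarise_draws(draws)
  res_age$age_label <- paste0(res_age$age_start, "-",
                              ifelse(res_age$age_start == 95, "plus",
                                     res_age$age_start + 4))
  res_std <- summarise_draws(std_agg)
  res_std$age_start <- NA_real_
  cols <- c("location_id", "year", "sex", "age_label", "mean", "lower", "upper")
  results <- rbind(res_age[, cols], res_std[, cols])
  change <- change_over_time(draws, window[1], window[2], age_start = 20)

  aafe <- NULL
  if (!is.null(microdata)) {
    mods <- exclude_high_missingness_modules(microdata)
    frec <- filter_records(mods$kept)
    aafe <- list(distribution = compute_distribution(frec$kept),
                 exclusions = frec$report,
                 modules = mods$report,
                 diagnostics = aafe_diagnostics(microdata))
    note("aafe_records", nrow(frec$kept))
  }

  out <- structure(list(results = results, draws = draws,
                        std_draws = std_agg, crosswalk = xwalk,
                        disclosure = disc, age_pattern = pattern,
                        flags = flags, change_20_24 = change, aafe = aafe,
                        manifest = do.call(rbind, manifest), seed = seed),
                   class = "svac_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(out$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.svac_result <- function(x, ...) {
  cat("SVAC prevalence estimation results\n")
  print(x$manifest, row.names = FALSE)
  g <- x$results[x$results$age_label == "age_standardised_20plus" &
                   x$results$location_id == 1, , drop = FALSE]
  g <- g[g$year == max(g$year), , drop = FALSE]
  if (nrow(g)) {
    cat("\nGlobal age-standardised prevalence (ages 20+),",
        max(g$year), ":\n")
    for (i in seq_len(nrow(g))) {
      cat(sprintf("  %-6s %.1f%% (95%% UI %.1f-%.1f)\n", g$sex[i],
                  100 * g$mean[i], 100 * g$lower[i], 100 * g$upper[i]))
    }
  }
  invisible(x)
}

#' @export
summary.svac_result <- function(object, ...) object$results
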