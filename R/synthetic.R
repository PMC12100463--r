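#' Synthetic study designs
#'
#' The generator builds (i) a known truth surface of logit lifetime
#' prevalence on a desk-scale grid, (ii) source-level observations with
#' the bias structure the pipeline must undo (alternative case
#' definitions with fixed logit offsets, a face-to-face disclosure gap,
#' wide age bins, data-free countries), and (iii) survey microdata for
#' the age-at-first-experience analysis. Every draw is recorded in a
#' ledger so recovery tests can compute their target quantities without
#' running the pipeline.
#'
#' Lifetime exposure is accrued entirely before age 18, so the true
#' surface is constant within a birth cohort once the cohort is past
#' the childhood window: `eta` depends on (country, sex, cohort =
#' year - age_start) for all age groups from \[20,25) upward, exactly.
#' The youngest modelled group \[15,20) sits partly inside the window
#' and carries a negative offset (exposure not yet complete).
#'
#' @param n_countries,n_regions,n_super_regions grid size; defaults are
#'   the desk-scale grid (12 countries, 3 regions, 2 super-regions).
#' @param years modelled calendar years.
#' @param age_max_start start of the oldest modelled age group.
#' @return `truth_config()` returns a config list; see individual
#'   fields in the function body.
#' @export
truth_config <- function(n_countries = 12, n_regions = 3, n_super_regions = 2,
                         years = 1990:2023, age_max_start = 65) {
  list(
    n_countries = n_countries,
    n_regions = n_regions,
    n_super_regions = n_super_regions,
    years = years,
    age_groups = canonical_age_groups(15, age_max_start),
    mu0 = logit(0.18),          # global intercept, female reference
    sex_offset = -0.35,         # male minus female, logit scale
    sd_super = 0.30,            # random-intercept SDs by level
    sd_region = 0.25,
    sd_country = 0.20,
    cohort_slope = 0.30,        # smooth trend across birth cohorts
    cohort_amp = 0.20,
    young_offset = -0.25        # [15,20): childhood window incomplete
  )
}

#' Build a synthetic location hierarchy
#'
#' Countries are assigned round-robin to regions, regions to
#' super-regions, under a single global root.
#'
#' @inheritParams truth_config
#' @return a `svac_hierarchy`.
#' @export
synthetic_hierarchy <- function(n_countries = 12, n_regions = 3,
                                n_super_regions = 2) {
  sr_ids <- 10 + seq_len(n_super_regions)
  r_ids <- 100 + seq_len(n_regions)
  c_ids <- 1000 + seq_len(n_countries)
  nodes <- rbind(
    data.frame(location_id = 1, name = "Global", level = "global",
               parent_id = NA, stringsAsFactors = FALSE),
    data.frame(location_id = sr_ids,
               name = paste("Super-region", seq_along(sr_ids)),
               level = "super_region", parent_id = 1),
    data.frame(location_id = r_ids,
               name = paste("Region", seq_along(r_ids)),
               level = "region",
               parent_id = sr_ids[(seq_along(r_ids) - 1) %% n_super_regions + 1]),
    data.frame(location_id = c_ids,
               name = paste("Country", seq_along(c_ids)),
               level = "country",
               parent_id = r_ids[(seq_along(c_ids) - 1) %% n_regions + 1])
  )
  location_hierarchy(nodes)
}

# smooth trend over birth cohorts; centred near cohort 1970
cohort_curve <- function(cohort, config) {
  config$cohort_slope * (cohort - 1970) / 40 +
    config$cohort_amp * sin((cohort - 1970) / 15)
}

#' Generate the known truth surface
#'
#' @param config from [truth_config()].
#' @param seed integer seed; the surface is deterministic given
#'   (config, seed).
#' @return an object of class `"svac_truth"`: a list with the grid
#'   (`eta` per country-year-age-sex), the hierarchy, a population
#'   table, and the drawn random-effect components.
#' @export
make_truth <- function(config = truth_config(), seed = 1) {
  hier <- synthetic_hierarchy(config$n_countries, config$n_regions,
                              config$n_super_regions)
  cn <- countries(hier)
  set.seed(seed)
  u_super <- stats::setNames(stats::rnorm(config$n_super_regions, 0, config$sd_super),
                             hier$location_id[hier$level == "super_region"])
  u_region <- stats::setNames(stats::rnorm(config$n_regions, 0, config$sd_region),
                              hier$location_id[hier$level == "region"])
  u_country <- stats::setNames(stats::rnorm(config$n_countries, 0, config$sd_country),
                               cn$location_id)
  grid <- expand.grid(location_id = cn$location_id, year = config$years,
                      age_start = config$age_groups$age_start,
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_end <- config$age_groups$age_end[match(grid$age_start,
                                                  config$age_groups$age_start)]
  cohort <- grid$year - grid$age_start
  eta <- config$mu0 +
    config$sex_offset * (grid$sex == "male") +
    u_super[as.character(cn$super_region_id[match(grid$location_id, cn$location_id)])] +
    u_region[as.character(cn$region_id[match(grid$location_id, cn$location_id)])] +
    u_country[as.character(grid$location_id)] +
    cohort_curve(cohort, config) +
    config$young_offset * (grid$age_start == 15)
  grid$eta <- as.numeric(eta)

  # populations: country scale factor, gentle decline with age, flat in
  # time; parents aggregate children by construction downstream
  pop_scale <- stats::setNames(exp(stats::rnorm(config$n_countries, log(1e6), 0.4)),
                               cn$location_id)
  popgrid <- grid[, c("location_id", "year", "sex", "age_start")]
  idx <- age_group_index(popgrid$age_start, config$age_groups)
  popgrid$population <- round(pop_scale[as.character(popgrid$location_id)] *
                                0.95^idx / 20)
  structure(list(grid = grid, hierarchy = hier,
                 population = population_table(popgrid),
                 components = list(u_super = u_super, u_region = u_region,
                                   u_country = u_country),
                 config = config, seed = seed),
            class = "svac_truth")
}

#' @export
print.svac_truth <- function(x, ...) {
  cat("Synthetic truth surface:", nrow(x$grid), "cells (",
      x$config$n_countries, "countries x", length(x$config$years),
      "years x", nrow(x$config$age_groups), "age groups x 2 sexes )\n")
  invisible(x)
}

# look up true eta; for spans covering several groups, the
# population-weighted prevalence of covered groups, on logit scale
truth_eta <- function(truth, location_id, year, sex, age_start, age_end = age_start + 5) {
  g <- truth$grid
  cov <- covered_age_groups(age_start, age_end, truth$config$age_groups)
  i <- g$location_id == location_id & g$year == year & g$sex == sex &
    g$age_start %in% cov$age_start
  p <- truth$population
  j <- p$location_id == location_id & p$year == year & p$sex == sex &
    p$age_start %in% cov$age_start
  w <- p$population[j][match(g$age_start[i], p$age_start[j])]
  logit(sum(expit(g$eta[i]) * w) / sum(w))
}

#' Observation design for the synthetic generator
#'
#' Field defaults are the generator's study conditions: roughly eight
#' sources per country with three data-free countries, a majority of
#' sources using the reference case definition, 30% face-to-face
#' interviews with a logit disclosure gap of -0.3, logit sampling-noise
#' SD 0.12, and the published definition offsets used as generator
#' truth.
#'
#' @param sources_per_country expected source count per country with data.
#' @param n_data_free number of countries that receive no observations.
#' @param p_definition named probabilities over definition tags.
#' @param p_face_to_face probability an observation is face-to-face.
#' @param p_multi_age probability an observation spans 2-3 age groups.
#' @param p_pair probability an alternative-definition observation has
#'   a matched reference-definition twin in the same cell (crosswalk
#'   pairs).
#' @param noise_sd sampling-noise SD on the logit scale.
#' @param offsets true logit offsets per alternative definition.
#' @param mode_gap true face-to-face logit offset (negative:
#'   under-disclosure).
#' @param p_exclude probability an observation fails one (randomly
#'   chosen) inclusion criterion.
#' @return design list.
#' @export
observation_design <- function(sources_per_country = 12,
                               n_data_free = 3,
                               p_definition = c(reference = 0.55,
                                                noncontact_included = 0.15,
                                                intercourse_only = 0.10,
                                                before_16 = 0.10,
                                                before_12 = 0.10),
                               p_face_to_face = 0.3,
                               p_multi_age = 0.15,
                               p_pair = 0.5,
                               noise_sd = 0.12,
                               offsets = c(noncontact_included = 0.434,
                                           intercourse_only = -0.426,
                                           before_16 = -0.455,
                                           before_12 = -1.279),
                               mode_gap = -0.3,
                               p_exclude = 0) {
  stopifnot(abs(sum(p_definition) - 1) < 1e-8, noise_sd >= 0,
            p_face_to_face >= 0, p_face_to_face <= 1)
  as.list(environment())
}

#' Sample source-level observations from the truth surface
#'
#' Each observation's mean is `expit(eta + definition offset + mode
#' offset + noise)`; its reported natural-scale `se` is consistent with
#' the logit noise SD via the delta method. The returned ledger records
#' the true `eta` and every applied offset per row, plus the inclusion
#' flag corruption, so recovery tests have exact targets.
#'
#' @param truth from [make_truth()].
#' @param design from [observation_design()].
#' @param seed integer seed.
#' @return list with `obs` (a `svac_obs` table) and `ledger` (one row
#'   per observation: eta_true, def_offset, mode_offset, noise,
#'   excluded_reason).
#' @export
sample_observations <- function(truth, design = observation_design(), seed = 2) {
  set.seed(seed)
  cn <- countries(truth$hierarchy)
  n_c <- nrow(cn)
  data_free <- if (design$n_data_free > 0) {
    cn$location_id[sample.int(n_c, design$n_data_free)]
  } else numeric(0)
  with_data <- setdiff(cn$location_id, data_free)
  ag <- truth$config$age_groups
  years <- truth$config$years
  rows <- list(); led <- list(); k <- 0
  for (loc in with_data) {
    n_src <- max(1, stats::rpois(1, design$sources_per_country))
    for (s in seq_len(n_src)) {
      sid <- paste0("src_", loc, "_", s)
      year <- sample(years, 1)
      sex <- sample(c("female", "male"), 1)
      multi <- stats::runif(1) < design$p_multi_age
      gi <- sample.int(nrow(ag), 1)
      span <- if (multi) min(sample(2:3, 1), nrow(ag) - gi + 1) else 1
      age_start <- ag$age_start[gi]
      age_end <- ag$age_end[gi + span - 1]
      def <- sample(names(design$p_definition), 1, prob = design$p_definition)
      mode <- if (stats::runif(1) < design$p_face_to_face) "face_to_face" else "confidential"
      emit <- function(sid, def, mode) {
        k <<- k + 1
        eta <- truth_eta(truth, loc, year, sex, age_start, age_end)
        d_off <- if (def == "reference") 0 else design$offsets[[def]]
        m_off <- if (mode == "face_to_face") design$mode_gap else 0
        noise <- stats::rnorm(1, 0, design$noise_sd)
        m <- expit(eta + d_off + m_off + noise)
        se <- max(design$noise_sd, 1e-3) * m * (1 - m)
        excl <- NA_character_
        if (stats::runif(1) < design$p_exclude) {
          excl <- sample(c("population_based", "representative", "self_report"), 1)
        }
        rows[[k]] <<- data.frame(
          source_id = sid, location_id = loc, year = year, sex = sex,
          age_start = age_start, age_end = age_end, mean = m, se = se,
          sample_size = round(m * (1 - m) / se^2),
          definition = def, mode = mode,
          population_based = !identical(excl, "population_based"),
          representative = !identical(excl, "representative"),
          self_report = !identical(excl, "self_report"),
          extrapolated = FALSE, variance_inflation = 1,
          stringsAsFactors = FALSE)
        led[[k]] <<- data.frame(
          source_id = sid, location_id = loc, year = year, sex = sex,
          age_start = age_start, age_end = age_end,
          eta_true = eta, def_offset = d_off, mode_offset = m_off,
          noise = noise, definition = def, mode = mode,
          excluded_reason = if (is.na(excl)) "" else excl,
          stringsAsFactors = FALSE)
      }
      emit(sid, def, mode)
      # matched within-study twin under the reference definition (and,
      # for face-to-face sources, a confidential twin) for crosswalk /
      # disclosure fitting
      if (def != "reference" && stats::runif(1) < design$p_pair) {
        emit(sid, "reference", mode)
      }
      if (mode == "face_to_face" && stats::runif(1) < design$p_pair) {
        emit(sid, def, "confidential")
      }
    }
  }
  obs <- observations(do.call(rbind, rows))
  ledger <- do.call(rbind, led)
  ledger$data_free <- FALSE
  attr(ledger, "data_free_countries") <- data_free
  list(obs = obs, ledger = ledger, data_free = data_free)
}

#' Microdata design for the age-at-first-experience generator
#'
#' @param n_per_module respondents per survey module.
#' @param n_dhs_modules,n_vacs_modules module counts (DHS samples
#'   females only; VACS samples both sexes).
#' @param p_ever named lifetime-exposure probability by sex.
#' @param beta_shape age-at-first distribution: a Beta over ages 5-23,
#'   discretised to integer years, parameters per sex.
#' @param missing_base,missing_male_excess probability a reported age
#'   is masked to missing; males get the excess added.
#' @param implausible_rate probability a non-missing reported age is
#'   corrupted to an implausible value (negative, or greater than the
#'   respondent's age).
#' @param n_high_missing_dhs number of DHS modules whose missingness is
#'   raised to `high_missing_rate` (they should be excluded by the
#'   >50% rule).
#' @param high_missing_rate missingness rate in those modules.
#' @return design list.
#' @export
microdata_design <- function(n_per_module = 500,
                             n_dhs_modules = 10, n_vacs_modules = 6,
                             p_ever = c(female = 0.25, male = 0.20),
                             beta_shape = list(female = c(4, 3), male = c(4.5, 3)),
                             missing_base = 0.15, missing_male_excess = 0.10,
                             implausible_rate = 0.02,
                             n_high_missing_dhs = 0, high_missing_rate = 0.7) {
  as.list(environment())
}

# discretised Beta pmf for age at first experience over integer ages
# 5..23, truncated at the respondent's age and renormalised
aafe_pmf <- function(shape, max_age = 23) {
  ages <- 5:23
  u <- (ages - 5) / 19; v <- (ages + 1 - 5) / 19
  p <- stats::pbeta(v, shape[1], shape[2]) - stats::pbeta(u, shape[1], shape[2])
  p <- p[ages <= max_age]
  p / sum(p)
}

#' Exact design CDF of age at first experience
#'
#' The marginal P(age_first < threshold) implied by the design,
#' averaging the truncated per-respondent-age distributions over the
#' series' uniform respondent-age window. This is the oracle the
#' threshold-CDF recovery tests compare against.
#'
#' @param design from [microdata_design()].
#' @param sex `"female"` or `"male"`.
#' @param series `"DHS"` (ages 15-49) or `"VACS"` (ages 13-24).
#' @param threshold integer age threshold.
#' @param age_window optional respondent-age restriction applied on top
#'   of the series window (e.g. `c(15, 24)` for the main DHS analysis).
#' @return probability in \[0, 1\].
#' @export
aafe_design_cdf <- function(design, sex, series, threshold,
                            age_window = NULL) {
  win <- if (series == "DHS") c(15, 49) else c(13, 24)
  if (!is.null(age_window)) {
    win <- c(max(win[1], age_window[1]), min(win[2], age_window[2]))
  }
  ages <- win[1]:win[2]
  shape <- design$beta_shape[[sex]]
  mean(vapply(ages, function(a) {
    pm <- aafe_pmf(shape, max_age = min(a, 23))
    sup <- 5:min(a, 23)
    sum(pm[sup < threshold])
  }, numeric(1)))
}

#' Generate survey microdata with known ground truth
#'
#' Respondent ages are uniform over the series window (DHS females
#' 15-49; VACS both sexes 13-24). Ever-exposed respondents receive a
#' true age at first experience from the design distribution truncated
#' at their current age; the observed field is then masked to missing
#' (with a male excess) or corrupted to an implausible value per the
#' design. The ledger keeps the uncorrupted values.
#'
#' @param truth from [make_truth()] (supplies countries/regions).
#' @param design from [microdata_design()].
#' @param seed integer seed.
#' @return list with `records` (data frame: survey_id, series, country,
#'   region, sex, respondent_age, ever_experienced, age_first,
#'   completed_primary, urban) and `ledger` (adds age_first_true,
#'   masked, implausible).
#' @export
make_microdata <- function(truth, design = microdata_design(), seed = 3) {
  set.seed(seed)
  cn <- countries(truth$hierarchy)
  mk_module <- function(survey_id, series, country, sexes, miss_rate_override = NA) {
    n <- design$n_per_module
    sex <- sample(sexes, n, replace = TRUE)
    win <- if (series == "DHS") c(15, 49) else c(13, 24)
    age <- sample(win[1]:win[2], n, replace = TRUE)
    ever <- stats::runif(n) < design$p_ever[sex]
    age_first_true <- rep(NA_integer_, n)
    for (i in which(ever)) {
      pm <- aafe_pmf(design$beta_shape[[sex[i]]], max_age = min(age[i], 23))
      sup <- 5:min(age[i], 23)
      age_first_true[i] <- sample(sup, 1, prob = pm)
    }
    p_miss <- ifelse(sex == "male",
                     design$missing_base + design$missing_male_excess,
                     design$missing_base)
    if (!is.na(miss_rate_override)) p_miss <- rep(miss_rate_override, n)
    masked <- ever & stats::runif(n) < p_miss
    implaus <- ever & !masked & stats::runif(n) < design$implausible_rate
    age_first <- age_first_true
    age_first[masked] <- NA_integer_
    for (i in which(implaus)) {
      age_first[i] <- if (stats::runif(1) < 0.5) -1L else age[i] + sample(1:5, 1)
    }
    rec <- data.frame(
      survey_id = survey_id, series = series, country = country,
      region = cn$region_id[match(country, cn$location_id)],
      sex = sex, respondent_age = age, ever_experienced = ever,
      age_first = age_first,
      completed_primary = stats::runif(n) < 0.6,
      urban = stats::runif(n) < 0.45,
      stringsAsFactors = FALSE)
    led <- cbind(rec[, c("survey_id", "series", "country", "sex",
                         "respondent_age", "ever_experienced")],
                 age_first_true = age_first_true,
                 masked = masked, implausible = implaus)
    list(rec = rec, led = led)
  }
  out <- list()
  hi <- seq_len(design$n_high_missing_dhs)
  for (m in seq_len(design$n_dhs_modules)) {
    ctry <- cn$location_id[(m - 1) %% nrow(cn) + 1]
    out[[length(out) + 1]] <- mk_module(
      sprintf("DHS_%02d", m), "DHS", ctry, "female",
      miss_rate_override = if (m %in% hi) design$high_missing_rate else NA)
  }
  for (m in seq_len(design$n_vacs_modules)) {
    ctry <- cn$location_id[(m - 1) %% nrow(cn) + 1]
    out[[length(out) + 1]] <- mk_module(
      sprintf("VACS_%02d", m), "VACS", ctry, c("female", "male"))
  }
  list(records = do.call(rbind, lapply(out, `[[`, "rec")),
       ledger = do.call(rbind, lapply(out, `[[`, "led")))
}

#' Simulate standalone crosswalk pairs
#'
#' Within-study logit differences `d = logit(mean_alt) -
#' logit(mean_ref)` drawn around the design's true definition offsets,
#' with an optional fraction of outlier pairs shifted by
#' `outlier_shift` (these are what the trimming step must discard).
#'
#' @param n_per_tag pairs per alternative-definition tag.
#' @param offsets named true logit offsets.
#' @param noise_sd SD of `d` around its true offset.
#' @param outlier_frac fraction of pairs shifted by `outlier_shift`.
#' @param outlier_shift logit shift applied to outlier pairs.
#' @param seed integer seed.
#' @return data frame with columns `tag`, `d`, `se`, `is_outlier`.
#' @export
simulate_crosswalk_pairs <- function(n_per_tag = 500,
                                     offsets = c(noncontact_included = 0.434,
                                                 intercourse_only = -0.426,
                                                 before_16 = -0.455,
                                                 before_12 = -1.279),
                                     noise_sd = 0.1, outlier_frac = 0.1,
                                     outlier_shift = 3, seed = 9) {
  set.seed(seed)
  out <- lapply(names(offsets), function(tag) {
    # exactly the stated fraction of outliers, at random positions
    is_out <- rep(FALSE, n_per_tag)
    is_out[sample.int(n_per_tag, round(outlier_frac * n_per_tag))] <- TRUE
    d <- offsets[[tag]] + stats::rnorm(n_per_tag, 0, noise_sd) +
      outlier_shift * is_out
    data.frame(tag = tag, d = d, se = noise_sd, is_outlier = is_out,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate paired-mode studies for the disclosure model
#'
#' Each study observes the same population twice: a confidential
#' self-report at the true logit prevalence and a face-to-face
#' interview shifted by `gap` (< 0: under-disclosure), both with
#' independent logit-scale noise.
#'
#' @param n number of paired studies.
#' @param gap true face-to-face logit offset.
#' @param noise_sd logit noise SD per arm.
#' @param seed integer seed.
#' @return data frame with `logit_true`, `logit_ftf`, `logit_conf`.
#' @export
simulate_mode_pairs <- function(n = 50, gap = -0.3, noise_sd = 0.05, seed = 13) {
  set.seed(seed)
  x <- stats::runif(n, logit(0.05), logit(0.45))
  data.frame(logit_true = x,
             logit_ftf = x + gap + stats::rnorm(n, 0, noise_sd),
             logit_conf = x + stats::rnorm(n, 0, noise_sd))
}

#' Write a full synthetic study to disk
#'
#' Generates truth, observations and microdata from one root seed
#' (substreams `seed+1`, `seed+2`, `seed+3`) and writes
#' `observations.csv`, `microdata.csv`, `truth.csv`, `ledger.csv` and
#' `population.csv` into `out_dir`.
#'
#' @param config from [truth_config()].
#' @param seed root integer seed.
#' @param out_dir output directory (created if needed).
#' @param obs_design,micro_design generator designs.
#' @return invisibly, the list of generated objects.
#' @export
svac_simulate <- function(config = truth_config(), seed = 1, out_dir,
                          obs_design = observation_design(),
                          micro_design = microdata_design()) {
  truth <- make_truth(config, seed + 1)
  samp <- sample_observations(truth, obs_design, seed + 2)
  micro <- make_microdata(truth, micro_design, seed + 3)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_observations(samp$obs, file.path(out_dir, "observations.csv"))
  utils::write.csv(micro$records, file.path(out_dir, "microdata.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(truth$grid, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(samp$ledger, file.path(out_dir, "ledger.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(truth$population),
                   file.path(out_dir, "population.csv"), row.names = FALSE)
  invisible(list(truth = truth, observations = samp, microdata = micro))
}
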