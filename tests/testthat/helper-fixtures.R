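# shared fixtures, built once per test run

published_offsets <- c(noncontact_included = 0.434, intercourse_only = -0.426,
                       before_16 = -0.455, before_12 = -1.279)

# quick observation-table builder with recycling
make_obs <- function(n = 1, mean = 0.2, se = 0.02, location_id = 1001,
                     year = 2010, sex = "female", age_start = 20,
                     age_end = age_start + 5, definition = "reference",
                     mode = "confidential", source_id = NULL,
                     population_based = TRUE, representative = TRUE,
                     self_report = TRUE, sample_size = 1000) {
  if (is.null(source_id)) source_id <- paste0("s", seq_len(n))
  observations(data.frame(
    source_id = rep_len(source_id, n), location_id = rep_len(location_id, n),
    year = rep_len(year, n), sex = rep_len(sex, n),
    age_start = rep_len(age_start, n), age_end = rep_len(age_end, n),
    mean = rep_len(mean, n), se = rep_len(se, n),
    sample_size = rep_len(sample_size, n),
    definition = rep_len(definition, n), mode = rep_len(mode, n),
    population_based = rep_len(population_based, n),
    representative = rep_len(representative, n),
    self_report = rep_len(self_report, n),
    stringsAsFactors = FALSE))
}

# flat population over a grid
make_population <- function(location_id = 1001, years = 1990:2023,
                            age_starts = seq(15, 65, 5), value = 1000) {
  g <- expand.grid(location_id = location_id, year = years,
                   sex = c("female", "male"), age_start = age_starts,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$population <- value
  population_table(g)
}

# bare logit surface for stage-2 / GP tests
make_surface <- function(value = -1.5, location_id = 1001,
                         years = 1990:2023, age_starts = 20,
                         sexes = "female") {
  g <- expand.grid(location_id = location_id, year = years,
                   age_start = age_starts, sex = sexes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$value <- rep_len(value, nrow(g))
  structure(g, class = c("svac_surface", "data.frame"), stage = "stage2")
}

# small draw surface
make_draws <- function(draws_matrix, location_id = 1001, years = NULL,
                       age_start = 20, sex = "female") {
  if (is.null(years)) years <- seq_len(nrow(draws_matrix)) + 1989
  g <- data.frame(location_id = location_id, year = years,
                  age_start = age_start, sex = sex)
  structure(list(grid = g, draws = draws_matrix,
                 n_draws = ncol(draws_matrix)),
            class = "svac_draws")
}

# one shared synthetic study for the heavier tests, built lazily
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    truth <- make_truth(truth_config(), seed = 101)
    samp <- sample_observations(truth, observation_design(), seed = 102)
    .shared$sim <- list(truth = truth, samp = samp)
  }
  .shared$sim
}

# independent dense-matrix GP conditioning oracle (kept separate from
# the implementation on purpose)
gp_oracle <- function(years, prior_mean, obs_years, obs_y, obs_var, amp, scale) {
  kern <- function(a, b) {
    r <- sqrt(3) * abs(outer(a, b, "-")) / scale
    amp^2 * (1 + r) * exp(-r)
  }
  if (length(obs_years) == 0) {
    return(list(mean = prior_mean, var = diag(kern(years, years))))
  }
  Koo <- kern(obs_years, obs_years) + diag(obs_var, length(obs_years))
  Kxo <- kern(years, obs_years)
  mo <- prior_mean[match(obs_years, years)]
  list(mean = as.numeric(prior_mean + Kxo %*% solve(Koo, obs_y - mo)),
       var = diag(kern(years, years) - Kxo %*% solve(Koo, t(Kxo))))
}
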