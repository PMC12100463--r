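std2 <- standard_population(data.frame(age_start = c(20, 25),
                                       weight = c(0.5, 0.5)))

# draws for two age groups at one location-year
two_group_draws <- function(p20, p25, n_draws = 10) {
  g <- expand.grid(location_id = 1001, year = 2010, age_start = c(20, 25),
                   sex = "female", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  structure(list(grid = g,
                 draws = rbind(matrix(p20, 1, n_draws),
                               matrix(p25, 1, n_draws)),
                 n_draws = n_draws),
            class = "svac_draws")
}

test_that("age-standardisation satisfies its arithmetic identities", {
  eq <- age_standardise(two_group_draws(0.2, 0.2), std2)
  expect_equal(as.numeric(eq$draws), rep(0.2, 10))   # constancy

  ws <- age_standardise(two_group_draws(0.1, 0.3), std2)
  expect_equal(as.numeric(ws$draws), rep(0.2, 10))   # 0.5*0.1 + 0.5*0.3

  # uniform weights equal the unweighted mean over groups
  skew <- standard_population(data.frame(age_start = c(20, 25),
                                         weight = c(2, 2)))
  un <- age_standardise(two_group_draws(0.12, 0.28), skew)
  expect_equal(as.numeric(un$draws), rep(mean(c(0.12, 0.28)), 10))

  # groups below 20 are silently excluded from standardisation
  g3 <- two_group_draws(0.1, 0.3)
  g3$grid$age_start[1] <- 15
  only25 <- age_standardise(g3, std2)
  expect_equal(as.numeric(only25$draws), rep(0.3, 10))

  # a location missing one modelled age group is an error naming it
  g4 <- two_group_draws(0.1, 0.3)
  g4$grid <- rbind(g4$grid, data.frame(location_id = 1002, year = 2010,
                                       age_start = 20, sex = "female"))
  g4$draws <- rbind(g4$draws, matrix(0.2, 1, 10))
  expect_error(age_standardise(g4, std2), "missing age group 25")
})

test_that("hierarchy aggregation is population-weighted and associative", {
  h <- synthetic_hierarchy(4, 2, 2)
  pop <- make_population(location_id = 1001:1004, years = 2010,
                         age_starts = c(20, 25))
  g <- expand.grid(location_id = 1001:1004, year = 2010, age_start = NA_real_,
                   sex = "female", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  dm <- matrix(c(0.1, 0.3, 0.2, 0.4), 4, 8)
  dr <- structure(list(grid = g, draws = dm, n_draws = 8),
                  class = "svac_draws")
  agg <- aggregate_locations(dr, h, pop)
  # equal populations: region = plain mean of its two children
  r101 <- agg$draws[agg$grid$location_id == 101, ]
  kids <- h$location_id[!is.na(h$parent_id) & h$parent_id == 101]
  expect_equal(as.numeric(r101),
               as.numeric(colMeans(dm[match(kids, g$location_id), ])))
  # global equals the population-weighted mean over countries directly
  glob <- agg$draws[agg$grid$location_id == 1, ]
  expect_lt(max(abs(glob - colMeans(dm))), 1e-12)

  # single-child parent equals the child
  h1 <- synthetic_hierarchy(1, 1, 1)
  pop1 <- make_population(location_id = 1001, years = 2010,
                          age_starts = c(20, 25))
  dr1 <- structure(list(grid = g[1, ], draws = dm[1, , drop = FALSE],
                        n_draws = 8), class = "svac_draws")
  agg1 <- aggregate_locations(dr1, h1, pop1)
  expect_equal(agg1$draws[agg1$grid$location_id == 1, ],
               agg1$draws[agg1$grid$location_id == 1001, ])
})

test_that("unequal populations weight the aggregate accordingly", {
  h <- synthetic_hierarchy(2, 1, 1)
  pop <- make_population(location_id = 1001:1002, years = 2010,
                         age_starts = 20)
  pop$population[pop$location_id == 1002] <- 3000   # 3x weight
  g <- expand.grid(location_id = 1001:1002, year = 2010, age_start = 20,
                   sex = "female", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  dr <- structure(list(grid = g, draws = matrix(c(0.1, 0.3), 2, 4),
                       n_draws = 4), class = "svac_draws")
  agg <- aggregate_locations(dr, h, pop)
  expect_equal(as.numeric(agg$draws[agg$grid$location_id == 1, ]),
               rep((1000 * 0.1 + 3000 * 0.3) / 4000, 4), tolerance = 1e-12)
})

test_that("draw summaries use type-7 percentiles and behave under shifts", {
  const <- summarise_draws(matrix(0.3, 1, 200))
  expect_equal(unlist(const[c("mean", "lower", "upper")]),
               c(mean = 0.3, lower = 0.3, upper = 0.3))

  set.seed(33)
  perm <- matrix(sample(1:1000), 1, 1000)
  s <- summarise_draws(perm)
  expect_equal(s$lower, 25.975)    # 1 + 0.025 * 999
  expect_equal(s$upper, 975.025)
  expect_equal(s$mean, 500.5)
  expect_equal(summarise_draws(matrix(sort(perm), 1, 1000)), s)

  shifted <- summarise_draws(perm + 5)
  expect_equal(unlist(shifted[c("mean", "lower", "upper")]),
               unlist(s[c("mean", "lower", "upper")]) + 5)
  expect_true(with(s, lower <= mean && mean <= upper))
})

test_that("change over time differences draws before summarising", {
  g <- expand.grid(location_id = 1001, year = c(1990, 2023), age_start = 20,
                   sex = "female", KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  dm <- rbind(seq(0.1, 0.2, length.out = 50),
              seq(0.1, 0.2, length.out = 50) + 0.05)
  dr <- structure(list(grid = g, draws = dm, n_draws = 50),
                  class = "svac_draws")
  ch <- change_over_time(dr, 1990, 2023)
  expect_equal(ch$mean, 0.05, tolerance = 1e-12)
  expect_equal(ch$lower, 0.05, tolerance = 1e-12)   # perfectly correlated
  expect_equal(ch$upper, 0.05, tolerance = 1e-12)

  same <- change_over_time(dr, 1990, 1990)
  expect_equal(unlist(same[c("mean", "lower", "upper")]),
               c(mean = 0, lower = 0, upper = 0))
  expect_error(change_over_time(dr, 1990, 1991), "1991")
})

test_that("an estimated decline is detected with the right sign", {
  # truth with a falling cohort trend; does the pipeline's 1990->2023
  # difference for ages 20-24 recover the sign?
  cfg <- truth_config(n_countries = 4, n_regions = 2, n_super_regions = 2,
                      years = 1990:2023, age_max_start = 40)
  cfg$cohort_slope <- -0.6; cfg$cohort_amp <- 0
  tr <- make_truth(cfg, seed = 23)
  des <- observation_design(sources_per_country = 20, n_data_free = 0,
                            p_multi_age = 0, p_pair = 0, p_face_to_face = 0,
                            p_definition = c(reference = 1,
                                             noncontact_included = 0,
                                             intercourse_only = 0,
                                             before_16 = 0, before_12 = 0))
  samp <- sample_observations(tr, des, seed = 24)
  grid <- tr$grid[, c("location_id", "year", "age_start", "sex")]
  s1 <- stage1_fit(samp$obs, tr$hierarchy, grid)
  s2 <- stage2_smooth(s1, samp$obs, tr$hierarchy)
  dr <- gpr_fit(s2, samp$obs, stgpr_config(n_draws = 200), seed = 25)
  ch <- change_over_time(dr, 1990, 2023, age_start = 20)
  g <- tr$grid
  for (i in seq_len(nrow(ch))) {
    tru <- expit(g$eta[g$location_id == ch$location_id[i] & g$year == 2023 &
                         g$age_start == 20 & g$sex == ch$sex[i]]) -
      expit(g$eta[g$location_id == ch$location_id[i] & g$year == 1990 &
                    g$age_start == 20 & g$sex == ch$sex[i]])
    expect_lt(tru, 0)
  }
  expect_gt(mean(sign(ch$mean) == -1), 0.95)
})
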