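test_that("stage 1 recovers a pure sex offset from pooled data", {
  cfg <- truth_config(n_countries = 6, n_regions = 2, n_super_regions = 2)
  cfg$sd_super <- cfg$sd_region <- cfg$sd_country <- 0
  cfg$cohort_slope <- cfg$cohort_amp <- 0
  cfg$sex_offset <- -0.2
  tr <- make_truth(cfg, seed = 20)
  des <- observation_design(sources_per_country = 30, n_data_free = 0,
                            p_multi_age = 0, p_pair = 0, p_face_to_face = 0,
                            p_definition = c(reference = 1,
                                             noncontact_included = 0,
                                             intercourse_only = 0,
                                             before_16 = 0, before_12 = 0))
  samp <- sample_observations(tr, des, seed = 21)
  grid <- tr$grid[, c("location_id", "year", "age_start", "sex")]
  s1 <- stage1_fit(samp$obs, tr$hierarchy, grid)
  se_approx <- 2 * des$noise_sd / sqrt(nrow(samp$obs))
  expect_lt(abs(attr(s1, "sex_coef") - (-0.2)), 2 * se_approx + 0.02)
})

test_that("stage 1 degenerates gracefully and passes effects down the tree", {
  h <- synthetic_hierarchy(6, 2, 2)
  grid <- expand.grid(location_id = 1001:1006, year = 2000:2010,
                      age_start = c(20, 25), sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  single <- make_obs(1, mean = 0.2)
  s1 <- stage1_fit(single, h, grid)
  expect_equal(unique(s1$value), logit(0.2), tolerance = 1e-10)

  # countries under one region share the stage-1 prediction: a
  # data-free country inherits its region's level
  sim <- shared_sim()
  tr <- sim$truth
  obs <- sim$samp$obs
  g <- tr$grid[, c("location_id", "year", "age_start", "sex")]
  s1b <- stage1_fit(obs, tr$hierarchy, g)
  cn <- countries(tr$hierarchy)
  r1 <- cn$location_id[cn$region_id == cn$region_id[1]]
  a <- s1b$value[s1b$location_id == r1[1]]
  b <- s1b$value[s1b$location_id == r1[2]]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("stage 2 falls back to stage 1 without data and adds the single residual", {
  surf <- make_surface(-1.5, years = 2000:2010)
  h <- synthetic_hierarchy(3, 2, 2)
  empty <- make_obs(1)[0, ]
  class(empty) <- c("svac_obs", "data.frame")
  s2 <- stage2_smooth(surf, empty, h)
  expect_equal(s2$value, surf$value)

  one <- make_obs(1, mean = expit(-1.5 + 0.4), year = 2005)
  s2b <- stage2_smooth(surf, one, h)
  at_cell <- s2b$value[s2b$year == 2005]
  expect_equal(at_cell, -1.5 + 0.4, tolerance = 1e-10)
})

test_that("stage 2 weights follow the space-age-time kernel formula", {
  # flat prior, two observations in one country at years 1990 and 2023;
  # expected value at the 1990 cell computed directly from the kernel
  surf <- make_surface(-1.5, years = 1990:2023,
                       sexes = c("female", "male"))
  h <- synthetic_hierarchy(3, 2, 2)
  obs <- make_obs(2, mean = expit(c(-1.5 + 0.5, -1.5 - 0.3)),
                  year = c(1990, 2023))
  cfg <- stgpr_config(lam = 0.5, omega = 0.5, zeta = 0.9)
  s2 <- stage2_smooth(surf, obs, h, cfg)
  w1 <- (1 - (0 / 34)^0.5)^3      # same year
  w2 <- (1 - (33 / 34)^0.5)^3     # 33 years away
  expected <- -1.5 + (w1 * 0.5 + w2 * (-0.3)) / (w1 + w2)
  expect_equal(s2$value[s2$year == 1990 & s2$sex == "female"], expected,
               tolerance = 1e-10)
  # other sexes / countries without data keep the prior
  expect_equal(s2$value[s2$sex == "male"],
               rep(-1.5, sum(s2$sex == "male")))
})

test_that("GP with no data returns its prior with amplitude-width draws", {
  surf <- make_surface(-1.5, years = 1990:2019)
  empty <- make_obs(1, year = 1990)[0, ]
  class(empty) <- c("svac_obs", "data.frame")
  # amplitude floors at the configured value when no residuals exist
  surf2 <- make_surface(-1.5, years = 1990:2019, location_id = 1002)
  both <- rbind(surf, surf2)
  class(both) <- class(surf)
  one_obs <- make_obs(1, mean = expit(-1.5), year = 2000, location_id = 1002)
  cfg <- stgpr_config(amplitude_floor = 0.3, n_draws = 2000)
  dr <- gpr_fit(both, one_obs, cfg, seed = 4)
  expect_equal(dr$amplitude, 0.3)
  free <- dr$grid$location_id == 1001
  post <- dr$post_mean[free]
  expect_equal(post, rep(-1.5, sum(free)))
  sd_logit <- apply(logit(dr$draws[free, ]), 1, sd)
  expect_equal(mean(sd_logit), 0.3, tolerance = 0.02)
})

test_that("a near-noiseless observation pins the posterior mean", {
  surf <- make_surface(-1.5, years = 1990:2019)
  obs <- make_obs(1, mean = expit(-0.9), se = 1e-6, year = 2005)
  dr <- gpr_fit(surf, obs, stgpr_config(amplitude_floor = 0.3), seed = 5)
  at <- dr$post_mean[dr$grid$year == 2005]
  expect_equal(at, -0.9, tolerance = 1e-4)
})

test_that("GP posterior matches dense-matrix conditioning oracles", {
  years <- 1990:2019
  # two observations: explicit 2x2 inversion oracle
  amp <- 0.4; scale <- 10
  m <- rep(-1.2, length(years))
  ty <- c(1995, 2010); yy <- c(-0.8, -1.6); vv <- c(0.04, 0.09)
  kf <- function(d) amp^2 * (1 + sqrt(3) * abs(d) / scale) *
    exp(-sqrt(3) * abs(d) / scale)
  K11 <- kf(0) + vv[1]; K22 <- kf(0) + vv[2]; K12 <- kf(15)
  det2 <- K11 * K22 - K12^2
  inv2 <- matrix(c(K22, -K12, -K12, K11), 2) / det2
  target_year <- 2000
  kx <- c(kf(target_year - ty[1]), kf(target_year - ty[2]))
  hand <- -1.2 + sum(kx * (inv2 %*% (yy - m[1])))
  post <- gp_posterior(years, m, ty, yy, vv, amp, scale)
  expect_equal(post$mean[years == target_year], hand, tolerance = 1e-8)

  # 0- to 5-observation series vs the generic dense oracle
  set.seed(23)
  for (n_obs in 0:5) {
    prior <- sin(seq(0, 3, length.out = length(years))) - 1.5
    ty <- sort(sample(years, n_obs))
    yy <- rnorm(n_obs, -1.5, 0.4)
    vv <- runif(pmax(n_obs, 1), 0.01, 0.2)[seq_len(n_obs)]
    post <- gp_posterior(years, prior, ty, yy, vv, amp = 0.35, scale = 8)
    orac <- gp_oracle(years, prior, ty, yy, vv, amp = 0.35, scale = 8)
    expect_lt(max(abs(post$mean - orac$mean)), 1e-8)
    expect_lt(max(abs(diag(post$cov) - orac$var)), 1e-8)
  }
})

test_that("inflating an observation's variance pushes the fit away from it", {
  surf <- make_surface(-1.5, years = 1990:2019)
  mk <- function(vi) {
    o <- make_obs(1, mean = expit(-0.9), se = 0.02, year = 2005)
    o$variance_inflation <- vi
    o$extrapolated <- vi > 1
    o
  }
  cfg <- stgpr_config(amplitude_floor = 0.3)
  r1 <- gpr_fit(surf, mk(1), cfg, seed = 6)
  r2 <- gpr_fit(surf, mk(2), cfg, seed = 6)
  d1 <- abs(r1$post_mean[r1$grid$year == 2005] - (-0.9))
  d2 <- abs(r2$post_mean[r2$grid$year == 2005] - (-0.9))
  expect_gt(d2, d1)
})

test_that("draws are deterministic in the seed and stay inside (0,1)", {
  sim <- shared_sim()
  tr <- sim$truth
  obs <- sim$samp$obs
  obs <- obs[(obs$age_end - obs$age_start) <= 5, ]
  class(obs) <- c("svac_obs", "data.frame")
  grid <- tr$grid[tr$grid$year %in% 2000:2010 & tr$grid$age_start <= 30,
                  c("location_id", "year", "age_start", "sex")]
  obs <- obs[obs$year %in% 2000:2010 & obs$age_start <= 30, ]
  class(obs) <- c("svac_obs", "data.frame")
  s1 <- stage1_fit(obs, tr$hierarchy, grid)
  s2 <- stage2_smooth(s1, obs, tr$hierarchy)
  cfg <- stgpr_config(n_draws = 200)
  d1 <- gpr_fit(s2, obs, cfg, seed = 9)
  d2 <- gpr_fit(s2, obs, cfg, seed = 9)
  expect_identical(d1$draws, d2$draws)
  expect_true(all(d1$draws > 0 & d1$draws < 1))
  d3 <- gpr_fit(s2, obs, cfg, seed = 10)
  expect_false(identical(d1$draws, d3$draws))
})
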