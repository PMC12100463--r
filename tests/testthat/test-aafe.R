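mk_records <- function(n, series = "VACS", sex = "female",
                       respondent_age = 20, ever = TRUE, age_first = 10,
                       survey_id = "S1", country = 1001, region = 101,
                       primary = TRUE, urban = FALSE) {
  data.frame(survey_id = rep_len(survey_id, n), series = rep_len(series, n),
             country = rep_len(country, n), region = rep_len(region, n),
             sex = rep_len(sex, n),
             respondent_age = rep_len(respondent_age, n),
             ever_experienced = rep_len(ever, n),
             age_first = rep_len(age_first, n),
             completed_primary = rep_len(primary, n),
             urban = rep_len(urban, n), stringsAsFactors = FALSE)
}

test_that("record filtering excludes implausible and out-of-window cases", {
  rec <- rbind(
    mk_records(1, age_first = -1),                       # implausible
    mk_records(1, age_first = 25, respondent_age = 20),  # > current age
    mk_records(1, age_first = 20, respondent_age = 20),  # boundary: kept
    mk_records(1, age_first = NA),                       # missing
    mk_records(1, ever = FALSE, age_first = NA),
    mk_records(1, series = "DHS", respondent_age = 30),  # outside 15-24
    mk_records(1, age_first = 12))
  res <- filter_records(rec)
  expect_equal(nrow(res$kept), 2)
  expect_true(any(res$kept$age_first == 20))
  expect_equal(unname(res$report["implausible"]), 2L)
  expect_equal(unname(res$report["missing"]), 1L)
  expect_equal(unname(res$report["never_experienced"]), 1L)
  expect_equal(unname(res$report["age_window"]), 1L)
})

test_that("filter exclusion counts match the generator ledger", {
  tr <- make_truth(truth_config(n_countries = 6, n_regions = 2,
                                n_super_regions = 2), seed = 29)
  des <- microdata_design(n_per_module = 400, n_dhs_modules = 0,
                          n_vacs_modules = 6, implausible_rate = 0.05)
  md <- make_microdata(tr, des, seed = 29)
  res <- filter_records(md$records)
  expect_equal(unname(res$report["implausible"]), sum(md$ledger$implausible))
  expect_equal(unname(res$report["missing"]), sum(md$ledger$masked))
})

test_that("module exclusion is strict at the 50% boundary", {
  # module A: exactly 50% missing -> retained; module B: 60% -> dropped
  a <- rbind(mk_records(10, survey_id = "A", series = "DHS", age_first = 10),
             mk_records(10, survey_id = "A", series = "DHS", age_first = NA))
  b <- rbind(mk_records(4, survey_id = "B", series = "DHS", age_first = 10),
             mk_records(6, survey_id = "B", series = "DHS", age_first = NA))
  v <- rbind(mk_records(2, survey_id = "V", series = "VACS", age_first = 10),
             mk_records(8, survey_id = "V", series = "VACS", age_first = NA))
  res <- exclude_high_missingness_modules(rbind(a, b, v))
  expect_setequal(res$dropped, "B")
  expect_true(all(c("A", "V") %in% res$kept$survey_id))  # VACS never dropped
  expect_equal(res$report$missing_fraction[res$report$survey_id == "A"], 0.5)
})

test_that("planted high-missingness DHS modules are exactly the ones dropped", {
  tr <- make_truth(truth_config(n_countries = 6, n_regions = 2,
                                n_super_regions = 2), seed = 31)
  des <- microdata_design(n_per_module = 300, n_dhs_modules = 10,
                          n_vacs_modules = 2, n_high_missing_dhs = 3,
                          high_missing_rate = 0.75, missing_base = 0.1,
                          missing_male_excess = 0)
  md <- make_microdata(tr, des, seed = 31)
  res <- exclude_high_missingness_modules(md$records)
  expect_setequal(res$dropped, sprintf("DHS_%02d", 1:3))
})

test_that("threshold CDF percentages count strictly-before ages", {
  rec <- mk_records(4, age_first = c(11, 15, 17, 20),
                    respondent_age = c(20, 20, 20, 22))
  dist <- compute_distribution(rec)
  all_row <- dist[dist$series == "aggregate" & dist$region == "all", ]
  expect_equal(all_row$pct_before_12, 25)
  expect_equal(all_row$pct_before_16, 50)
  expect_equal(all_row$pct_before_18, 75)
  expect_equal(all_row$n, 4)

  ten <- compute_distribution(mk_records(5, age_first = 10))
  expect_true(all(ten[ten$n > 0, c("pct_before_12", "pct_before_16",
                                   "pct_before_18")] == 100))
})

test_that("threshold monotonicity holds on every synthetic output row", {
  tr <- make_truth(truth_config(n_countries = 6, n_regions = 2,
                                n_super_regions = 2), seed = 37)
  md <- make_microdata(tr, microdata_design(), seed = 37)
  res <- filter_records(exclude_high_missingness_modules(md$records)$kept)
  dist <- compute_distribution(res$kept)
  ok <- dist$n > 0
  expect_true(all(dist$pct_before_12[ok] <= dist$pct_before_16[ok]))
  expect_true(all(dist$pct_before_16[ok] <= dist$pct_before_18[ok]))
  expect_true(all(dist$pct_before_18[ok] <= 100))
  expect_true(all(dist$pct_before_12[ok] >= 0))
})

test_that("recovered distributions match the exact design CDF", {
  tr <- make_truth(truth_config(n_countries = 6, n_regions = 2,
                                n_super_regions = 2), seed = 37)
  des <- microdata_design(n_per_module = 1250, n_dhs_modules = 0,
                          n_vacs_modules = 8, missing_base = 0.1,
                          missing_male_excess = 0.1, implausible_rate = 0.02)
  md <- make_microdata(tr, des, seed = 38)
  res <- filter_records(md$records)
  dist <- compute_distribution(res$kept)
  for (sx in c("female", "male")) {
    row <- dist[dist$sex == sx & dist$series == "VACS" &
                  dist$region == "all", ]
    for (thr in c(12, 16, 18)) {
      p <- aafe_design_cdf(des, sx, "VACS", thr)
      se <- sqrt(p * (1 - p) / row$n)
      expect_lt(abs(row[[paste0("pct_before_", thr)]] / 100 - p), 3 * se)
    }
  }
})

test_that("diagnostics report correlations and missingness contrasts", {
  rec <- mk_records(50, respondent_age = 15:24,
                    age_first = 15:24 - 1)
  d <- aafe_diagnostics(rec)
  expect_equal(d$correlations$r[1], 1)

  # independent ages: correlation near zero
  set.seed(41)
  n <- 2000
  rec2 <- mk_records(n, respondent_age = sample(18:24, n, TRUE),
                     age_first = sample(5:17, n, TRUE))
  d2 <- aafe_diagnostics(rec2)
  expect_lt(abs(d2$correlations$r[1]), 0.05)

  # male missingness excess recovered within 2 SE
  tr <- make_truth(truth_config(n_countries = 6, n_regions = 2,
                                n_super_regions = 2), seed = 42)
  des <- microdata_design(n_per_module = 1000, n_dhs_modules = 0,
                          n_vacs_modules = 6, missing_base = 0.12,
                          missing_male_excess = 0.1)
  md <- make_microdata(tr, des, seed = 42)
  d3 <- aafe_diagnostics(md$records)
  mrow <- d3$missingness[d3$missingness$quantity ==
                           "male_minus_female_missingness", ]
  expect_gt(mrow$estimate, 0)
  expect_lt(abs(mrow$estimate - 0.1), 2 * mrow$se)
})
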