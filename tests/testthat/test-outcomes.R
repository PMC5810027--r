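# Cohort-level outcome aggregation.

test_that("age-at-ESRD summaries handle small and degenerate cohorts", {
  two <- make_outcomes(c("esrd", "esrd"), age_at_esrd = c(50, 54))
  s <- age_at_esrd_summary(two)
  expect_equal(s$mean, 52)
  expect_equal(s$median, 52)
  expect_equal(s$n_progressors, 2L)
  one <- make_outcomes(c("esrd", "dead"), age_at_esrd = c(51, NA))
  s1 <- age_at_esrd_summary(one)
  expect_equal(s1$sd, 0)
  expect_true(s1$single_progressor)
  none <- make_outcomes(c("dead", "dead"))
  s0 <- age_at_esrd_summary(none) # empty result, not an exception
  expect_equal(s0$n_progressors, 0L)
  expect_true(is.na(s0$mean) && is.na(s0$median) && is.na(s0$sd))
})

test_that("summary quantiles match an independent sort-based oracle", {
  set.seed(55)
  for (n in c(5, 17, 200)) {
    ages <- 40 + 20 * runif(n)
    out <- make_outcomes(rep("esrd", n), age_at_esrd = ages)
    s <- age_at_esrd_summary(out)
    o <- quantile_oracle(ages, c(0.25, 0.5, 0.75))
    expect_equal(c(s$iqr_low, s$median, s$iqr_high), o,
                 tolerance = 1e-12)
  }
})

test_that("time in stages averages progressors and conserves totals", {
  y <- rbind(c(0, 3, 0, 0), c(1, 2, 4, 1))
  out <- make_outcomes(c("esrd", "esrd"), age_at_esrd = c(43, 48),
                       years = y)
  tis <- time_in_stages(out)
  expect_equal(unname(tis$by_stage), c(0.5, 2.5, 2, 0.5))
  expect_equal(tis$total_ckd1_4, 5.5)
  # single patient only in stage 2
  solo <- make_outcomes("esrd", age_at_esrd = 43,
                        years = matrix(c(0, 3, 0, 0), 1))
  expect_equal(unname(time_in_stages(solo)$by_stage), c(0, 3, 0, 0))
  # stage totals equal pre-ESRD time for simulated progressors
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 40), seed = 9)
  cfg <- simulation_config(seed = 33, mortality_enabled = FALSE)
  sim <- simulate_cohort(cohort, config = cfg)
  pr <- sim$patients[sim$patients$status == "esrd", ]
  expect_equal(pr$years_stage1 + pr$years_stage2 + pr$years_stage3 +
                 pr$years_stage4, as.numeric(pr$cycles))
})

test_that("cumulative incidence is monotone with the whole cohort as denominator", {
  out <- make_outcomes(c("esrd", "esrd", "dead", "horizon_censored"),
                       age_at_esrd = c(50, 50, NA, NA))
  ci <- cumulative_esrd_by_age(out, ages = c(45, 55))
  expect_equal(ci$cum_incidence, c(0, 0.5)) # denominator includes all 4
  expect_error(cumulative_esrd_by_age(out, ages = c(55, 45)), "ascending")
  # monotone and converging to the lifetime incidence
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 200), seed = 10)
  cfg <- simulation_config(seed = 12, mortality_enabled = TRUE)
  sim <- simulate_cohort(cohort, life_table = synthetic_uk_like_table(),
                         config = cfg)
  ci2 <- cumulative_esrd_by_age(sim, ages = seq(40, 140, by = 5))
  expect_true(all(diff(ci2$cum_incidence) >= 0))
  expect_equal(ci2$cum_incidence[nrow(ci2)], lifetime_esrd_incidence(sim))
})

test_that("lifetime incidence counts terminal ESRD over everyone", {
  out <- make_outcomes(c("esrd", "dead", "dead", "esrd"),
                       age_at_esrd = c(50, NA, NA, 60))
  expect_equal(lifetime_esrd_incidence(out), 0.5)
  # certain immediate death: nobody progresses
  cohort <- fixed_profile_cohort(40, 1500, 80, n = 10)
  cfg <- simulation_config(seed = 3, mortality_enabled = TRUE,
                           sample_coefficients = FALSE)
  sim <- simulate_cohort(cohort, life_table = certain_death_table(),
                         config = cfg)
  expect_equal(lifetime_esrd_incidence(sim), 0)
  # mortality off on a lifetime horizon: nearly every TEMPO-like patient
  # reaches ESRD; the exception is the small-kidney regime, where the TKV
  # equation predicts shrinkage (beta + delta*age < 0 past age ~50) and
  # eGFR can plateau above 15 -- those patients are censored, never lost
  ch <- sample_baseline_cohort(tempo34_cohort_spec(n = 100), seed = 14)
  sim2 <- suppressWarnings(simulate_cohort(ch, config = simulation_config(
    seed = 14, sample_coefficients = FALSE, mortality_enabled = FALSE)))
  expect_true(all(sim2$patients$status %in% c("esrd", "horizon_censored")))
  expect_gte(lifetime_esrd_incidence(sim2), 0.95)
  cens <- sim2$patients[sim2$patients$status == "horizon_censored", ]
  expect_true(all(cens$baseline_tkv < 750))
})

test_that("trajectory summaries order their percentiles and collapse for identical paths", {
  cohort <- fixed_profile_cohort(40, 1500, 80, female_fraction = 0, n = 8)
  cfg <- simulation_config(seed = 2, sample_coefficients = FALSE,
                           mortality_enabled = FALSE,
                           record_trajectories = TRUE)
  sim <- simulate_cohort(cohort, config = cfg)
  ts <- trajectory_summary(sim)
  expect_true(all(ts$egfr_p2.5 == ts$egfr_p97.5)) # identical trajectories
  expect_true(all(ts$tkv_p2.5 == ts$tkv_p97.5))
  cfg$sample_coefficients <- TRUE
  sim2 <- simulate_cohort(fixed_profile_cohort(40, 1500, 80, 0, 200),
                          config = cfg)
  ts2 <- trajectory_summary(sim2)
  expect_true(all(ts2$egfr_p2.5 <= ts2$egfr_median + 1e-12))
  expect_true(all(ts2$egfr_median <= ts2$egfr_p97.5 + 1e-12))
  expect_true(all(ts2$n_at_risk == cummin(ts2$n_at_risk))) # non-increasing
  expect_error(trajectory_summary(simulate_cohort(
    cohort, config = simulation_config(seed = 2, mortality_enabled = FALSE))),
    "not recorded")
})

test_that("scenario grids run the Cartesian product under common random numbers", {
  cfg <- simulation_config(seed = 19, mortality_enabled = FALSE)
  base <- list(age = 40, tkv = 1500, egfr = 80, female_fraction = 0.5,
               n = 80)
  # single cell reproduces a plain run
  g1 <- scenario_grid(base, list(tkv = 1500), config = cfg)
  plain <- simulate_cohort(fixed_profile_cohort(40, 1500, 80, 0.5, 80),
                           config = cfg)
  expect_equal(g1$mean_age_esrd, age_at_esrd_summary(plain)$mean)
  expect_equal(g1$lifetime_incidence, lifetime_esrd_incidence(plain))
  # larger kidneys at baseline bring ESRD forward
  g2 <- scenario_grid(base, list(tkv = c(1000, 2000)), config = cfg)
  expect_lt(g2$mean_age_esrd[g2$tkv == 2000],
            g2$mean_age_esrd[g2$tkv == 1000])
  # zero-variation cells are identical under common random numbers
  g3 <- scenario_grid(base, list(egfr = c(80, 80)), config = cfg)
  expect_equal(g3[1, -1], g3[2, -1], ignore_attr = TRUE)
  # Cartesian product shape
  g4 <- scenario_grid(base, list(tkv = c(1000, 2000), age = c(30, 40)),
                      config = cfg)
  expect_equal(nrow(g4), 4)
  expect_error(scenario_grid(base, list(), config = cfg), "non-empty")
  expect_error(scenario_grid(base, list(tkv = numeric(0)), config = cfg),
               "empty value")
  expect_error(scenario_grid(base, list(banana = 1), config = cfg),
               "not present")
})

test_that("scenario grids accept a cohort spec base", {
  cfg <- simulation_config(seed = 20, mortality_enabled = FALSE)
  base <- tempo34_cohort_spec(n = 60)
  g <- scenario_grid(base, list(mean_tkv = c(1200, 2200)), config = cfg)
  expect_equal(nrow(g), 2)
  expect_lt(g$mean_age_esrd[2], g$mean_age_esrd[1])
})
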