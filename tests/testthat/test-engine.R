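# Annual-cycle simulation engine.

point_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, sample_coefficients = FALSE,
                    mortality_enabled = FALSE, ...)
}

test_that("the deterministic mean-path run reaches ESRD at cycle 13, age 51.7", {
  sp <- simulate_patient(mean_male_patient(), config = point_cfg())
  expect_identical(sp$final$status, "esrd")
  expect_equal(sp$final$cycles, 13L)
  expect_equal(sp$final$age_at_esrd, 51.7, tolerance = 1e-9)
  # trajectory: baseline row plus one row per cycle, strictly increasing
  expect_equal(nrow(sp$trajectory), 14)
  expect_identical(sp$trajectory$cycle, 0:13)
  expect_true(all(diff(sp$trajectory$tkv) > 0))
  expect_true(all(diff(sp$trajectory$egfr) < 0))
  expect_identical(sp$trajectory$status[14], "esrd")
  expect_true(all(sp$trajectory$status[-14] == "progressing"))
})

test_that("a patient at ESRD at baseline returns immediately", {
  pat <- fixed_profile_cohort(50, 2000, 14, female_fraction = 0, n = 1)
  sp <- simulate_patient(pat, config = point_cfg())
  expect_identical(sp$final$status, "esrd")
  expect_equal(sp$final$cycles, 0L)
  expect_equal(sp$final$age_at_esrd, 50)
  expect_true(all(sp$final[paste0("years_stage", 1:4)] == 0))
})

test_that("certain death at cycle 1 precludes any progression", {
  pat <- mean_male_patient()
  cfg <- simulation_config(seed = 1, sample_coefficients = FALSE,
                           mortality_enabled = TRUE)
  sp <- simulate_patient(pat, life_table = certain_death_table(),
                         config = cfg)
  expect_identical(sp$final$status, "dead")
  expect_equal(sp$final$cycles, 0L)
  expect_true(all(sp$final[paste0("years_stage", 1:4)] == 0))
  # only the baseline trajectory row exists: no update happened
  expect_equal(nrow(sp$trajectory), 1)
})

test_that("mortality requires a life table", {
  cfg <- simulation_config(seed = 1, mortality_enabled = TRUE)
  expect_error(simulate_cohort(mean_male_patient(), config = cfg),
               "life table")
})

test_that("a one-patient cohort reproduces simulate_patient exactly", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 6), seed = 5)
  cfg <- simulation_config(seed = 17, mortality_enabled = TRUE)
  lt <- synthetic_uk_like_table()
  out <- simulate_cohort(cohort, life_table = lt, config = cfg)
  for (i in c(1, 4, 6)) {
    sp <- simulate_patient(cohort[i, ], life_table = lt, config = cfg)
    expect_equal(sp$final, out$patients[i, ], ignore_attr = TRUE)
  }
})

test_that("per-patient outcomes are invariant to cohort ordering", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 40), seed = 3)
  cfg <- simulation_config(seed = 29, mortality_enabled = TRUE)
  lt <- synthetic_uk_like_table()
  out1 <- simulate_cohort(cohort, life_table = lt, config = cfg)
  perm <- rev(seq_len(nrow(cohort)))
  out2 <- simulate_cohort(cohort[perm, ], life_table = lt, config = cfg)
  reordered <- out2$patients[order(out2$patients$patient_id), ]
  expect_equal(reordered, out1$patients, ignore_attr = TRUE)
})

test_that("runs are fully deterministic under a fixed seed", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 30), seed = 4)
  cfg <- simulation_config(seed = 10, mortality_enabled = TRUE,
                           record_trajectories = TRUE)
  lt <- synthetic_uk_like_table()
  out1 <- simulate_cohort(cohort, life_table = lt, config = cfg)
  out2 <- simulate_cohort(cohort, life_table = lt, config = cfg)
  expect_identical(out1$patients, out2$patients)
  expect_identical(out1$trajectories, out2$trajectories)
})

test_that("an all-zero life table reproduces the mortality-off run", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 25), seed = 6)
  cfg_on <- simulation_config(seed = 13, mortality_enabled = TRUE)
  cfg_off <- simulation_config(seed = 13, mortality_enabled = FALSE)
  out_on <- simulate_cohort(cohort, life_table = zero_life_table(),
                            config = cfg_on)
  out_off <- simulate_cohort(cohort, config = cfg_off)
  expect_equal(out_on$patients, out_off$patients, ignore_attr = TRUE)
})

test_that("years credited to stages are conserved", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 50), seed = 7)
  cfg <- simulation_config(seed = 21, mortality_enabled = TRUE)
  out <- simulate_cohort(cohort, life_table = synthetic_uk_like_table(),
                         config = cfg)
  p <- out$patients
  total <- p$years_stage1 + p$years_stage2 + p$years_stage3 + p$years_stage4
  # stage-years equal completed progression cycles for every patient
  expect_equal(total, as.numeric(p$cycles))
  expect_true(all(p$cycles <= cfg$horizon_years))
  # for progressors, elapsed cycles equal age at ESRD minus baseline age
  pr <- p[p$status == "esrd" & p$cycles > 0, ]
  expect_equal(pr$age_at_esrd - pr$baseline_age, as.numeric(pr$cycles))
})

test_that("terminal statuses are absorbing and exhaustive", {
  cohort <- sample_baseline_cohort(tempo34_cohort_spec(n = 60), seed = 8)
  cfg <- simulation_config(seed = 23, mortality_enabled = TRUE,
                           record_trajectories = TRUE)
  out <- simulate_cohort(cohort, life_table = synthetic_uk_like_table(),
                         config = cfg)
  expect_true(all(out$patients$status %in%
                    c("esrd", "dead", "horizon_censored")))
  # no trajectory rows beyond each patient's terminal cycle
  last <- tapply(out$trajectories$cycle, out$trajectories$patient_id, max)
  expect_true(all(last[as.character(out$patients$patient_id)] <=
                    pmax(out$patients$cycles, 0)))
  # ESRD rows are terminal: at most one per patient, at the last cycle
  esrd_rows <- out$trajectories[out$trajectories$status == "esrd", ]
  expect_true(!anyDuplicated(esrd_rows$patient_id))
})

test_that("without sampling or mortality a fixed profile has zero outcome dispersion", {
  cohort <- fixed_profile_cohort(40, 1800, 75, female_fraction = 0, n = 20)
  out <- simulate_cohort(cohort, config = point_cfg(seed = 2))
  ages <- out$patients$age_at_esrd
  expect_true(all(out$patients$status == "esrd"))
  expect_equal(stats::sd(ages), 0)
})

test_that("age at ESRD is monotone in baseline TKV and eGFR on the mean path", {
  cfg <- point_cfg(seed = 3)
  esrd_age <- function(tkv, egfr) {
    pat <- fixed_profile_cohort(40, tkv, egfr, female_fraction = 0, n = 1)
    simulate_patient(pat, config = cfg)$final$age_at_esrd
  }
  by_tkv <- vapply(seq(800, 3000, by = 200), esrd_age, numeric(1),
                   egfr = 80)
  expect_true(all(diff(by_tkv) <= 0))
  by_egfr <- vapply(seq(40, 120, by = 10), function(e) esrd_age(1500, e),
                    numeric(1))
  expect_true(all(diff(by_egfr) >= 0))
})

test_that("coefficient sampling makes identical baselines diverge, reproducibly", {
  cohort <- fixed_profile_cohort(40, 1800, 75, female_fraction = 0.5,
                                 n = 30)
  cfg <- simulation_config(seed = 41, mortality_enabled = FALSE)
  out <- simulate_cohort(cohort, config = cfg)
  ages <- out$patients$age_at_esrd[out$patients$status == "esrd"]
  expect_gt(stats::sd(ages), 0)
  out2 <- simulate_cohort(cohort, config = cfg)
  expect_identical(out$patients, out2$patients)
})

test_that("per-cycle coefficient redraw and ESRD-age interpolation options work", {
  pat <- mean_male_patient()
  cfg_r <- simulation_config(seed = 5, mortality_enabled = FALSE,
                             redraw_each_cycle = TRUE)
  sp_r <- simulate_patient(pat, config = cfg_r)
  expect_true(sp_r$final$status %in% c("esrd", "horizon_censored"))
  cfg_i <- point_cfg(seed = 5, interpolate_esrd_age = TRUE)
  sp_i <- simulate_patient(pat, config = cfg_i)
  # interpolated age lies strictly inside the crossing year
  expect_gt(sp_i$final$age_at_esrd, 50.7)
  expect_lt(sp_i$final$age_at_esrd, 51.7)
})

test_that("configuration and cohort validation reject bad input", {
  expect_error(simulation_config(), "mandatory")
  expect_error(simulation_config(seed = 1.5), "integer")
  expect_error(simulation_config(seed = 1, horizon_years = 0), ">= 1")
  cfg <- point_cfg()
  expect_error(simulate_cohort(data.frame(), config = cfg),
               "required columns")
  ch <- mean_male_patient()
  ch$tkv <- -1
  expect_error(simulate_cohort(ch, config = cfg), "positive")
  ch2 <- rbind(mean_male_patient(), mean_male_patient())
  expect_error(simulate_cohort(ch2, config = cfg), "duplicated")
})
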