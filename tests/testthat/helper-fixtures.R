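# Shared fixtures, built in code.

toy_life_table <- function(qx = 0.01, max_age = 5, qx_female = qx) {
  life_table(0:max_age, rep(qx, max_age + 1), rep(qx_female, max_age + 1))
}

zero_life_table <- function(max_age = 120) {
  life_table(0:max_age, rep(0, max_age + 1), rep(0, max_age + 1))
}

certain_death_table <- function(max_age = 120) {
  life_table(0:max_age, rep(1, max_age + 1), rep(1, max_age + 1))
}

# TEMPO mean male profile used by the deterministic mean-path checks.
mean_male_patient <- function() {
  fixed_profile_cohort(38.7, 1692, 81.61, female_fraction = 0, n = 1)
}

# Minimal cohort_outcomes wrapper for summary-function tests with
# hand-chosen per-patient records.
make_outcomes <- function(status, age_at_esrd = rep(NA_real_, length(status)),
                          years = matrix(0, length(status), 4),
                          seed = 1) {
  n <- length(status)
  patients <- data.frame(
    patient_id = seq_len(n), is_female = rep(FALSE, n),
    baseline_age = rep(40, n), baseline_tkv = rep(1500, n),
    baseline_egfr = rep(80, n), status = status,
    age_at_esrd = age_at_esrd,
    cycles = ifelse(is.na(age_at_esrd), 0L, round(age_at_esrd - 40)),
    years_stage1 = years[, 1], years_stage2 = years[, 2],
    years_stage3 = years[, 3], years_stage4 = years[, 4])
  structure(list(patients = patients, trajectories = NULL, n = n,
                 config = simulation_config(seed = seed),
                 coefficients = list(tkv = "t", egfr = "g")),
            class = "cohort_outcomes")
}

# Sort-based linear-interpolation quantile, written independently of
# stats::quantile, as the oracle for IQR/percentile outputs.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo + 1 >= n) return(s[n])
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }, numeric(1))
}
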