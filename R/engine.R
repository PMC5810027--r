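# Annual-cycle patient-level simulation engine.
#
# Each simulated patient advances through fixed 1-year cycles until ESRD
# (eGFR < 15), death, or the simulation horizon. Within a cycle the event
# order is fixed: (1) mortality is evaluated at the age at cycle start;
# (2) annual TKV and eGFR changes are computed from the state at cycle
# start; (3) the state is updated, age advances by one year and one year is
# credited to the CKD stage occupied at cycle start; (4) the ESRD rule is
# checked on the updated eGFR. A patient therefore cannot progress in the
# cycle in which they die.
#
# Every patient owns an RNG substream derived deterministically from
# (config seed, patient_id), so cohort results are invariant to patient
# ordering and each patient is reproducible in isolation.

#' Simulation configuration
#'
#' @param seed Integer master seed (mandatory: there is no silent
#'   nondeterminism; every random draw descends from this seed).
#' @param horizon_years Maximum number of annual cycles (default 80, i.e. a
#'   lifetime horizon).
#' @param sample_coefficients Draw one multivariate-normal coefficient
#'   vector per patient (default \code{TRUE}); when \code{FALSE} the point
#'   estimates are used for everyone.
#' @param mortality_enabled Apply life-table mortality (default
#'   \code{TRUE}); requires a life table when on.
#' @param record_trajectories Keep per-cycle TKV/eGFR trajectories (default
#'   \code{FALSE}; single-patient runs always record).
#' @param redraw_each_cycle Redraw the coefficient vectors every cycle
#'   instead of once per patient (default \code{FALSE}; the default holds a
#'   patient's draw fixed for life, which is what makes identical baselines
#'   diverge into persistent fast and slow progressors).
#' @param interpolate_esrd_age Linearly interpolate the age at ESRD within
#'   the crossing year (default \code{FALSE}: ESRD timing is resolved at
#'   whole-cycle granularity).
#' @param tkv_floor Lower clamp on TKV in mL (default 100; the equations
#'   were fitted on TKV >= 750 mL and are not meant to extrapolate to
#'   vanishing kidneys).
#' @return An object of class \code{simulation_config}.
#' @export
#' @examples
#' simulation_config(seed = 1)
simulation_config <- function(seed, horizon_years = 80L,
                              sample_coefficients = TRUE,
                              mortality_enabled = TRUE,
                              record_trajectories = FALSE,
                              redraw_each_cycle = FALSE,
                              interpolate_esrd_age = FALSE,
                              tkv_floor = 100) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed) || seed != round(seed))
    stop("'seed' is mandatory and must be a single integer", call. = FALSE)
  if (!is.numeric(horizon_years) || length(horizon_years) != 1 ||
      horizon_years < 1 || horizon_years != round(horizon_years))
    stop("'horizon_years' must be a single integer >= 1", call. = FALSE)
  if (!is.finite(tkv_floor) || tkv_floor <= 0)
    stop("'tkv_floor' must be positive", call. = FALSE)
  structure(
    list(seed = as.integer(seed),
         horizon_years = as.integer(horizon_years),
         cycle_length = 1,
         sample_coefficients = isTRUE(sample_coefficients),
         mortality_enabled = isTRUE(mortality_enabled),
         record_trajectories = isTRUE(record_trajectories),
         redraw_each_cycle = isTRUE(redraw_each_cycle),
         interpolate_esrd_age = isTRUE(interpolate_esrd_age),
         tkv_floor = tkv_floor),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  seed %d, horizon %d years (1-year cycles)\n", x$seed,
              x$horizon_years))
  cat(sprintf("  coefficient sampling %s%s, mortality %s, trajectories %s\n",
              if (x$sample_coefficients) "on" else "off",
              if (x$redraw_each_cycle) " (redrawn each cycle)" else "",
              if (x$mortality_enabled) "on" else "off",
              if (x$record_trajectories) "recorded" else "not recorded"))
  invisible(x)
}

# Deterministic per-patient substream seed: a Lehmer-style hash of the
# master seed and patient id over a prime modulus. Kept below 2^31 and
# exact in double arithmetic (48271 * p < 2^53).
patient_seed <- function(seed, patient_id) {
  p <- 2147483629
  (48271 * (as.numeric(seed) %% p) + as.numeric(patient_id)) %% p
}

STATUS_LEVELS <- c("progressing", "esrd", "dead", "horizon_censored")

# Vectorized engine core. B_t (n x 5) and B_g (n x 2) hold per-patient
# coefficient values, or n x 5m / n x 2m when coefficients are redrawn each
# cycle (m = horizon). U is the n x horizon matrix of mortality uniforms or
# NULL. Returns the per-patient outcome table and, optionally, per-cycle
# state matrices.
run_engine <- function(cohort, B_t, B_g, U, table, config) {
  n <- nrow(cohort)
  horizon <- config$horizon_years
  redraw <- config$redraw_each_cycle
  a <- cohort$age
  k <- cohort$tkv
  e <- cohort$egfr
  fem <- as.numeric(cohort$is_female)

  status <- rep(1L, n) # index into STATUS_LEVELS
  age_esrd <- rep(NA_real_, n)
  cycles <- rep(0L, n)
  yrs <- matrix(0, n, 4L)
  n_floored <- 0L

  # patients already at ESRD at baseline never enter the cycle loop
  at_esrd <- e < 15
  status[at_esrd] <- 2L
  age_esrd[at_esrd] <- a[at_esrd]

  record <- config$record_trajectories
  if (record) {
    A <- K <- E <- matrix(NA_real_, n, horizon + 1L)
    A[, 1L] <- a; K[, 1L] <- k; E[, 1L] <- e
  }

  if (config$mortality_enabled) {
    qm <- table$qx_male
    qf <- table$qx_female
    max_age <- max(table$age)
  }

  for (cyc in seq_len(horizon)) {
    act <- status == 1L
    if (!any(act)) break
    if (config$mortality_enabled) {
      idx <- pmin(floor(a), max_age) + 1L
      q <- ifelse(fem > 0, qf[idx], qm[idx])
      died <- act & U[, cyc] < q
      status[died] <- 3L
      act <- act & !died
    }
    st <- .stage_index(e)
    lt <- log(k)
    if (redraw) {
      jt <- (cyc - 1L) * 5L
      jg <- (cyc - 1L) * 2L
      dk <- .dtkv_v(a, lt, fem, B_t[, jt + 1L], B_t[, jt + 2L],
                    B_t[, jt + 3L], B_t[, jt + 4L], B_t[, jt + 5L])
      de <- .degfr_v(lt, B_g[, jg + 1L], B_g[, jg + 2L])
    } else {
      dk <- .dtkv_v(a, lt, fem, B_t[, 1L], B_t[, 2L], B_t[, 3L], B_t[, 4L],
                    B_t[, 5L])
      de <- .degfr_v(lt, B_g[, 1L], B_g[, 2L])
    }
    e_prev <- e
    k_new <- k + dk
    n_floored <- n_floored + sum(act & k_new < config$tkv_floor)
    k[act] <- pmax(k_new[act], config$tkv_floor)
    e[act] <- pmax(e_prev[act] + de[act], 0)
    yrs[cbind(which(act), st[act])] <- yrs[cbind(which(act), st[act])] + 1
    a[act] <- a[act] + 1
    cycles[act] <- cyc
    hit <- act & e < 15
    status[hit] <- 2L
    age_esrd[hit] <- if (config$interpolate_esrd_age) {
      (a[hit] - 1) + (e_prev[hit] - 15) / (e_prev[hit] - e[hit])
    } else {
      a[hit]
    }
    if (record) {
      A[act, cyc + 1L] <- a[act]
      K[act, cyc + 1L] <- k[act]
      E[act, cyc + 1L] <- e[act]
    }
  }
  status[status == 1L] <- 4L # still progressing at horizon -> censored
  status_chr <- c(NA, "esrd", "dead", "horizon_censored")[status]

  if (n_floored > 0)
    warning(sprintf(
      "TKV clamped at the %g mL floor in %d patient-cycle(s); the equations extrapolate poorly below 750 mL",
      config$tkv_floor, n_floored), call. = FALSE)

  patients <- data.frame(
    patient_id = cohort$patient_id,
    is_female = cohort$is_female,
    baseline_age = cohort$age,
    baseline_tkv = cohort$tkv,
    baseline_egfr = cohort$egfr,
    status = status_chr,
    age_at_esrd = age_esrd,
    cycles = cycles,
    years_stage1 = yrs[, 1L],
    years_stage2 = yrs[, 2L],
    years_stage3 = yrs[, 3L],
    years_stage4 = yrs[, 4L]
  )
  out <- list(patients = patients)
  if (record) out[c("A", "K", "E")] <- list(A, K, E)
  out
}

# Melt recorded state matrices to the long trajectory format. A patient
# contributes one row per cycle in which progression was applied (plus the
# baseline row); the death cycle contributes no row because no update
# occurred in it.
melt_trajectories <- function(res) {
  pts <- res$patients
  tk <- as.vector(t(res$K))
  eg <- as.vector(t(res$E))
  ag <- as.vector(t(res$A))
  cy <- rep(0:(ncol(res$A) - 1L), times = nrow(pts))
  ok <- !is.na(ag)
  df <- data.frame(patient_id = rep(pts$patient_id, each = ncol(res$A))[ok],
                   cycle = cy[ok], age = ag[ok], tkv = tk[ok],
                   egfr = eg[ok])
  df$stage <- ckd_stage(df$egfr)
  df$status <- ifelse(df$stage == "esrd", "esrd", "progressing")
  df
}

# Build per-patient coefficient-draw matrices from each patient's RNG
# substream. Substream layout per patient: TKV-equation z values, then
# eGFR-equation z values, then mortality uniforms (when mortality is on).
draw_patient_streams <- function(cohort, tkv_coeffs, egfr_coeffs, config) {
  n <- nrow(cohort)
  horizon <- config$horizon_years
  m <- if (config$redraw_each_cycle) horizon else 1L
  sampling <- config$sample_coefficients
  if (sampling) {
    vt <- tkv_coeffs$vcov
    if (is.null(vt)) vt <- default_vcov_from_se(tkv_coeffs$se)
    vg <- egfr_coeffs$vcov
    if (is.null(vg)) vg <- default_vcov_from_se(egfr_coeffs$se)
    Lt <- mvn_factor(as.matrix(vt), 5L)
    Lg <- mvn_factor(as.matrix(vg), 2L)
    Zt <- matrix(NA_real_, n, 5L * m)
    Zg <- matrix(NA_real_, n, 2L * m)
  }
  U <- if (config$mortality_enabled) matrix(NA_real_, n, horizon)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, cohort$patient_id[i]))
    if (sampling) {
      Zt[i, ] <- stats::rnorm(5L * m)
      Zg[i, ] <- stats::rnorm(2L * m)
    }
    if (config$mortality_enabled) U[i, ] <- stats::runif(horizon)
  }
  mu_t <- tkv_coeffs$coef
  mu_g <- egfr_coeffs$coef
  if (sampling) {
    B_t <- matrix(NA_real_, n, 5L * m)
    B_g <- matrix(NA_real_, n, 2L * m)
    for (j in seq_len(m)) {
      jt <- (j - 1L) * 5L
      jg <- (j - 1L) * 2L
      B_t[, jt + (1:5)] <- sweep(Zt[, jt + (1:5), drop = FALSE] %*% t(Lt),
                                 2L, mu_t, "+")
      B_g[, jg + (1:2)] <- sweep(Zg[, jg + (1:2), drop = FALSE] %*% t(Lg),
                                 2L, mu_g, "+")
    }
  } else {
    B_t <- matrix(mu_t, n, 5L, byrow = TRUE)
    B_g <- matrix(mu_g, n, 2L, byrow = TRUE)
  }
  list(B_t = B_t, B_g = B_g, U = U)
}

#' Simulate one patient through annual cycles
#'
#' Runs a single patient to ESRD (eGFR < 15), death, or the horizon. A
#' patient whose baseline eGFR is already below 15 is returned immediately
#' with status \code{"esrd"} and zero cycles. The patient's random draws
#' come from an RNG substream derived from \code{(config$seed,
#' patient_id)} unless \code{seed} overrides it, so a one-patient run of
#' [simulate_cohort()] reproduces this function exactly.
#'
#' @param patient A one-row \code{patient_cohort} data frame, or a list
#'   with fields \code{patient_id}, \code{is_female}, \code{age},
#'   \code{tkv}, \code{egfr}.
#' @param tkv_coeffs,egfr_coeffs Coefficient sets (defaults: bundled
#'   TEMPO 3:4 estimates).
#' @param life_table A [life_table()]; required when mortality is enabled.
#' @param config A [simulation_config()].
#' @param seed Optional integer overriding the derived substream seed.
#' @return A \code{simulated_patient} list: \code{final} (one-row outcome
#'   data frame) and \code{trajectory} (per-cycle record with columns
#'   \code{patient_id}, \code{cycle}, \code{age}, \code{tkv}, \code{egfr},
#'   \code{stage}, \code{status}).
#' @export
#' @examples
#' pat <- fixed_profile_cohort(38.7, 1692, 81.61, female_fraction = 0, n = 1)
#' cfg <- simulation_config(seed = 1, sample_coefficients = FALSE,
#'                          mortality_enabled = FALSE)
#' simulate_patient(pat, config = cfg)$final
simulate_patient <- function(patient,
                             tkv_coeffs = tempo34_tkv_coefficients(),
                             egfr_coeffs = tempo34_egfr_coefficients(),
                             life_table = NULL, config, seed = NULL) {
  if (!is.data.frame(patient)) patient <- as.data.frame(patient)
  validate_patient_cohort(patient)
  if (nrow(patient) != 1)
    stop("'patient' must describe exactly one patient", call. = FALSE)
  cfg <- config
  cfg$record_trajectories <- TRUE
  out <- simulate_cohort_internal(patient, tkv_coeffs, egfr_coeffs,
                                  life_table, cfg, override_seed = seed)
  structure(list(final = out$patients,
                 trajectory = out$trajectories),
            class = "simulated_patient")
}

#' @export
print.simulated_patient <- function(x, ...) {
  f <- x$final
  cat(sprintf("<simulated_patient %d: %s after %d cycle(s)>\n",
              f$patient_id, f$status, f$cycles))
  if (!is.na(f$age_at_esrd))
    cat(sprintf("  age at ESRD: %.2f years\n", f$age_at_esrd))
  invisible(x)
}

#' Simulate a cohort of patients
#'
#' Advances every patient in \code{cohort} independently through annual
#' cycles. Each patient's draws come from an RNG substream keyed on
#' \code{(config$seed, patient_id)}: results are therefore invariant to
#' patient ordering, and any patient can be re-simulated alone. When
#' coefficient sampling is enabled, one multivariate-normal draw of each
#' equation's coefficients is made per patient (from the coefficient sets'
#' covariance matrices, or a diagonal SE^2 fallback with a warning).
#'
#' @inheritParams simulate_patient
#' @param cohort A \code{patient_cohort} data frame (at least one patient,
#'   unique ids), e.g. from [sample_baseline_cohort()] or
#'   [fixed_profile_cohort()].
#' @return A \code{cohort_outcomes} object: list with \code{patients} (one
#'   row per patient: baseline snapshot, terminal \code{status} --
#'   \code{"esrd"}, \code{"dead"} or \code{"horizon_censored"} --
#'   \code{age_at_esrd}, \code{cycles}, and per-stage occupancy
#'   \code{years_stage1} .. \code{years_stage4}), \code{trajectories}
#'   (long data frame or \code{NULL}), \code{n}, \code{config}.
#' @seealso [age_at_esrd_summary()], [time_in_stages()],
#'   [lifetime_esrd_incidence()], [cumulative_esrd_by_age()]
#' @export
#' @examples
#' cohort <- fixed_profile_cohort(40, 1500, 80, n = 5)
#' cfg <- simulation_config(seed = 7, mortality_enabled = FALSE)
#' simulate_cohort(cohort, config = cfg)
simulate_cohort <- function(cohort,
                            tkv_coeffs = tempo34_tkv_coefficients(),
                            egfr_coeffs = tempo34_egfr_coefficients(),
                            life_table = NULL, config) {
  simulate_cohort_internal(cohort, tkv_coeffs, egfr_coeffs, life_table,
                           config)
}

simulate_cohort_internal <- function(cohort, tkv_coeffs, egfr_coeffs,
                                     life_table, config,
                                     override_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_patient_cohort(cohort)
  stopifnot(inherits(tkv_coeffs, "coefficient_set"),
            tkv_coeffs$equation == "tkv",
            inherits(egfr_coeffs, "coefficient_set"),
            egfr_coeffs$equation == "egfr")
  if (config$mortality_enabled) {
    if (is.null(life_table))
      stop("mortality is enabled but no life table was supplied",
           call. = FALSE)
    stopifnot(inherits(life_table, "life_table"))
  }
  if (!is.null(override_seed)) {
    # single-patient convenience: draw the whole substream from the given
    # seed instead of the derived hash
    streams <- local({
      cfg2 <- config
      n <- nrow(cohort)
      stopifnot(n == 1)
      set.seed(override_seed)
      draw_patient_streams_seeded(cohort, tkv_coeffs, egfr_coeffs, cfg2)
    })
  } else {
    streams <- draw_patient_streams(cohort, tkv_coeffs, egfr_coeffs, config)
  }
  res <- run_engine(cohort, streams$B_t, streams$B_g, streams$U, life_table,
                    config)
  trajectories <- if (config$record_trajectories) melt_trajectories(res)
  structure(
    list(patients = res$patients, trajectories = trajectories,
         n = nrow(cohort), config = config,
         coefficients = list(tkv = tkv_coeffs$name, egfr = egfr_coeffs$name)),
    class = "cohort_outcomes"
  )
}

# As draw_patient_streams() but consuming the current RNG state rather than
# seeding per patient (used for explicit single-patient seeds).
draw_patient_streams_seeded <- function(cohort, tkv_coeffs, egfr_coeffs,
                                        config) {
  n <- nrow(cohort)
  horizon <- config$horizon_years
  m <- if (config$redraw_each_cycle) horizon else 1L
  sampling <- config$sample_coefficients
  B_t <- matrix(tkv_coeffs$coef, n, 5L, byrow = TRUE)
  B_g <- matrix(egfr_coeffs$coef, n, 2L, byrow = TRUE)
  if (sampling) {
    vt <- tkv_coeffs$vcov
    if (is.null(vt)) vt <- default_vcov_from_se(tkv_coeffs$se)
    vg <- egfr_coeffs$vcov
    if (is.null(vg)) vg <- default_vcov_from_se(egfr_coeffs$se)
    Lt <- mvn_factor(as.matrix(vt), 5L)
    Lg <- mvn_factor(as.matrix(vg), 2L)
    Zt <- matrix(stats::rnorm(5L * m), 1L, 5L * m)
    Zg <- matrix(stats::rnorm(2L * m), 1L, 2L * m)
    B_t <- matrix(NA_real_, n, 5L * m)
    B_g <- matrix(NA_real_, n, 2L * m)
    for (j in seq_len(m)) {
      jt <- (j - 1L) * 5L
      jg <- (j - 1L) * 2L
      B_t[, jt + (1:5)] <- sweep(Zt[, jt + (1:5), drop = FALSE] %*% t(Lt),
                                 2L, tkv_coeffs$coef, "+")
      B_g[, jg + (1:2)] <- sweep(Zg[, jg + (1:2), drop = FALSE] %*% t(Lg),
                                 2L, egfr_coeffs$coef, "+")
    }
  }
  U <- if (config$mortality_enabled)
    matrix(stats::runif(horizon), 1L, horizon)
  list(B_t = B_t, B_g = B_g, U = U)
}

#' @export
print.cohort_outcomes <- function(x, ...) {
  tab <- table(factor(x$patients$status,
                      levels = c("esrd", "dead", "horizon_censored")))
  cat(sprintf("<cohort_outcomes: %d patients (seed %d, horizon %d y)>\n",
              x$n, x$config$seed, x$config$horizon_years))
  cat(sprintf("  ESRD %d (%.1f%%), dead %d, censored %d\n",
              tab[["esrd"]], 100 * tab[["esrd"]] / x$n, tab[["dead"]],
              tab[["horizon_censored"]]))
  if (tab[["esrd"]] > 0)
    cat(sprintf("  mean age at ESRD: %.1f years\n",
                mean(x$patients$age_at_esrd[x$patients$status == "esrd"])))
  invisible(x)
}

#' Write simulated trajectories to CSV
#'
#' Long format, one row per patient-cycle:
#' \code{patient_id,cycle,age,tkv,egfr,stage,status}.
#'
#' @param outcomes A \code{cohort_outcomes} with recorded trajectories.
#' @param path File path.
#' @export
write_trajectories <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  if (is.null(outcomes$trajectories))
    stop("trajectories were not recorded; set record_trajectories = TRUE",
         call. = FALSE)
  utils::write.csv(outcomes$trajectories, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
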