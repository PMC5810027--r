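# Cohort-level outcome aggregation.
#
# Denominator conventions: lifetime incidence and cumulative incidence by
# age use the full cohort (deaths and censored patients included in the
# denominator); age-at-ESRD and stage-occupancy statistics are computed
# over progressors only. Quantiles use linear interpolation between order
# statistics (R type 7).

progressors <- function(outcomes) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  outcomes$patients[outcomes$patients$status == "esrd", , drop = FALSE]
}

#' Summary of age at ESRD onset
#'
#' Mean, median, interquartile range and standard deviation of the age at
#' ESRD onset among patients who reached ESRD. Quantiles (including the
#' IQR endpoints) use linear interpolation between order statistics. With
#' no progressors an empty summary (all \code{NA}, \code{n_progressors =
#' 0}) is returned rather than an error; with a single progressor the SD
#' is reported as 0 and flagged.
#'
#' @param outcomes A \code{cohort_outcomes} from [simulate_cohort()].
#' @return An \code{esrd_age_summary} list: \code{n_progressors},
#'   \code{mean}, \code{median}, \code{iqr_low}, \code{iqr_high},
#'   \code{sd}, \code{single_progressor}.
#' @export
age_at_esrd_summary <- function(outcomes) {
  ages <- progressors(outcomes)$age_at_esrd
  n <- length(ages)
  out <- if (n == 0) {
    list(n_progressors = 0L, mean = NA_real_, median = NA_real_,
         iqr_low = NA_real_, iqr_high = NA_real_, sd = NA_real_,
         single_progressor = FALSE)
  } else {
    q <- stats::quantile(ages, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(n_progressors = n, mean = mean(ages), median = q[2],
         iqr_low = q[1], iqr_high = q[3],
         sd = if (n == 1) 0 else stats::sd(ages),
         single_progressor = n == 1)
  }
  structure(out, class = "esrd_age_summary")
}

#' @export
print.esrd_age_summary <- function(x, ...) {
  if (x$n_progressors == 0) {
    cat("<age at ESRD: no progressors>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<age at ESRD over %d progressor(s)>\n  mean %.1f, median %.1f, IQR %.1f-%.1f, SD %.1f years\n",
    x$n_progressors, x$mean, x$median, x$iqr_low, x$iqr_high, x$sd))
  if (x$single_progressor)
    cat("  (single progressor: SD reported as 0)\n")
  invisible(x)
}

#' Mean years spent in each CKD stage before ESRD
#'
#' Average per-stage occupancy among progressors, plus the mean total time
#' in CKD stages 1-4 (the sum of the four stage means, equal to the mean
#' pre-ESRD simulation time).
#'
#' @param outcomes A \code{cohort_outcomes}.
#' @return List with \code{by_stage} (named vector, stages "1".."4"),
#'   \code{total_ckd1_4}, and \code{n_progressors}. Stage means are
#'   \code{NA} when there are no progressors.
#' @export
time_in_stages <- function(outcomes) {
  pr <- progressors(outcomes)
  cols <- paste0("years_stage", 1:4)
  by_stage <- if (nrow(pr) == 0) {
    stats::setNames(rep(NA_real_, 4), as.character(1:4))
  } else {
    stats::setNames(colMeans(pr[, cols, drop = FALSE]), as.character(1:4))
  }
  list(by_stage = by_stage, total_ckd1_4 = sum(by_stage),
       n_progressors = nrow(pr))
}

#' Cumulative ESRD incidence by age
#'
#' Fraction of the whole cohort (denominator: all patients, including
#' deaths and censored) that has reached ESRD by each given age. The
#' result is non-decreasing in age; its limit for large ages equals
#' [lifetime_esrd_incidence()].
#'
#' @param outcomes A \code{cohort_outcomes}.
#' @param ages Ascending ages (years) at which to evaluate the cumulative
#'   incidence.
#' @return Data frame with columns \code{age} and \code{cum_incidence}.
#' @export
#' @examples
#' # cumulative incidence is evaluated as P(age at ESRD <= age)
cumulative_esrd_by_age <- function(outcomes, ages = c(45, 50, 55, 60, 65)) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  if (is.unsorted(ages))
    stop("'ages' must be sorted ascending", call. = FALSE)
  esrd_age <- outcomes$patients$age_at_esrd[outcomes$patients$status ==
                                              "esrd"]
  ci <- vapply(ages, function(a) sum(esrd_age <= a), numeric(1)) /
    outcomes$n
  data.frame(age = ages, cum_incidence = ci)
}

#' Lifetime ESRD incidence
#'
#' Proportion of the whole simulated cohort whose terminal status is ESRD
#' (rather than death or horizon censoring).
#'
#' @param outcomes A \code{cohort_outcomes}.
#' @return A proportion in [0, 1].
#' @export
lifetime_esrd_incidence <- function(outcomes) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  mean(outcomes$patients$status == "esrd")
}

#' Per-cycle trajectory percentiles
#'
#' Mean, median and 2.5/97.5 percentiles of TKV and eGFR across patients
#' still at risk at each cycle (patients contribute to a cycle while they
#' have a recorded state there; trajectories end at ESRD, death or the
#' horizon). The 95% band is a Monte-Carlo prediction interval reflecting
#' baseline heterogeneity and coefficient-draw variability.
#'
#' @param x A \code{cohort_outcomes} with recorded trajectories, or a long
#'   trajectory data frame with columns \code{cycle}, \code{tkv},
#'   \code{egfr}.
#' @return A \code{trajectory_summary} data frame, one row per cycle:
#'   \code{cycle}, \code{n_at_risk}, then \code{mean}, \code{median},
#'   \code{p2.5}, \code{p97.5} for TKV and eGFR.
#' @export
trajectory_summary <- function(x) {
  traj <- if (inherits(x, "cohort_outcomes")) {
    if (is.null(x$trajectories))
      stop("trajectories were not recorded; set record_trajectories = TRUE",
           call. = FALSE)
    x$trajectories
  } else {
    x
  }
  stopifnot(is.data.frame(traj),
            all(c("cycle", "tkv", "egfr") %in% names(traj)))
  if (nrow(traj) == 0) stop("no trajectory rows", call. = FALSE)
  per_cycle <- function(v) {
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    c(mean = mean(v), median = q[2], p2.5 = q[1], p97.5 = q[3])
  }
  cyc <- sort(unique(traj$cycle))
  rows <- lapply(cyc, function(cc) {
    sub <- traj[traj$cycle == cc, ]
    c(cycle = cc, n_at_risk = nrow(sub),
      stats::setNames(per_cycle(sub$tkv),
                      c("tkv_mean", "tkv_median", "tkv_p2.5", "tkv_p97.5")),
      stats::setNames(per_cycle(sub$egfr),
                      c("egfr_mean", "egfr_median", "egfr_p2.5",
                        "egfr_p97.5")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' Run a grid of simulation scenarios
#'
#' Simulates every combination of the varied baseline parameters (Cartesian
#' product) and summarizes each cell: mean and median age at ESRD onset and
#' lifetime ESRD incidence. All cells share the same configuration seed
#' (common random numbers), so differences between cells isolate the
#' parameter effects; a cell varied by 0% reproduces the base cell exactly.
#'
#' @param base A [baseline_cohort_spec()] or a fixed-profile list with
#'   fields \code{age}, \code{tkv}, \code{egfr}, \code{female_fraction},
#'   \code{n}.
#' @param vary Named list of value vectors; names must be fields of
#'   \code{base} (e.g. \code{list(tkv = c(1000, 1500, 2000))}).
#' @param tkv_coeffs,egfr_coeffs Coefficient sets.
#' @param life_table A [life_table()] when mortality is enabled.
#' @param config A [simulation_config()].
#' @return Data frame, one row per grid cell: the varied parameter values,
#'   \code{n_progressors}, \code{mean_age_esrd}, \code{median_age_esrd},
#'   \code{lifetime_incidence}.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 3, mortality_enabled = FALSE)
#' base <- list(age = 40, tkv = 1500, egfr = 80, female_fraction = 0.5,
#'              n = 50)
#' scenario_grid(base, list(tkv = c(1000, 2000)), config = cfg)
scenario_grid <- function(base, vary,
                          tkv_coeffs = tempo34_tkv_coefficients(),
                          egfr_coeffs = tempo34_egfr_coefficients(),
                          life_table = NULL, config) {
  if (!is.list(vary) || length(vary) < 1 || is.null(names(vary)) ||
      any(names(vary) == ""))
    stop("'vary' must be a non-empty named list of value vectors",
         call. = FALSE)
  if (any(lengths(vary) == 0))
    stop("'vary' contains an empty value list for: ",
         paste(names(vary)[lengths(vary) == 0], collapse = ", "),
         call. = FALSE)
  is_spec <- inherits(base, "cohort_spec")
  base_fields <- if (is_spec) {
    setdiff(names(unclass(base)), c("bounds", "correlation"))
  } else {
    c("age", "tkv", "egfr", "female_fraction", "n")
  }
  unknown <- setdiff(names(vary), base_fields)
  if (length(unknown))
    stop("'vary' names not present in the base scenario: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grid <- expand.grid(vary, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  summaries <- lapply(seq_len(nrow(grid)), function(i) {
    b <- base
    for (nm in names(vary)) b[[nm]] <- grid[[nm]][i]
    cohort <- if (is_spec) {
      sample_baseline_cohort(b, seed = config$seed)
    } else {
      fixed_profile_cohort(b$age, b$tkv, b$egfr, b$female_fraction, b$n)
    }
    out <- simulate_cohort(cohort, tkv_coeffs, egfr_coeffs, life_table,
                           config)
    s <- age_at_esrd_summary(out)
    data.frame(n_progressors = s$n_progressors, mean_age_esrd = s$mean,
               median_age_esrd = s$median,
               lifetime_incidence = lifetime_esrd_incidence(out))
  })
  cbind(grid, do.call(rbind, summaries))
}

#' Machine-readable summary of a cohort run
#'
#' Collects the headline outputs (status counts, age-at-ESRD summary,
#' stage occupancy, cumulative and lifetime incidence) into one list,
#' suitable for JSON serialization.
#'
#' @param outcomes A \code{cohort_outcomes}.
#' @param ages Ages for the cumulative-incidence section.
#' @return A nested list.
#' @export
outcome_summary <- function(outcomes, ages = c(45, 50, 55, 60, 65)) {
  stopifnot(inherits(outcomes, "cohort_outcomes"))
  s <- age_at_esrd_summary(outcomes)
  tis <- time_in_stages(outcomes)
  ci <- cumulative_esrd_by_age(outcomes, ages)
  list(
    n = outcomes$n,
    seed = outcomes$config$seed,
    status_counts = as.list(table(outcomes$patients$status)),
    age_at_esrd = s[c("n_progressors", "mean", "median", "iqr_low",
                      "iqr_high", "sd")],
    mean_years_in_stage = as.list(tis$by_stage),
    mean_years_ckd1_4 = tis$total_ckd1_4,
    cumulative_incidence = stats::setNames(as.list(ci$cum_incidence),
                                           paste0("by_age_", ci$age)),
    lifetime_incidence = lifetime_esrd_incidence(outcomes)
  )
}
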