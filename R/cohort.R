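# Baseline cohort generation from summary statistics.
#
# Only mean +- SD summaries of the fitting cohort are published, so baseline
# age, TKV and eGFR are drawn from independent truncated normal
# distributions (moments are those of the untruncated parent); sex is
# Bernoulli. An optional correlation matrix couples the three continuous
# variables through a Gaussian copula over the truncated marginals.

#' Baseline cohort specification
#'
#' Distributional description of a patient cohort at baseline: means and SDs
#' of age, TKV and eGFR (of the untruncated normal parents), the male
#' fraction, per-variable truncation bounds, and the cohort size.
#'
#' Default bounds are age 18--60 years, TKV 300--8000 mL and eGFR 20--150
#' mL/min/1.73 m^2: wide enough to leave the published moments essentially
#' unchanged while excluding clinically impossible baselines.
#'
#' @param n Number of patients.
#' @param mean_age,sd_age Age moments (years).
#' @param mean_tkv,sd_tkv TKV moments (mL).
#' @param mean_egfr,sd_egfr eGFR moments (mL/min/1.73 m^2).
#' @param male_fraction Probability that a patient is male.
#' @param bounds Named list with elements \code{age}, \code{tkv},
#'   \code{egfr}, each a \code{c(low, high)} pair with \code{low < high}.
#' @param correlation Optional 3x3 correlation matrix for (age, tkv, egfr),
#'   applied as a Gaussian copula; \code{NULL} (the default) samples the
#'   three variables independently.
#' @return An object of class \code{cohort_spec}.
#' @seealso [tempo34_cohort_spec()], [sample_baseline_cohort()]
#' @export
baseline_cohort_spec <- function(n,
                                 mean_age = 38.7, sd_age = 7.1,
                                 mean_tkv = 1692, sd_tkv = 905,
                                 mean_egfr = 81.61, sd_egfr = 21.60,
                                 male_fraction = 0.516,
                                 bounds = default_cohort_bounds(),
                                 correlation = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  sds <- c(sd_age, sd_tkv, sd_egfr)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  if (!is.finite(male_fraction) || male_fraction < 0 || male_fraction > 1)
    stop("'male_fraction' must lie in [0, 1]", call. = FALSE)
  for (v in c("age", "tkv", "egfr")) {
    b <- bounds[[v]]
    if (is.null(b) || length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2])
      stop(sprintf("bounds$%s must be c(low, high) with low < high", v),
           call. = FALSE)
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    check_vcov(correlation, 3L)
    if (max(abs(diag(correlation) - 1)) > 1e-8)
      stop("'correlation' must have unit diagonal", call. = FALSE)
  }
  structure(
    list(n = as.integer(n),
         mean_age = mean_age, sd_age = sd_age,
         mean_tkv = mean_tkv, sd_tkv = sd_tkv,
         mean_egfr = mean_egfr, sd_egfr = sd_egfr,
         male_fraction = male_fraction,
         bounds = bounds[c("age", "tkv", "egfr")],
         correlation = correlation),
    class = "cohort_spec"
  )
}

#' @rdname baseline_cohort_spec
#' @export
default_cohort_bounds <- function() {
  list(age = c(18, 60), tkv = c(300, 8000), egfr = c(20, 150))
}

#' TEMPO 3:4-matched baseline cohort specification
#'
#' The overall TEMPO 3:4 study cohort at baseline: age 38.7 +- 7.1 years,
#' TKV 1692 +- 905 mL, eGFR 81.61 +- 21.60 mL/min/1.73 m^2, 51.6% male.
#'
#' @param n Number of patients (default 10,000).
#' @return A [baseline_cohort_spec()].
#' @export
#' @examples
#' tempo34_cohort_spec(n = 100)
tempo34_cohort_spec <- function(n = 10000) {
  baseline_cohort_spec(n = n)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec: n = %d>\n", x$n))
  cat(sprintf("  age  %.2f +- %.2f y   bounds [%g, %g]\n",
              x$mean_age, x$sd_age, x$bounds$age[1], x$bounds$age[2]))
  cat(sprintf("  TKV  %.0f +- %.0f mL  bounds [%g, %g]\n",
              x$mean_tkv, x$sd_tkv, x$bounds$tkv[1], x$bounds$tkv[2]))
  cat(sprintf("  eGFR %.2f +- %.2f    bounds [%g, %g]\n",
              x$mean_egfr, x$sd_egfr, x$bounds$egfr[1], x$bounds$egfr[2]))
  cat(sprintf("  male fraction %.3f%s\n", x$male_fraction,
              if (is.null(x$correlation)) "" else "; correlated marginals"))
  invisible(x)
}

# Truncated-normal inverse-CDF transform of uniforms; sd = 0 collapses to
# the mean (which must respect the bounds).
.qtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop(sprintf("degenerate distribution (sd = 0) has mean %g outside ",
                   mean), sprintf("bounds [%g, %g]", lo, hi), call. = FALSE)
    return(rep(mean, length(u)))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12)
    stop(sprintf(
      "infeasible bounds [%g, %g]: no probability mass under N(%g, %g)",
      lo, hi, mean, sd), call. = FALSE)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Sample a baseline cohort from a specification
#'
#' Draws \code{spec$n} patients: age, TKV and eGFR from truncated normal
#' distributions (independent unless \code{spec$correlation} is set, in
#' which case a Gaussian copula couples them), and sex from a Bernoulli
#' distribution with the specified male fraction. Fully reproducible from
#' the seed.
#'
#' @param spec A [baseline_cohort_spec()].
#' @param seed Optional integer seed.
#' @return A \code{patient_cohort} data frame with columns
#'   \code{patient_id}, \code{is_female}, \code{age}, \code{tkv},
#'   \code{egfr}.
#' @export
#' @examples
#' head(sample_baseline_cohort(tempo34_cohort_spec(n = 5), seed = 1))
sample_baseline_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  if (is.null(spec$correlation)) {
    u <- list(age = stats::runif(n), tkv = stats::runif(n),
              egfr = stats::runif(n))
  } else {
    L <- mvn_factor(spec$correlation, 3L)
    Z <- matrix(stats::rnorm(3L * n), ncol = 3L, byrow = TRUE) %*% t(L)
    u <- list(age = stats::pnorm(Z[, 1L]), tkv = stats::pnorm(Z[, 2L]),
              egfr = stats::pnorm(Z[, 3L]))
  }
  age <- .qtruncnorm(u$age, spec$mean_age, spec$sd_age,
                     spec$bounds$age[1], spec$bounds$age[2])
  tkv <- .qtruncnorm(u$tkv, spec$mean_tkv, spec$sd_tkv,
                     spec$bounds$tkv[1], spec$bounds$tkv[2])
  egfr <- .qtruncnorm(u$egfr, spec$mean_egfr, spec$sd_egfr,
                      spec$bounds$egfr[1], spec$bounds$egfr[2])
  is_female <- stats::runif(n) >= spec$male_fraction
  new_patient_cohort(seq_len(n), is_female, age, tkv, egfr)
}

#' Cohort of patients with identical renal characteristics
#'
#' Builds \code{n} patients sharing one baseline profile; only sex varies.
#' Sex is assigned deterministically -- the first
#' \code{ceiling(female_fraction * n)} patients are female -- so a fixed
#' profile cohort involves no random number generation and downstream
#' variability comes only from coefficient sampling and mortality.
#'
#' @param age Baseline age in years.
#' @param tkv Baseline TKV in mL (positive).
#' @param egfr Baseline eGFR in mL/min/1.73 m^2 (non-negative).
#' @param female_fraction Fraction of female patients.
#' @param n Number of patients (\code{>= 1}).
#' @return A \code{patient_cohort} data frame.
#' @export
#' @examples
#' fixed_profile_cohort(40, 1500, 80, female_fraction = 0.5, n = 2)
fixed_profile_cohort <- function(age, tkv, egfr, female_fraction = 0.5,
                                 n = 1000) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  check_progression_inputs(tkv, age)
  if (!is.finite(egfr) || egfr < 0)
    stop("'egfr' must be finite and non-negative", call. = FALSE)
  if (!is.finite(female_fraction) || female_fraction < 0 ||
      female_fraction > 1)
    stop("'female_fraction' must lie in [0, 1]", call. = FALSE)
  n_female <- ceiling(female_fraction * n)
  new_patient_cohort(seq_len(n),
                     is_female = seq_len(n) <= n_female,
                     age = rep(age, n), tkv = rep(tkv, n),
                     egfr = rep(egfr, n))
}

new_patient_cohort <- function(patient_id, is_female, age, tkv, egfr) {
  structure(
    data.frame(patient_id = as.integer(patient_id),
               is_female = as.logical(is_female),
               age = age, tkv = tkv, egfr = egfr),
    class = c("patient_cohort", "data.frame")
  )
}

validate_patient_cohort <- function(cohort) {
  req <- c("patient_id", "is_female", "age", "tkv", "egfr")
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(cohort) < 1) stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(cohort$patient_id))
    stop("cohort has duplicated patient_id values", call. = FALSE)
  with(cohort, {
    if (any(!is.finite(age)) || any(age < 0))
      stop("cohort ages must be finite and non-negative", call. = FALSE)
    if (any(!is.finite(tkv)) || any(tkv <= 0))
      stop("cohort TKV values must be finite and positive", call. = FALSE)
    if (any(!is.finite(egfr)) || any(egfr < 0))
      stop("cohort eGFR values must be finite and non-negative",
           call. = FALSE)
  })
  invisible(cohort)
}

#' Read or write a patient cohort as CSV
#'
#' Plain CSV with header \code{patient_id,is_female,age,tkv,egfr};
#' \code{is_female} serialized as \code{TRUE}/\code{FALSE}.
#'
#' @param path File path.
#' @return \code{read_cohort} returns a \code{patient_cohort};
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_patient_cohort(df)
  new_patient_cohort(df$patient_id, as.logical(df$is_female), df$age,
                     df$tkv, df$egfr)
}

#' @rdname read_cohort
#' @param cohort A \code{patient_cohort} data frame.
#' @export
write_cohort <- function(cohort, path) {
  validate_patient_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, c("patient_id", "is_female",
                                             "age", "tkv", "egfr")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
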