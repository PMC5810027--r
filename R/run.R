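# Reproducible end-to-end runs from a YAML configuration, plus fixture
# generation and the bundled illustrative patient profiles.

#' Read and validate a run configuration
#'
#' YAML layout (all simulation fields optional except \code{seed}):
#' \preformatted{
#' seed: 1
#' horizon_years: 80
#' sample_coefficients: true
#' mortality_enabled: true
#' record_trajectories: false
#' cohort:
#'   preset: tempo34        # or csv: path, or spec: {...}, or profile: {...}
#'   n: 10000
#' coefficients:
#'   tkv: default           # or a path to a coefficient JSON
#'   egfr: default
#' life_table: synthetic    # or a path to a life-table CSV
#' output_dir: adpkdsim-output
#' reports: [summary, outcomes]
#' }
#' Validation failures name the offending field.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{run_config} list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("config field '%s': %s", field, why), call. = FALSE)
  if (is.null(cfg$seed)) fail("seed", "is mandatory")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    fail("seed", "must be an integer")
  defaults <- list(horizon_years = 80L, sample_coefficients = TRUE,
                   mortality_enabled = TRUE, record_trajectories = FALSE,
                   output_dir = "adpkdsim-output",
                   reports = c("summary", "outcomes"),
                   life_table = "synthetic",
                   coefficients = list(tkv = "default", egfr = "default"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$coefficients$tkv)) cfg$coefficients$tkv <- "default"
  if (is.null(cfg$coefficients$egfr)) cfg$coefficients$egfr <- "default"
  if (is.null(cfg$cohort)) fail("cohort", "is mandatory")
  # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
  fix_n_key <- function(l) {
    if (!is.null(l)) names(l)[names(l) %in% c("FALSE", "F")] <- "n"
    l
  }
  cfg$cohort <- fix_n_key(cfg$cohort)
  cfg$cohort$spec <- fix_n_key(cfg$cohort$spec)
  cfg$cohort$profile <- fix_n_key(cfg$cohort$profile)
  src <- intersect(names(cfg$cohort), c("preset", "csv", "spec", "profile"))
  if (length(src) != 1)
    fail("cohort", "must have exactly one of: preset, csv, spec, profile")
  if (src == "preset" && !identical(cfg$cohort$preset, "tempo34") &&
      !cfg$cohort$preset %in% names(preset_profiles()))
    fail("cohort.preset", sprintf(
      "unknown preset '%s' (valid: tempo34, %s)", cfg$cohort$preset,
      paste(names(preset_profiles()), collapse = ", ")))
  if (src == "csv" && !file.exists(cfg$cohort$csv))
    fail("cohort.csv", sprintf("file '%s' does not exist", cfg$cohort$csv))
  for (eq in c("tkv", "egfr")) {
    p <- cfg$coefficients[[eq]]
    if (!identical(p, "default") && !file.exists(p))
      fail(paste0("coefficients.", eq),
           sprintf("file '%s' does not exist", p))
  }
  if (!identical(cfg$life_table, "synthetic") &&
      !file.exists(cfg$life_table)) {
    why <- sprintf("file '%s' does not exist", cfg$life_table)
    if (isTRUE(cfg$mortality_enabled))
      fail("life_table", paste0(why, " (required: mortality is enabled)"))
    fail("life_table", why)
  }
  bad <- setdiff(cfg$reports, c("summary", "outcomes", "trajectories"))
  if (length(bad))
    fail("reports", paste("unknown report(s):", paste(bad, collapse = ", ")))
  if ("trajectories" %in% cfg$reports) cfg$record_trajectories <- TRUE
  structure(cfg, class = "run_config")
}

build_cohort_from_config <- function(cfg) {
  ch <- cfg$cohort
  if (!is.null(ch$preset)) {
    if (identical(ch$preset, "tempo34")) {
      n <- if (is.null(ch$n)) 10000L else as.integer(ch$n)
      return(sample_baseline_cohort(tempo34_cohort_spec(n = n),
                                    seed = cfg$seed))
    }
    pr <- preset_profiles()[[ch$preset]]
    n <- if (is.null(ch$n)) pr$n else as.integer(ch$n)
    return(fixed_profile_cohort(pr$age, pr$tkv, pr$egfr,
                                pr$female_fraction, n))
  }
  if (!is.null(ch$csv)) return(read_cohort(ch$csv))
  if (!is.null(ch$spec)) {
    sp <- do.call(baseline_cohort_spec, ch$spec)
    return(sample_baseline_cohort(sp, seed = cfg$seed))
  }
  do.call(fixed_profile_cohort, ch$profile)
}

#' Run a full simulation from a configuration
#'
#' Loads the configured coefficient sets, life table and cohort, simulates,
#' prints the headline summary, and writes the requested reports to the
#' output directory: \code{outcomes.csv} (one row per patient),
#' \code{summary.json}, and optionally \code{trajectories.csv}. The log
#' line records the seed, a config fingerprint and the package version;
#' identical configurations and seeds produce byte-identical outputs.
#'
#' @param config Path to a YAML file, or a list as returned by
#'   [read_run_config()].
#' @param output_dir Optional override of the configured output directory.
#' @return The \code{cohort_outcomes}, invisibly.
#' @export
run_simulation <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir

  tkv_coeffs <- if (identical(cfg$coefficients$tkv, "default"))
    tempo34_tkv_coefficients() else read_coefficients(cfg$coefficients$tkv)
  egfr_coeffs <- if (identical(cfg$coefficients$egfr, "default"))
    tempo34_egfr_coefficients() else read_coefficients(cfg$coefficients$egfr)
  table <- if (identical(cfg$life_table, "synthetic"))
    synthetic_uk_like_table() else load_life_table(cfg$life_table)

  cohort <- build_cohort_from_config(cfg)
  sim_cfg <- simulation_config(
    seed = cfg$seed, horizon_years = cfg$horizon_years,
    sample_coefficients = cfg$sample_coefficients,
    mortality_enabled = cfg$mortality_enabled,
    record_trajectories = cfg$record_trajectories)

  n_extrap <- sum(cohort$age > 50 | cohort$tkv < 750)
  if (n_extrap > 0)
    message(sprintf(
      "INFO: %d of %d baseline patients lie outside the fitting domain (age > 50 or TKV < 750 mL); predictions there are extrapolations",
      n_extrap, nrow(cohort)))

  outcomes <- simulate_cohort(cohort, tkv_coeffs, egfr_coeffs, table,
                              sim_cfg)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if ("outcomes" %in% cfg$reports)
    utils::write.csv(outcomes$patients,
                     file.path(cfg$output_dir, "outcomes.csv"),
                     row.names = FALSE, quote = FALSE)
  if ("summary" %in% cfg$reports)
    jsonlite::write_json(outcome_summary(outcomes),
                         file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if ("trajectories" %in% cfg$reports)
    write_trajectories(outcomes,
                       file.path(cfg$output_dir, "trajectories.csv"))

  message(sprintf("INFO: seed %d | config %s | adpkdsim %s | n %d",
                  cfg$seed, config_fingerprint(cfg),
                  as.character(utils::packageVersion("adpkdsim")),
                  outcomes$n))
  s <- age_at_esrd_summary(outcomes)
  cat(sprintf("Simulated %d patients over %d years\n", outcomes$n,
              cfg$horizon_years))
  if (s$n_progressors > 0) {
    cat(sprintf(
      "Mean age at ESRD onset: %.1f years (median %.1f; IQR %.1f-%.1f; SD %.1f)\n",
      s$mean, s$median, s$iqr_low, s$iqr_high, s$sd))
    cat(sprintf("Lifetime ESRD incidence: %.1f%%\n",
                100 * lifetime_esrd_incidence(outcomes)))
  } else {
    cat("No patient reached ESRD\n")
  }
  invisible(outcomes)
}

# Short deterministic fingerprint of a config list for the run log.
config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97)) %%
            .Machine$integer.max)
}

#' Generate deterministic fixture files
#'
#' Writes small synthetic input files for tests and documentation:
#' \describe{
#'   \item{\code{"life-table"}}{a [synthetic_uk_like_table()] CSV
#'     (\code{params} are passed through to the generator).}
#'   \item{\code{"cohort"}}{a TEMPO 3:4-matched sampled cohort CSV
#'     (\code{params$n}, default 10).}
#'   \item{\code{"toy-trajectories"}}{a long trajectory CSV from a small
#'     fixed-profile cohort run (\code{params$n}, default 3).}
#' }
#' Identical seeds give identical files.
#'
#' @param kind One of the kinds above.
#' @param path Output file path.
#' @param seed Integer seed.
#' @param params Optional list of generator parameters.
#' @return \code{path}, invisibly.
#' @export
generate_fixtures <- function(kind, path, seed = 1, params = list()) {
  kinds <- c("life-table", "cohort", "toy-trajectories")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds)
    stop("unknown fixture kind '", paste(kind, collapse = ","),
         "'; valid kinds: ", paste(kinds, collapse = ", "), call. = FALSE)
  switch(kind,
    "life-table" = {
      table <- do.call(synthetic_uk_like_table, params)
      write_life_table(table, path)
    },
    "cohort" = {
      n <- if (is.null(params$n)) 10L else as.integer(params$n)
      write_cohort(sample_baseline_cohort(tempo34_cohort_spec(n = n),
                                          seed = seed), path)
    },
    "toy-trajectories" = {
      n <- if (is.null(params$n)) 3L else as.integer(params$n)
      cohort <- fixed_profile_cohort(40, 1500, 80, 0.5, n)
      cfg <- simulation_config(seed = seed, mortality_enabled = FALSE,
                               record_trajectories = TRUE)
      out <- simulate_cohort(cohort, config = cfg)
      write_trajectories(out, path)
    })
  invisible(path)
}

#' Bundled illustrative patient profiles
#'
#' Three fixed-profile cohorts spanning the clinical spectrum the model is
#' meant to discriminate: a rapidly progressing patient (high TKV, reduced
#' eGFR), a young patient with kidneys large for their age, and an older
#' patient with preserved renal function. The numeric baselines are
#' representative choices for those descriptions, not published values.
#' Simulated mean age at ESRD is earliest for the rapid profile and latest
#' for the older preserved profile.
#'
#' @return Named list of profile lists (\code{age}, \code{tkv},
#'   \code{egfr}, \code{female_fraction}, \code{n}, \code{description}),
#'   usable as the \code{base} of [scenario_grid()] or via
#'   [fixed_profile_cohort()].
#' @export
#' @examples
#' names(preset_profiles())
preset_profiles <- function() {
  list(
    rapid = list(
      age = 45, tkv = 2500, egfr = 45, female_fraction = 0.5, n = 1000,
      description = "rapidly progressing patient: high TKV, low eGFR"),
    young = list(
      age = 28, tkv = 1600, egfr = 95, female_fraction = 0.5, n = 1000,
      description = "young patient with large kidneys for their age"),
    older_preserved = list(
      age = 55, tkv = 1700, egfr = 78, female_fraction = 0.5, n = 1000,
      description = "older patient with preserved renal function")
  )
}
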