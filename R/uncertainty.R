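# Multivariate-normal sampling of progression-equation coefficients.
#
# One coefficient draw per simulated patient induces the inter-patient
# trajectory variability of the model: patients with identical baseline
# characteristics follow different TKV/eGFR paths.

#' Diagonal covariance matrix from standard errors
#'
#' Fallback covariance when a coefficient set carries standard errors but no
#' full variance-covariance matrix: a diagonal matrix of squared SEs. A
#' warning is emitted because off-diagonal terms of regression-coefficient
#' covariances are typically large and negative (intercept versus slopes),
#' so a diagonal approximation overstates predictive dispersion
#' substantially; prefer a full matrix (see [reconstruct_vcov()]).
#'
#' @param se Vector of non-negative standard errors.
#' @return Diagonal matrix \code{diag(se^2)}.
#' @export
#' @examples
#' suppressWarnings(default_vcov_from_se(c(0.08244, 0.01124)))
default_vcov_from_se <- function(se) {
  if (!is.numeric(se) || length(se) < 1 || any(!is.finite(se)))
    stop("'se' must be a finite numeric vector", call. = FALSE)
  if (any(se < 0))
    stop("standard errors must be non-negative", call. = FALSE)
  warning("building a diagonal covariance from standard errors: ",
          "off-diagonal covariance terms are omitted, which typically ",
          "overstates coefficient-draw dispersion", call. = FALSE)
  v <- diag(se^2, nrow = length(se))
  dimnames(v) <- list(names(se), names(se))
  v
}

# Matrix square root of a PSD covariance via symmetric eigendecomposition;
# tolerates rank deficiency (zero-variance coefficients stay constant).
mvn_factor <- function(vcov, k) {
  check_vcov(vcov, k)
  ed <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE)
  ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k)
}

#' Sample progression-equation coefficients
#'
#' Draws \code{n} coefficient vectors from a multivariate normal
#' distribution centred on the point estimates of \code{coeffs}, using a
#' matrix square root (eigendecomposition) of the covariance. The covariance
#' used is, in order of preference: the \code{vcov} argument, the matrix
#' attached to \code{coeffs}, or a diagonal matrix of squared standard
#' errors via [default_vcov_from_se()] (with its warning).
#'
#' @param coeffs A [coefficient_set][tkv_coefficients()].
#' @param n Number of draws (\code{>= 1}).
#' @param vcov Optional covariance matrix overriding the one in
#'   \code{coeffs}.
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return A \code{coefficient_draws} object: list with \code{draws}
#'   (\code{n} x k matrix, one row per draw), \code{point},
#'   \code{equation}.
#' @export
#' @examples
#' cs <- tempo34_egfr_coefficients()
#' d <- sample_coefficients(cs, n = 5, seed = 1)
#' d$draws
sample_coefficients <- function(coeffs, n, vcov = NULL, seed = NULL) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  mu <- coeffs$coef
  k <- length(mu)
  if (is.null(vcov)) vcov <- coeffs$vcov
  if (is.null(vcov)) {
    if (is.null(coeffs$se))
      stop("no covariance available: supply 'vcov' or a coefficient set ",
           "with standard errors", call. = FALSE)
    vcov <- default_vcov_from_se(coeffs$se)
  }
  L <- mvn_factor(as.matrix(vcov), k)
  if (!is.null(seed)) set.seed(seed)
  # one draw per row; z values consumed consecutively per draw, matching the
  # per-patient substream layout used by the simulation engine
  Z <- matrix(stats::rnorm(n * k), ncol = k, byrow = TRUE)
  draws <- sweep(Z %*% t(L), 2L, mu, "+")
  colnames(draws) <- names(mu)
  structure(list(equation = coeffs$equation, point = mu, draws = draws),
            class = "coefficient_draws")
}

#' @export
print.coefficient_draws <- function(x, ...) {
  cat(sprintf("<coefficient_draws: %d draws of the %s equation>\n",
              nrow(x$draws), x$equation))
  cat("  empirical means:\n")
  print(colMeans(x$draws), ...)
  invisible(x)
}

#' Reconstruct a regression coefficient covariance from standard errors
#'
#' Builds a synthetic variance-covariance matrix for progression-equation
#' coefficients when only the standard errors are published. Regression
#' coefficient estimates are strongly correlated -- with uncentred
#' covariates the intercept and slope estimates are near-perfectly
#' anticorrelated -- and those correlations are determined by the design
#' matrix, not the residual variance:
#' \eqn{cov(\hat\beta) = \sigma^2 (X'X)^{-1}}. This function simulates a
#' large design matrix \eqn{X} from a baseline cohort specification matched
#' to the fitting cohort, takes the correlation structure of
#' \eqn{(X'X)^{-1}}, and rescales it so the implied standard errors equal
#' the published ones exactly:
#' \deqn{\Sigma = D\, corr\{(X'X)^{-1}\}\, D, \quad D = diag(se).}
#'
#' The result is synthetic -- it reproduces the published marginal standard
#' errors and the design-implied correlations, not the unpublished fitted
#' matrix.
#'
#' @param equation \code{"tkv"} (design columns: intercept, age, ln TKV,
#'   female, age x ln TKV) or \code{"egfr"} (intercept, ln TKV).
#' @param se Published standard errors (length 5 for \code{"tkv"}, 2 for
#'   \code{"egfr"}).
#' @param spec A [baseline_cohort_spec()] describing the fitting cohort;
#'   its \code{n} is ignored in favour of \code{n_design}.
#' @param n_design Number of simulated design rows (large, for stable
#'   moments).
#' @param seed Integer seed for the design simulation.
#' @return A symmetric positive semi-definite covariance matrix.
#' @export
#' @examples
#' spec <- baseline_cohort_spec(n = 1, mean_age = 39, sd_age = 7,
#'                              mean_tkv = 1668, sd_tkv = 873,
#'                              male_fraction = 0.519)
#' v <- reconstruct_vcov("egfr", c(0.08244, 0.01124), spec,
#'                       n_design = 5000, seed = 1)
#' sqrt(diag(v)) # equals the supplied standard errors
reconstruct_vcov <- function(equation = c("tkv", "egfr"), se, spec,
                             n_design = 200000, seed = 484) {
  equation <- match.arg(equation)
  k <- if (equation == "tkv") 5L else 2L
  if (length(se) != k)
    stop(sprintf("'se' must have length %d for the %s equation", k,
                 equation), call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("'se' must be finite and positive", call. = FALSE)
  stopifnot(inherits(spec, "cohort_spec"))
  spec$n <- as.integer(n_design)
  cohort <- sample_baseline_cohort(spec, seed = seed)
  X <- if (equation == "tkv") {
    cbind(1, cohort$age, log(cohort$tkv), as.numeric(cohort$is_female),
          cohort$age * log(cohort$tkv))
  } else {
    cbind(1, log(cohort$tkv))
  }
  R <- stats::cov2cor(solve(crossprod(X) / nrow(X)))
  v <- outer(se, se) * R
  nm <- if (equation == "tkv") TKV_COEF_NAMES else EGFR_COEF_NAMES
  dimnames(v) <- list(nm, nm)
  v
}
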