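# Coefficient sets for the two annual-change progression equations.
#
# The TKV equation predicts the 1-year change in total kidney volume,
#   dTKV = exp(lambda + alpha*age + beta*ln(TKV) + gamma*[female]
#              + delta*age*ln(TKV)) - 500,
# and the eGFR equation the 1-year change in kidney function,
#   dEGFR = exp(lambda + beta*ln(TKV)) - 60.
# Both were fitted on offset annual changes (TKV + 500, eGFR + 60) so the
# linear predictor is exponentiated and the offset subtracted.

TKV_COEF_NAMES <- c("lambda", "alpha", "beta", "gamma", "delta")
EGFR_COEF_NAMES <- c("lambda", "beta")

#' Create a coefficient set for the TKV progression equation
#'
#' Bundles the five coefficients of the annual TKV change equation
#' \deqn{\Delta TKV = \exp(\lambda + \alpha\,age + \beta\,\ln TKV +
#'   \gamma\,[female] + \delta\,age\cdot\ln TKV) - 500}
#' together with optional standard errors and an optional variance-covariance
#' matrix used for multivariate-normal coefficient sampling.
#'
#' @param lambda Intercept.
#' @param alpha Coefficient per year of age.
#' @param beta Coefficient per unit \code{ln(TKV)}.
#' @param gamma Coefficient for the female indicator (female = 1, male = 0).
#' @param delta Coefficient for the age-by-\code{ln(TKV)} interaction.
#' @param se Optional vector of five non-negative standard errors, in the
#'   order lambda, alpha, beta, gamma, delta.
#' @param vcov Optional 5x5 symmetric positive semi-definite covariance
#'   matrix in the same order.
#' @param name Label carried through to printed output and serialized files.
#' @return An object of class \code{coefficient_set}.
#' @seealso [tempo34_tkv_coefficients()] for the bundled default values,
#'   [annual_tkv_change()] for the equation itself.
#' @export
#' @examples
#' # a null equation: exp(log(500)) - 500 == 0 for every input
#' tkv_coefficients(log(500), 0, 0, 0, 0, name = "null")
tkv_coefficients <- function(lambda, alpha, beta, gamma, delta,
                             se = NULL, vcov = NULL, name = "custom") {
  coef <- c(lambda = lambda, alpha = alpha, beta = beta,
            gamma = gamma, delta = delta)
  new_coefficient_set(coef, se, vcov, equation = "tkv", name = name)
}

#' Create a coefficient set for the eGFR progression equation
#'
#' Bundles the two coefficients of the annual eGFR change equation
#' \deqn{\Delta eGFR = \exp(\lambda + \beta\,\ln TKV) - 60}
#' with optional standard errors and covariance matrix.
#'
#' @param lambda Intercept.
#' @param beta Coefficient per unit \code{ln(TKV)}.
#' @param se Optional vector of two non-negative standard errors.
#' @param vcov Optional 2x2 symmetric positive semi-definite matrix.
#' @param name Label for printing and serialization.
#' @return An object of class \code{coefficient_set}.
#' @seealso [tempo34_egfr_coefficients()], [annual_egfr_change()]
#' @export
egfr_coefficients <- function(lambda, beta, se = NULL, vcov = NULL,
                              name = "custom") {
  coef <- c(lambda = lambda, beta = beta)
  new_coefficient_set(coef, se, vcov, equation = "egfr", name = name)
}

new_coefficient_set <- function(coef, se, vcov, equation, name) {
  if (!all(is.finite(coef)))
    stop("coefficient values must be finite", call. = FALSE)
  k <- length(coef)
  if (!is.null(se)) {
    se <- as.numeric(se)
    if (length(se) != k)
      stop(sprintf("'se' must have length %d for the %s equation, got %d",
                   k, equation, length(se)), call. = FALSE)
    if (any(!is.finite(se)) || any(se < 0))
      stop("standard errors must be finite and non-negative", call. = FALSE)
    names(se) <- names(coef)
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    check_vcov(vcov, k)
    dimnames(vcov) <- list(names(coef), names(coef))
  }
  structure(
    list(name = name, equation = equation, coef = coef, se = se, vcov = vcov),
    class = "coefficient_set"
  )
}

# Symmetry and positive semi-definiteness within tolerance; errors name the
# offending eigenvalue so a bad user-supplied matrix is diagnosable.
check_vcov <- function(vcov, k, tol = 1e-8) {
  if (!is.numeric(vcov) || nrow(vcov) != k || ncol(vcov) != k)
    stop(sprintf("'vcov' must be a %dx%d numeric matrix", k, k),
         call. = FALSE)
  if (any(!is.finite(vcov)))
    stop("'vcov' contains non-finite entries", call. = FALSE)
  scale <- max(1, max(abs(vcov)))
  if (max(abs(vcov - t(vcov))) > tol * scale)
    stop("'vcov' is not symmetric", call. = FALSE)
  ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * scale)
    stop(sprintf("'vcov' is not positive semi-definite (eigenvalue %.6g)",
                 min(ev)), call. = FALSE)
  invisible(ev)
}

#' Default TKV progression coefficients fitted to the TEMPO 3:4 placebo arm
#'
#' Reads the bundled coefficient file carrying the published point estimates
#' and standard errors of the TKV equation (intercept 0.7889, age 0.1107,
#' ln(TKV) 0.8027, female -0.0486, age:ln(TKV) -0.0160), together with a
#' synthetic variance-covariance matrix. The published covariance matrix is
#' not reproduced here; the bundled matrix is reconstructed from the
#' correlation structure of a simulated fitting-cohort design matrix,
#' rescaled so its diagonal matches the published standard errors exactly
#' (see [reconstruct_vcov()]).
#'
#' @return A \code{coefficient_set} for the TKV equation.
#' @export
#' @examples
#' tempo34_tkv_coefficients()
tempo34_tkv_coefficients <- function() {
  read_coefficients(system.file("extdata", "tempo34_tkv.json",
                                package = "adpkdsim", mustWork = TRUE))
}

#' Default eGFR progression coefficients fitted to the TEMPO 3:4 placebo arm
#'
#' Reads the bundled coefficient file for the eGFR equation (intercept
#' 4.48474, ln(TKV) -0.06227; fitted to reciprocal-serum-creatinine eGFR).
#' As for [tempo34_tkv_coefficients()], the bundled covariance matrix is a
#' synthetic design-based reconstruction matching the published standard
#' errors.
#'
#' @return A \code{coefficient_set} for the eGFR equation.
#' @export
tempo34_egfr_coefficients <- function() {
  read_coefficients(system.file("extdata", "tempo34_egfr.json",
                                package = "adpkdsim", mustWork = TRUE))
}

#' Read or write a coefficient set as JSON
#'
#' The JSON layout is \code{{"name", "equation", "coefficients": {...},
#' "se": {...}, "vcov": [[...]]}} with \code{vcov} as a row-major list of
#' lists; \code{se} and \code{vcov} may be absent.
#'
#' @param path File path.
#' @return \code{read_coefficients} returns a \code{coefficient_set};
#'   \code{write_coefficients} returns \code{path} invisibly.
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("equation", "coefficients"))
    if (is.null(x[[field]]))
      stop(sprintf("coefficient file '%s' lacks required field '%s'",
                   path, field), call. = FALSE)
  expected <- switch(x$equation,
    tkv = TKV_COEF_NAMES, egfr = EGFR_COEF_NAMES,
    stop(sprintf("unknown equation '%s' in '%s' (expected 'tkv' or 'egfr')",
                 x$equation, path), call. = FALSE))
  co <- unlist(x$coefficients)
  if (!setequal(names(co), expected))
    stop(sprintf("coefficient file '%s' must name exactly: %s",
                 path, paste(expected, collapse = ", ")), call. = FALSE)
  co <- co[expected]
  se <- if (!is.null(x$se)) unlist(x$se)[expected]
  vcov <- if (!is.null(x$vcov)) as.matrix(x$vcov)
  name <- if (is.null(x$name)) "unnamed" else x$name
  new_coefficient_set(co, se, vcov, equation = x$equation, name = name)
}

#' @rdname read_coefficients
#' @param x A \code{coefficient_set}.
#' @export
write_coefficients <- function(x, path) {
  stopifnot(inherits(x, "coefficient_set"))
  out <- list(name = x$name, equation = x$equation,
              coefficients = as.list(x$coef))
  if (!is.null(x$se)) out$se <- as.list(x$se)
  if (!is.null(x$vcov)) out$vcov <- unname(x$vcov)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.coefficient_set <- function(x, ...) {
  form <- if (x$equation == "tkv")
    "dTKV = exp(lambda + alpha*age + beta*ln(TKV) + gamma*[female] + delta*age*ln(TKV)) - 500"
  else
    "dEGFR = exp(lambda + beta*ln(TKV)) - 60"
  cat(sprintf("<coefficient_set '%s' (%s equation)>\n", x$name, x$equation))
  cat(" ", form, "\n", sep = "")
  tab <- rbind(estimate = x$coef)
  if (!is.null(x$se)) tab <- rbind(tab, se = x$se)
  print(tab, ...)
  if (!is.null(x$vcov)) cat(sprintf("  vcov: %dx%d matrix attached\n",
                                    nrow(x$vcov), ncol(x$vcov)))
  invisible(x)
}
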