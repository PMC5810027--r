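# Annual-change equations and CKD staging.

# Unchecked kernels shared by the exported wrappers and the simulation
# engine, so the engine hot loop and the public API evaluate the identical
# arithmetic. Coefficient arguments may be scalars (point estimates) or
# per-patient vectors (one coefficient draw per patient).
.dtkv_v <- function(age, lt, female, l, a, b, g, d) {
  exp(l + a * age + b * lt + g * female + d * age * lt) - 500
}

.degfr_v <- function(lt, l, b) {
  exp(l + b * lt) - 60
}

.dtkv <- function(age, tkv, female, b) {
  .dtkv_v(age, log(tkv), female, b[[1L]], b[[2L]], b[[3L]], b[[4L]], b[[5L]])
}

.degfr <- function(tkv, b) {
  .degfr_v(log(tkv), b[[1L]], b[[2L]])
}

#' Annual change in total kidney volume
#'
#' Evaluates the log-linear TKV progression equation
#' \deqn{\Delta TKV = \exp(\lambda + \alpha\,age + \beta\,\ln TKV +
#'   \gamma\,[female] + \delta\,age\cdot\ln TKV) - 500.}
#' The equation was fitted to annual TKV changes offset by +500 mL, so the
#' returned change is always greater than -500 mL. Inputs are recycled to a
#' common length.
#'
#' @param age Age in years (non-negative).
#' @param tkv Total kidney volume in mL (strictly positive).
#' @param is_female Logical; female indicator.
#' @param coeffs A TKV [coefficient_set][tkv_coefficients()]; defaults to
#'   the bundled TEMPO 3:4 estimates.
#' @return Predicted 1-year change in TKV (mL/year).
#' @export
#' @examples
#' annual_tkv_change(38.7, 1692, is_female = FALSE) # about +124.6 mL/year
#' annual_tkv_change(38.7, 1692, is_female = TRUE)  # about +94.9 mL/year
annual_tkv_change <- function(age, tkv, is_female,
                              coeffs = tempo34_tkv_coefficients()) {
  stopifnot(inherits(coeffs, "coefficient_set"), coeffs$equation == "tkv")
  check_progression_inputs(tkv, age)
  if (!is.logical(is_female) || anyNA(is_female))
    stop("'is_female' must be logical and non-missing", call. = FALSE)
  .dtkv(age, tkv, as.numeric(is_female), coeffs$coef)
}

#' Annual change in estimated glomerular filtration rate
#'
#' Evaluates the eGFR progression equation
#' \deqn{\Delta eGFR = \exp(\lambda + \beta\,\ln TKV) - 60,}
#' fitted to annual eGFR changes offset by +60, so the returned change is
#' always greater than -60. With the bundled estimates (\eqn{\beta < 0}) the
#' predicted decline steepens as kidneys enlarge.
#'
#' @param tkv Total kidney volume in mL (strictly positive).
#' @param coeffs An eGFR [coefficient_set][egfr_coefficients()]; defaults to
#'   the bundled TEMPO 3:4 estimates.
#' @return Predicted 1-year change in eGFR (mL/min/1.73 m^2 per year).
#' @export
#' @examples
#' annual_egfr_change(1668) # about -4.15
#' annual_egfr_change(1000) # about -2.34
annual_egfr_change <- function(tkv, coeffs = tempo34_egfr_coefficients()) {
  stopifnot(inherits(coeffs, "coefficient_set"), coeffs$equation == "egfr")
  check_progression_inputs(tkv)
  .degfr(tkv, coeffs$coef)
}

check_progression_inputs <- function(tkv, age = NULL) {
  if (!is.numeric(tkv) || any(!is.finite(tkv)))
    stop("'tkv' must be finite and numeric", call. = FALSE)
  if (any(tkv <= 0))
    stop("'tkv' must be strictly positive (log of TKV is taken)",
         call. = FALSE)
  if (!is.null(age)) {
    if (!is.numeric(age) || any(!is.finite(age)))
      stop("'age' must be finite and numeric", call. = FALSE)
    if (any(age < 0))
      stop("'age' must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# Stage index 1..5 (5 = ESRD) from eGFR; KDIGO bins, half-open and
# lower-inclusive: [90,Inf) -> 1, [60,90) -> 2, [30,60) -> 3, [15,30) -> 4,
# [0,15) -> ESRD.
.stage_index <- function(egfr) {
  5L - findInterval(egfr, c(15, 30, 60, 90))
}

CKD_STAGE_LABELS <- c("1", "2", "3", "4", "esrd")

#' CKD stage from eGFR
#'
#' Classifies eGFR into KDIGO chronic kidney disease stages using half-open,
#' lower-inclusive bins: stage 1 \eqn{[90,\infty)}, stage 2 \eqn{[60,90)},
#' stage 3 \eqn{[30,60)}, stage 4 \eqn{[15,30)}, and \code{"esrd"} below 15.
#' Stage 3 is kept as a single state (no 3a/3b split) because stage
#' occupancy is reported as one stage-3 total.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (non-negative); vectorized.
#' @return Character vector with values \code{"1"}, \code{"2"}, \code{"3"},
#'   \code{"4"} or \code{"esrd"}.
#' @export
#' @examples
#' ckd_stage(c(95, 90, 59.99, 15, 14.999))
ckd_stage <- function(egfr) {
  if (!is.numeric(egfr) || any(!is.finite(egfr)))
    stop("'egfr' must be finite and numeric", call. = FALSE)
  if (any(egfr < 0))
    stop("'egfr' must be non-negative", call. = FALSE)
  CKD_STAGE_LABELS[.stage_index(egfr)]
}
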