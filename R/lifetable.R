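# Gender-specific life tables for all-cause background mortality.

#' Construct and validate a life table
#'
#' A life table holds annual death probabilities (qx) by integer age and
#' sex. Ages must be contiguous from 0; probabilities must lie in [0, 1].
#' Ages beyond the final row use the final row's values (plateau rule).
#'
#' @param age Integer ages, contiguous from 0.
#' @param qx_male,qx_female Annual death probabilities per age.
#' @return An object of class \code{life_table} (a data frame).
#' @seealso [synthetic_uk_like_table()], [load_life_table()],
#'   [annual_death_probability()]
#' @export
#' @examples
#' life_table(0:2, rep(0.01, 3), rep(0.01, 3))
life_table <- function(age, qx_male, qx_female) {
  df <- data.frame(age = age, qx_male = qx_male, qx_female = qx_female)
  validate_life_table(df)
}

validate_life_table <- function(df, path = NULL) {
  where <- if (is.null(path)) "" else sprintf(" in '%s'", path)
  req <- c("age", "qx_male", "qx_female")
  if (!all(req %in% names(df)))
    stop(sprintf("life table%s must have columns: %s", where,
                 paste(req, collapse = ", ")), call. = FALSE)
  if (nrow(df) < 1) stop("life table", where, " is empty", call. = FALSE)
  bad <- which(!is.finite(df$age) | df$age != round(df$age))
  if (length(bad))
    stop(sprintf("life table%s: non-integer age at row %d", where, bad[1]),
         call. = FALSE)
  dup <- which(duplicated(df$age))
  if (length(dup))
    stop(sprintf("life table%s: duplicate age %d at row %d", where,
                 df$age[dup[1]], dup[1]), call. = FALSE)
  df <- df[order(df$age), , drop = FALSE]
  if (df$age[1] != 0 || any(diff(df$age) != 1)) {
    gap <- if (df$age[1] != 0) 0 else df$age[which(diff(df$age) != 1)[1]] + 1
    stop(sprintf("life table%s: ages must be contiguous from 0 (missing age %d)",
                 where, gap), call. = FALSE)
  }
  for (col in c("qx_male", "qx_female")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad))
      stop(sprintf("life table%s: %s = %g outside [0, 1] at row %d", where,
                   col, df[[col]][bad[1]], bad[1]), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("life_table", "data.frame"))
}

#' Load a life table from CSV
#'
#' Expects a plain CSV with header \code{age,qx_male,qx_female}. Rows are
#' validated: ages must be contiguous integers from 0 and all probabilities
#' within [0, 1]; violations are reported with their row number.
#'
#' @param path CSV file path.
#' @return A \code{life_table}.
#' @export
load_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df, path = path)
}

#' @rdname load_life_table
#' @param table A \code{life_table}.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Synthetic UK-like life table from a Gompertz-Makeham hazard
#'
#' Generates a life table whose male annual death probability follows
#' \deqn{q_x = 1 - \exp\{-(a + b\,c^{x})\},}
#' a Gompertz-Makeham hazard, with the female hazard scaled by
#' \code{female_hazard_ratio}. The defaults approximate the age pattern of
#' recent UK national life tables in the adult range relevant here
#' (cumulative male mortality from age 39 to 65 of roughly 10%). This is a
#' synthetic stand-in, not published national data; substitute a real table
#' via [load_life_table()] for applied work.
#'
#' @param makeham_a Age-independent hazard component (\code{>= 0}).
#' @param gompertz_b Gompertz level (\code{> 0}).
#' @param gompertz_c Gompertz rate per year (\code{> 1}).
#' @param female_hazard_ratio Multiplier on the female hazard (\code{> 0}).
#' @param max_age Last tabulated age; older ages plateau at the last row.
#' @return A \code{life_table} for ages 0..\code{max_age}.
#' @export
#' @examples
#' lt <- synthetic_uk_like_table()
#' lt[lt$age %in% c(40, 65, 90), ]
synthetic_uk_like_table <- function(makeham_a = 5e-5, gompertz_b = 2.7e-5,
                                    gompertz_c = 1.098,
                                    female_hazard_ratio = 0.55,
                                    max_age = 100) {
  if (!is.finite(makeham_a) || makeham_a < 0)
    stop("'makeham_a' must be >= 0", call. = FALSE)
  if (!is.finite(gompertz_b) || gompertz_b <= 0)
    stop("'gompertz_b' must be > 0", call. = FALSE)
  if (!is.finite(gompertz_c) || gompertz_c <= 1)
    stop("'gompertz_c' must be > 1", call. = FALSE)
  if (!is.finite(female_hazard_ratio) || female_hazard_ratio <= 0)
    stop("'female_hazard_ratio' must be > 0", call. = FALSE)
  age <- 0:max_age
  hz <- makeham_a + gompertz_b * gompertz_c^age
  qx_m <- 1 - exp(-hz)
  qx_f <- 1 - exp(-female_hazard_ratio * hz)
  if (any(qx_m > 1) || any(qx_f > 1)) {
    warning("hazard parameters produce qx > 1; clamping to 1",
            call. = FALSE)
    qx_m <- pmin(qx_m, 1)
    qx_f <- pmin(qx_f, 1)
  }
  life_table(age, qx_m, qx_f)
}

#' Annual death probability for a patient
#'
#' Looks up the sex-specific qx at \code{floor(age)}; ages beyond the last
#' tabulated row use the last row (plateau rule), so the lookup never
#' errors for valid ages. Vectorized over \code{age} and \code{is_female}.
#'
#' @param table A \code{life_table}.
#' @param age Age in years (\code{>= 0}), possibly non-integer.
#' @param is_female Logical.
#' @return Annual death probability in [0, 1].
#' @export
#' @examples
#' lt <- life_table(0:2, rep(0.01, 3), rep(0.02, 3))
#' annual_death_probability(lt, 1.7, is_female = FALSE)
annual_death_probability <- function(table, age, is_female) {
  stopifnot(inherits(table, "life_table"))
  if (any(!is.finite(age)) || any(age < 0))
    stop("'age' must be finite and >= 0", call. = FALSE)
  idx <- pmin(floor(age), max(table$age)) + 1L
  ifelse(is_female, table$qx_female[idx], table$qx_male[idx])
}

# All-zero table: disease outcomes with mortality enabled are then
# identical to mortality-off runs under the same seeds.
zero_mortality_table <- function(max_age = 100) {
  life_table(0:max_age, rep(0, max_age + 1), rep(0, max_age + 1))
}
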