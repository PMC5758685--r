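#' LMS growth reference
#'
#' An `lms_reference` holds a sex- and measurement-specific grid of
#' (age, L, M, S) rows supporting conversion between raw measurements and
#' standard deviation scores (SDS, z-scores) by the LMS method: the Box-Cox
#' power `L` removes skewness, `M` is the reference median, and `S` is the
#' coefficient of variation, each tabulated on an age grid and linearly
#' interpolated between rows.
#'
#' Age is in years for `height_for_age` and in completed weeks of gestation
#' for `birthweight_for_gestation`; `M` is in cm or g respectively.
#'
#' @param age numeric vector of grid ages, strictly increasing after sorting.
#' @param L,M,S numeric vectors of LMS parameters, one per grid age.
#'   `M > 0` and `S > 0` are required at every row.
#' @param sex `"female"` or `"male"`.
#' @param measurement `"height_for_age"` or `"birthweight_for_gestation"`.
#' @return An object of class `lms_reference` with fields `grid` (a
#'   data.frame with columns `age,L,M,S` sorted by age), `sex`,
#'   `measurement`, `age_min`, `age_max`.
#' @examples
#' ref <- lms_reference(age = c(1, 10, 20), L = 1, M = c(80, 140, 163),
#'                      S = 0.04, sex = "female",
#'                      measurement = "height_for_age")
#' lms_zscore(163, 20, ref)
#' @export
lms_reference <- function(age, L, M, S,
                          sex = c("female", "male"),
                          measurement = c("height_for_age",
                                          "birthweight_for_gestation")) {
  sex <- match.arg(sex)
  measurement <- match.arg(measurement)
  n <- length(age)
  grid <- data.frame(age = as.numeric(age),
                     L = rep_len(as.numeric(L), n),
                     M = rep_len(as.numeric(M), n),
                     S = rep_len(as.numeric(S), n))
  if (anyNA(grid))
    stop("LMS grid contains missing values", call. = FALSE)
  if (nrow(grid) < 2)
    stop("LMS grid needs at least 2 rows, got ", nrow(grid), call. = FALSE)
  if (anyDuplicated(grid$age))
    stop("duplicate ages in LMS grid", call. = FALSE)
  grid <- grid[order(grid$age), , drop = FALSE]
  rownames(grid) <- NULL
  if (any(grid$M <= 0) || any(grid$S <= 0))
    stop("LMS grid requires M > 0 and S > 0 at every row", call. = FALSE)
  structure(
    list(grid = grid, sex = sex, measurement = measurement,
         age_min = grid$age[1L], age_max = grid$age[nrow(grid)]),
    class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  cat(sprintf("<lms_reference> %s, %s: %d grid rows, age %s to %s\n",
              x$sex, x$measurement, nrow(x$grid),
              format(x$age_min), format(x$age_max)))
  invisible(x)
}

#' Read an LMS reference table from CSV
#'
#' The file must have header `age,L,M,S`, one row per grid age, dot decimals,
#' UTF-8. Rows may appear in any order; the grid is re-sorted ascending by
#' age. National reference tables (e.g. UK 1990) are supplied by the user in
#' this format and are never bundled.
#'
#' @param path path to the CSV file.
#' @inheritParams lms_reference
#' @return An [lms_reference].
#' @export
read_lms_table <- function(path, sex = c("female", "male"),
                           measurement = c("height_for_age",
                                           "birthweight_for_gestation")) {
  if (!file.exists(path))
    stop("LMS table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("age", "L", "M", "S")
  if (!identical(names(tab)[seq_along(required)], required))
    stop("LMS table must have header 'age,L,M,S'; got '",
         paste(names(tab), collapse = ","), "' in ", path, call. = FALSE)
  if (anyDuplicated(tab$age))
    stop("duplicate ages in LMS table ", path, call. = FALSE)
  lms_reference(tab$age, tab$L, tab$M, tab$S,
                sex = sex, measurement = measurement)
}

#' Write an LMS reference table to CSV
#'
#' Inverse of [read_lms_table()]; emits the `age,L,M,S` schema.
#'
#' @param ref an [lms_reference].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lms_table <- function(ref, path) {
  stopifnot(inherits(ref, "lms_reference"))
  utils::write.csv(ref$grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Interpolate L, M, S at `age` (vectorised), linear in age component-wise.
# Errors on any age outside the grid: extrapolation would silently corrupt
# SDS near the bounds, so it is refused outright.
lms_interp <- function(ref, age) {
  if (any(age < ref$age_min | age > ref$age_max))
    stop(sprintf("age outside reference grid [%s, %s]: %s",
                 format(ref$age_min), format(ref$age_max),
                 paste(format(age[age < ref$age_min | age > ref$age_max]),
                       collapse = ", ")),
         call. = FALSE)
  g <- ref$grid
  list(L = stats::approx(g$age, g$L, xout = age)$y,
       M = stats::approx(g$age, g$M, xout = age)$y,
       S = stats::approx(g$age, g$S, xout = age)$y)
}

# |L| below this uses the log-normal branch; the two branches agree to well
# below measurement precision at the switch.
.L_EPS <- 1e-7

#' Convert a measurement to an SDS (z-score) by the LMS method
#'
#' Applies z = ((x/M)^L - 1) / (L * S) for L != 0 and z = log(x/M) / S in the
#' L -> 0 limit, with L, M and S linearly interpolated in age between grid
#' rows. Exact inverse of [lms_value()].
#'
#' @param value measurement value(s), cm for height or g for birthweight;
#'   must be positive.
#' @param age age(s) at measurement, in the reference's age unit (years or
#'   completed weeks of gestation); must lie within the grid — no
#'   extrapolation.
#' @param ref an [lms_reference].
#' @param sex optional; if given, must match `ref$sex` (guards against
#'   converting a girl's height on a male reference).
#' @return numeric vector of SDS values.
#' @export
lms_zscore <- function(value, age, ref, sex = NULL) {
  stopifnot(inherits(ref, "lms_reference"))
  if (!is.null(sex) && !identical(sex, ref$sex))
    stop(sprintf("sex mismatch: measurement is '%s' but reference is '%s'",
                 sex, ref$sex), call. = FALSE)
  if (any(value <= 0, na.rm = TRUE))
    stop("measurement values must be positive", call. = FALSE)
  n <- max(length(value), length(age))
  value <- rep_len(value, n)
  age <- rep_len(age, n)
  p <- lms_interp(ref, age)
  z <- ifelse(abs(p$L) < .L_EPS,
              log(value / p$M) / p$S,
              ((value / p$M)^p$L - 1) / (p$L * p$S))
  as.numeric(z)
}

#' Convert an SDS back to a measurement value
#'
#' Inverse LMS transform: x = M * (1 + L*S*z)^(1/L) for L != 0 and
#' x = M * exp(S*z) in the L -> 0 limit. Monotone increasing in `z`;
#' round-trips through [lms_zscore()] to within 1e-9.
#'
#' For L < 0 the inverse is only defined for z < 1/(|L|*S) (and for L > 0
#' only for z > -1/(L*S)); values outside the admissible range raise a
#' domain error reporting the bound.
#'
#' @param z SDS value(s).
#' @inheritParams lms_zscore
#' @return numeric vector of measurement values (cm or g).
#' @export
lms_value <- function(z, age, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  n <- max(length(z), length(age))
  z <- rep_len(z, n)
  age <- rep_len(age, n)
  p <- lms_interp(ref, age)
  base <- 1 + p$L * p$S * z
  bad <- abs(p$L) >= .L_EPS & base <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    bound <- -1 / (p$L[i] * p$S[i])
    stop(sprintf(
      "z = %.4g outside the admissible range for L = %.4g, S = %.4g (z %s %.4g required)",
      z[i], p$L[i], p$S[i], if (p$L[i] < 0) "<" else ">", bound),
      call. = FALSE)
  }
  x <- ifelse(abs(p$L) < .L_EPS,
              p$M * exp(p$S * z),
              p$M * base^(1 / p$L))
  as.numeric(x)
}

#' Convert a centile to an SDS
#'
#' Standard normal quantile of `centile`/100, so the 2.5th centile maps to
#' -1.96 SDS and the 3rd centile (a conventional short-stature screening
#' threshold) to -1.88 SDS.
#'
#' @param centile percent, strictly between 0 and 100.
#' @return SDS (z) value(s).
#' @export
centile_to_z <- function(centile) {
  if (any(centile <= 0 | centile >= 100))
    stop("centile must lie strictly between 0 and 100", call. = FALSE)
  stats::qnorm(centile / 100)
}

#' Convert an SDS to a centile
#'
#' @param z SDS value(s).
#' @return centile (percent).
#' @export
z_to_centile <- function(z) 100 * stats::pnorm(z)

#' Synthetic analytic height-for-age reference (female)
#'
#' A smooth, fully analytic reference used for testing and simulation:
#' M(age) follows a saturating-exponential growth curve, L = 1 and S is
#' constant, so every conversion has a closed form
#' z = (x - M(age)) / (M(age) * S). It is a stand-in for national references
#' such as UK 1990, which are user-supplied input and never bundled.
#'
#' With L = 1, M(20) and constant S, mid-parental and target-range SDS at
#' the adult age are exactly linear in height, which the simulator's
#' closed-form calibration exploits.
#'
#' @param age_grid grid ages in years.
#' @param adult_cm asymptotic adult median height, cm.
#' @param infant_gap_cm shortfall of the curve below `adult_cm` at age 0.
#' @param rate exponential approach rate per year.
#' @param S constant coefficient of variation.
#' @return An [lms_reference] for `female` / `height_for_age`.
#' @export
synthetic_height_reference <- function(age_grid = seq(1, 25, by = 0.5),
                                       adult_cm = 165, infant_gap_cm = 95,
                                       rate = 0.165, S = 0.037) {
  M <- adult_cm - infant_gap_cm * exp(-rate * age_grid)
  lms_reference(age_grid, L = 1, M = M, S = S,
                sex = "female", measurement = "height_for_age")
}

#' Synthetic analytic birthweight-for-gestation reference (female)
#'
#' Analytic stand-in for a birthweight-by-gestation standard: the median
#' follows an exponential approach to a term weight over completed weeks of
#' gestation, with L = 1 and constant S. Gestations recorded in whole weeks
#' index the grid directly (week + 0.0).
#'
#' @param week_grid completed weeks of gestation covered by the grid.
#' @param term_g asymptotic median birthweight, g.
#' @param rate exponential approach rate per week.
#' @param S constant coefficient of variation.
#' @return An [lms_reference] for `female` / `birthweight_for_gestation`.
#' @export
synthetic_birthweight_reference <- function(week_grid = 22:46, term_g = 3600,
                                            rate = 0.085, S = 0.14) {
  M <- term_g * exp(-rate * pmax(40 - week_grid, 0)) *
    (1 + 0.01 * pmax(week_grid - 40, 0))
  lms_reference(week_grid, L = 1, M = M, S = S,
                sex = "female", measurement = "birthweight_for_gestation")
}
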