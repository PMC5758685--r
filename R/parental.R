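#' Parental heights with measurement provenance
#'
#' Records the heights of a girl's mother and father together with how each
#' was obtained: measured in clinic, reported by the parent, or missing.
#' Reported heights are accepted and carried through with their provenance
#' flag — they are never silently treated as measured, because reported
#' heights are systematically biased (fathers tend to overestimate, mothers
#' to underestimate).
#'
#' @param mother_cm,father_cm height in cm, or `NA` if unknown. A present
#'   height must lie in (100, 250) cm.
#' @param mother_source,father_source one of `"measured"`, `"reported"`,
#'   `"missing"`; must be `"missing"` exactly when the height is `NA`.
#' @return An object of class `parental_heights`.
#' @export
parental_heights <- function(mother_cm = NA_real_, father_cm = NA_real_,
                             mother_source = if (is.na(mother_cm)) "missing" else "measured",
                             father_source = if (is.na(father_cm)) "missing" else "measured") {
  sources <- c("measured", "reported", "missing")
  mother_source <- match.arg(mother_source, sources)
  father_source <- match.arg(father_source, sources)
  check_one <- function(h, src, who) {
    if (is.na(h) != (src == "missing"))
      stop(sprintf("%s: source must be 'missing' exactly when the height is missing", who),
           call. = FALSE)
    if (!is.na(h) && (h <= 100 || h >= 250))
      stop(sprintf("%s height %.1f cm outside plausible range (100, 250)", who, h),
           call. = FALSE)
  }
  check_one(mother_cm, mother_source, "mother")
  check_one(father_cm, father_source, "father")
  structure(list(mother_cm = as.numeric(mother_cm),
                 father_cm = as.numeric(father_cm),
                 mother_source = mother_source,
                 father_source = father_source),
            class = "parental_heights")
}

#' Mid-parental height for a daughter
#'
#' MPH = (mother + father - 12.5 cm) / 2: the daughter convention, in which
#' the sex-difference correction of 12.5 cm is subtracted from the father's
#' height before averaging. The correction is configurable because
#' Tanner-derived target-height systems admit variants.
#'
#' @param p a [parental_heights].
#' @param correction_cm sex-difference correction, cm (default 12.5, the
#'   daughter convention).
#' @return mid-parental height in cm.
#' @export
mid_parental_height <- function(p, correction_cm = 12.5) {
  stopifnot(inherits(p, "parental_heights"))
  missing_who <- c("mother", "father")[c(is.na(p$mother_cm), is.na(p$father_cm))]
  if (length(missing_who))
    stop("cannot compute mid-parental height: missing ",
         paste(missing_who, collapse = " and "), " height",
         call. = FALSE)
  (p$mother_cm + p$father_cm - correction_cm) / 2
}

#' Lower end of the parental target range
#'
#' LTR = MPH - 8.5 cm, taking 8.5 cm as two standard deviations below the
#' mid-parental height. A girl whose height SDS falls below the LTR SDS is
#' short relative to her family even if not short for the population.
#'
#' @param mph mid-parental height, cm.
#' @param drop_cm half-width of the target range below MPH, cm (default 8.5,
#'   two SDs).
#' @return lower target range in cm.
#' @export
lower_target_range <- function(mph, drop_cm = 8.5) mph - drop_cm

#' Mid-parental height and lower target range as SDS
#'
#' Computes MPH and LTR in cm and converts both to SDS at the adult
#' reference age (20 years) on the female height reference, so a girl's
#' height SDS can be compared directly with her family's expectation.
#'
#' `completeness` summarises parental provenance: `both_measured` only when
#' both flags are `measured`; `both_reported` only when both are `reported`;
#' `one_measured` when exactly one is measured and the other is present;
#' `insufficient` when either height is missing, in which case no numeric
#' fields are returned and callers must branch (mirroring per-stratum
#' analyses).
#'
#' @param p a [parental_heights].
#' @param female_ref female height-for-age [lms_reference] covering
#'   `adult_age`.
#' @param adult_age adult reference age in years (default 20).
#' @inheritParams mid_parental_height
#' @inheritParams lower_target_range
#' @return An object of class `target_range`: list with `mph_cm`, `ltr_cm`,
#'   `mph_sds`, `ltr_sds`, `completeness`. Numeric fields are `NA` when
#'   `completeness == "insufficient"`.
#' @export
target_range_sds <- function(p, female_ref, adult_age = 20,
                             correction_cm = 12.5, drop_cm = 8.5) {
  stopifnot(inherits(p, "parental_heights"))
  completeness <-
    if (p$mother_source == "missing" || p$father_source == "missing") {
      "insufficient"
    } else if (p$mother_source == "measured" && p$father_source == "measured") {
      "both_measured"
    } else if (p$mother_source == "reported" && p$father_source == "reported") {
      "both_reported"
    } else {
      "one_measured"
    }
  if (completeness == "insufficient") {
    tr <- list(mph_cm = NA_real_, ltr_cm = NA_real_,
               mph_sds = NA_real_, ltr_sds = NA_real_,
               completeness = completeness)
    return(structure(tr, class = "target_range"))
  }
  stopifnot(inherits(female_ref, "lms_reference"))
  mph <- mid_parental_height(p, correction_cm = correction_cm)
  ltr <- lower_target_range(mph, drop_cm = drop_cm)
  structure(list(
    mph_cm = mph, ltr_cm = ltr,
    mph_sds = lms_zscore(mph, adult_age, female_ref),
    ltr_sds = lms_zscore(ltr, adult_age, female_ref),
    completeness = completeness),
    class = "target_range")
}

#' @export
print.target_range <- function(x, ...) {
  if (x$completeness == "insufficient") {
    cat("<target_range> insufficient parental data\n")
  } else {
    cat(sprintf("<target_range> MPH %.1f cm (%.2f SDS), LTR %.1f cm (%.2f SDS), %s\n",
                x$mph_cm, x$mph_sds, x$ltr_cm, x$ltr_sds, x$completeness))
  }
  invisible(x)
}
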