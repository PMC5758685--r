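#' Karyotype categories
#'
#' The cytogenetic categories used for Turner syndrome cohorts: 45,X
#' monosomy, the common mosaic/structural variants, and `other`. The
#' mosaicisms `45X_46XX` and `45X_47XXX` are associated with a milder growth
#' phenotype.
#'
#' @export
karyotype_levels <- c("45X", "45X_46XiXq", "45X_46XY", "45X_46XX",
                      "45X_47XXX", "45X_46XrX", "46XiXq", "other")

#' One study subject
#'
#' A girl's record as used by the screening analysis: age at first accurate
#' (stadiometer) height measurement after the first year of life, the raw
#' height and/or a precomputed height SDS (fixtures carry SDS directly),
#' birthweight and gestation, karyotype category, and parental heights with
#' provenance.
#'
#' @param id opaque record identifier.
#' @param age_first_measurement age in years at first accurate measurement.
#' @param height_cm height at that age, cm, or `NA`.
#' @param height_sds precomputed height SDS, or `NA`. At least one of
#'   `height_cm` / `height_sds` must be present.
#' @param birthweight_g birthweight in g, or `NA`.
#' @param gestation_weeks completed weeks of gestation, or `NA`.
#' @param bw_sds precomputed birthweight SDS, or `NA` (fixtures only).
#' @param karyotype one of [karyotype_levels].
#' @param parents a [parental_heights].
#' @return An object of class `girl_record`.
#' @export
girl_record <- function(id, age_first_measurement,
                        height_cm = NA_real_, height_sds = NA_real_,
                        birthweight_g = NA_real_, gestation_weeks = NA_real_,
                        bw_sds = NA_real_,
                        karyotype = "other",
                        parents = parental_heights()) {
  karyotype <- match.arg(karyotype, karyotype_levels)
  stopifnot(inherits(parents, "parental_heights"))
  if (is.na(height_cm) && is.na(height_sds))
    stop("record ", id, ": at least one of height_cm / height_sds required",
         call. = FALSE)
  structure(list(id = as.character(id),
                 age_first_measurement = as.numeric(age_first_measurement),
                 height_cm = as.numeric(height_cm),
                 height_sds = as.numeric(height_sds),
                 birthweight_g = as.numeric(birthweight_g),
                 gestation_weeks = as.numeric(gestation_weeks),
                 bw_sds = as.numeric(bw_sds),
                 karyotype = karyotype,
                 parents = parents),
            class = "girl_record")
}

#' Age bands for the sensitivity tables
#'
#' Bands follow the convention 1-5 / 5.1-10 / 10.1-16 years, implemented as
#' the half-open intervals (1, 5], (5, 10], (10, 16]; ages above 16 fall in
#' `out_of_band` and are reported separately.
#'
#' @param age age(s) in years, each > 1.
#' @return factor with levels `band_1_5`, `band_5_10`, `band_10_16`,
#'   `out_of_band`.
#' @export
age_band <- function(age) {
  stopifnot(all(age > 1))
  b <- ifelse(age <= 5, "band_1_5",
              ifelse(age <= 10, "band_5_10",
                     ifelse(age <= 16, "band_10_16", "out_of_band")))
  factor(b, levels = c("band_1_5", "band_5_10", "band_10_16", "out_of_band"))
}

# Signal an excluded record as a classed condition so the pipeline can catch,
# log and count it rather than silently dropping the row.
signal_excluded <- function(id, reason) {
  stop(structure(class = c("excluded_record", "error", "condition"),
                 list(message = sprintf("record %s excluded: %s", id, reason),
                      call = NULL, id = id, reason = reason)))
}

#' Classify one girl against population and family thresholds
#'
#' Derives the quantities the screening evaluation needs: height SDS (from
#' the reference if only raw height is available), age band, the population
#' flag `short_population` (height SDS strictly below -2), the family flag
#' `below_family` (height SDS strictly below the LTR SDS; only defined when
#' a target range is available), and birthweight-below-cut-off flags.
#'
#' All threshold comparisons are strict `<`, with `>=` as the complement, so
#' a girl at exactly -2.00 SDS is not short.
#'
#' @param g a [girl_record].
#' @param height_ref female height-for-age [lms_reference]; required when
#'   the record carries only `height_cm`.
#' @param bw_ref female birthweight-for-gestation [lms_reference]; used when
#'   the record carries `birthweight_g` + `gestation_weeks` but no
#'   precomputed `bw_sds`.
#' @param tr a [target_range] for the girl's parents, or `NULL` when
#'   unavailable.
#' @param bw_cutoffs birthweight SDS cut-offs to flag (default -2, -1.5, -1).
#' @return One-row data.frame (class `classified_record`) with columns `id`,
#'   `age`, `age_band`, `ht_sds`, `ltr_sds`, `bw_sds`, `short_population`,
#'   `below_family`, `completeness`, `karyotype`, and one logical
#'   `bw_below_<cutoff>` column per cut-off. Records with age <= 1 year
#'   raise a classed `excluded_record` condition (measurements in the first
#'   year are not accurate screening measurements).
#' @export
classify <- function(g, height_ref = NULL, bw_ref = NULL, tr = NULL,
                     bw_cutoffs = c(-2, -1.5, -1)) {
  stopifnot(inherits(g, "girl_record"))
  if (g$age_first_measurement <= 1)
    signal_excluded(g$id, "age at first measurement <= 1 year")

  ht_sds <- g$height_sds
  if (!is.na(g$height_sds) && !is.na(g$height_cm)) {
    warning("record ", g$id,
            ": both height_cm and height_sds present; using height_sds",
            call. = FALSE)
  } else if (is.na(ht_sds)) {
    if (is.null(height_ref))
      stop("record ", g$id, ": height_ref needed to convert height_cm to SDS",
           call. = FALSE)
    ht_sds <- lms_zscore(g$height_cm, g$age_first_measurement, height_ref)
  }

  bw_sds <- g$bw_sds
  if (is.na(bw_sds) && !is.na(g$birthweight_g) && !is.na(g$gestation_weeks) &&
      !is.null(bw_ref)) {
    bw_sds <- lms_zscore(g$birthweight_g, g$gestation_weeks, bw_ref)
  }

  ltr_sds <- NA_real_
  completeness <- "insufficient"
  if (!is.null(tr)) {
    stopifnot(inherits(tr, "target_range"))
    ltr_sds <- tr$ltr_sds
    completeness <- tr$completeness
  }

  out <- data.frame(
    id = g$id,
    age = g$age_first_measurement,
    age_band = as.character(age_band(g$age_first_measurement)),
    ht_sds = ht_sds,
    ltr_sds = ltr_sds,
    bw_sds = bw_sds,
    short_population = ht_sds < -2,
    below_family = if (is.na(ltr_sds)) NA else ht_sds < ltr_sds,
    completeness = completeness,
    karyotype = g$karyotype,
    stringsAsFactors = FALSE)
  for (cut in bw_cutoffs)
    out[[paste0("bw_below_", cut)]] <- if (is.na(bw_sds)) NA else bw_sds < cut
  class(out) <- c("classified_record", "data.frame")
  out
}

#' Format a percentage
#'
#' `mode = "round"` rounds half to even (so 84.78 prints as 85 and 1.625 as
#' 1.6); `mode = "truncate"` drops digits beyond `digits` without rounding,
#' which some published tables use (94/172 = 54.65% prints as 54.7 under
#' rounding but 54.6 under truncation).
#'
#' @param x percentage value(s).
#' @param digits decimal places to keep.
#' @param mode `"round"` (half to even, the default) or `"truncate"`.
#' @return numeric vector.
#' @export
percent_format <- function(x, digits = 0, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "round") round(x, digits)
  else trunc(x * 10^digits) / 10^digits
}

#' Age-banded sensitivity table for family-referenced screening
#'
#' Cross-tabulates classified records by age band and by whether height SDS
#' fell below the lower parental target range (and, in parallel, below the
#' population -2 SDS cut-off), with per-band and overall counts and
#' percentages. This table is computed for the both-parents-measured
#' stratum, so every record must carry an LTR SDS.
#'
#' @param records a `classified_record` data.frame (rows from [classify()]).
#' @return An object of class `sensitivity_table`: a data.frame with one row
#'   per occupied age band plus `overall`, columns `n_total`, `n_below_ltr`,
#'   `n_at_or_above_ltr`, `pct_below_ltr`, `n_short_population`,
#'   `n_not_short`, `pct_short`. Percentages are displayed to the integer
#'   (half-to-even). The unrounded overall below-LTR sensitivity is kept in
#'   attribute `sensitivity_ltr`.
#' @export
sensitivity_table <- function(records) {
  if (NROW(records) == 0)
    stop("cannot build a sensitivity table from zero records", call. = FALSE)
  if (anyNA(records$ltr_sds))
    stop("all records need ltr_sds (both-parents-measured stratum)",
         call. = FALSE)
  bands <- levels(age_band(2))
  in_band <- factor(records$age_band, levels = bands)
  one <- function(sel) {
    n <- sum(sel)
    below <- sum(records$below_family[sel])
    short <- sum(records$short_population[sel])
    data.frame(n_total = n,
               n_below_ltr = below,
               n_at_or_above_ltr = n - below,
               pct_below_ltr = if (n) percent_format(100 * below / n) else NA_real_,
               n_short_population = short,
               n_not_short = n - short,
               pct_short = if (n) percent_format(100 * short / n) else NA_real_)
  }
  rows <- lapply(bands, function(b) one(in_band == b))
  tab <- do.call(rbind, c(rows, list(one(rep(TRUE, nrow(records))))))
  tab <- cbind(band = c(bands, "overall"), tab)
  tab <- tab[tab$n_total > 0 | tab$band == "overall", , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sensitivity_ltr") <-
    100 * tab$n_below_ltr[tab$band == "overall"] /
    tab$n_total[tab$band == "overall"]
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

#' Birthweight cut-off sensitivities
#'
#' For each SDS cut-off, counts records with birthweight SDS strictly below
#' it and expresses the count as a percentage of the denominator
#' (sensitivity, since all subjects are affected). Lowering a cut-off never
#' increases its count.
#'
#' @param records a `classified_record` data.frame, or a numeric vector of
#'   birthweight SDS values. Records without a birthweight SDS are dropped
#'   from numerator and denominator.
#' @param cutoffs SDS cut-offs (default -2, -1.5, -1).
#' @param denominator optional explicit denominator; defaults to the number
#'   of records with a birthweight SDS.
#' @return data.frame with columns `cutoff`, `n_below`, `denominator`,
#'   `percent` (one decimal, half-to-even).
#' @export
birthweight_sensitivity <- function(records, cutoffs = c(-2, -1.5, -1),
                                    denominator = NULL) {
  bw <- if (is.numeric(records)) records else records$bw_sds
  bw <- bw[!is.na(bw)]
  if (is.null(denominator)) denominator <- length(bw)
  if (denominator == 0)
    stop("no records with birthweight SDS", call. = FALSE)
  n_below <- vapply(cutoffs, function(cut) sum(bw < cut), integer(1))
  data.frame(cutoff = cutoffs,
             n_below = n_below,
             denominator = denominator,
             percent = percent_format(100 * n_below / denominator, 1))
}

#' Predictive yield of crude short-stature screening
#'
#' The population worked example: given annual live births, the female
#' fraction, the Turner syndrome prevalence per female birth, and a
#' short-stature centile threshold, compute how many girls screen short,
#' how many of those are expected to have Turner syndrome, and the resulting
#' positive predictive value. With `paper_compat = TRUE` the short-girl
#' count is rounded to the nearest hundred and the Turner count to the
#' nearest integer before the ratio is taken, reproducing the published
#' back-of-envelope convention (53,802 births, half female, 1/2000
#' prevalence, 3rd centile: 800 short girls, 13 with Turner syndrome, PPV
#' 1.6%); otherwise all quantities are exact.
#'
#' The 1.6% figure is sometimes loosely called a specificity, but it is the
#' proportion of screen-positives who truly have the condition — a PPV —
#' and is labelled as such here.
#'
#' @param annual_births live births per year.
#' @param female_fraction fraction of births that are girls.
#' @param ts_prevalence Turner syndrome prevalence per live female birth.
#' @param short_centile centile threshold defining short (percent, 0-100
#'   exclusive).
#' @param paper_compat round intermediate counts as in the published example
#'   (default `TRUE`).
#' @return list with `n_short_girls`, `n_ts_girls`, `ppv_percent` (one
#'   decimal in compatibility mode, exact otherwise).
#' @export
crude_screening_yield <- function(annual_births, female_fraction,
                                  ts_prevalence, short_centile,
                                  paper_compat = TRUE) {
  stopifnot(annual_births > 0, female_fraction > 0, ts_prevalence >= 0)
  if (short_centile <= 0 || short_centile >= 100)
    stop("short_centile must lie strictly between 0 and 100", call. = FALSE)
  n_female <- annual_births * female_fraction
  n_short <- n_female * short_centile / 100
  n_ts <- n_female * ts_prevalence
  if (paper_compat) {
    n_short <- round(n_short / 100) * 100
    n_ts <- round(n_ts)
  }
  ppv <- 100 * n_ts / n_short
  if (paper_compat) ppv <- percent_format(ppv, 1)
  list(n_short_girls = n_short, n_ts_girls = n_ts, ppv_percent = ppv)
}
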