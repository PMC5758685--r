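#' Analysis configuration
#'
#' Explicit configuration of the pipeline's exclusion and evaluation rules.
#' Exclusions are configuration, not code, because in a case-note review
#' they are applied judgement calls: a minimum age for an accurate
#' measurement, a manual id blacklist for clinically implausible records
#' (e.g. a girl with generalised oedema at birth whose birthweight SDS is
#' uninterpretable), and an automatic birthweight-SDS outlier screen.
#'
#' @param min_age records with age at first measurement at or below this
#'   (years) are excluded from classification.
#' @param manual_exclusions character vector of record ids to exclude, with
#'   reason `manual_exclusion`.
#' @param bw_outlier_abs_sds birthweight SDS magnitudes above this are
#'   dropped from the birthweight analysis (the record itself is kept).
#' @param bw_cutoffs birthweight SDS cut-offs for the sensitivity analysis.
#' @param adult_age adult reference age for MPH/LTR SDS, years.
#' @param correction_cm,drop_cm target-range constants, cm.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(min_age = 1,
                            manual_exclusions = character(),
                            bw_outlier_abs_sds = 3,
                            bw_cutoffs = c(-2, -1.5, -1),
                            adult_age = 20,
                            correction_cm = 12.5,
                            drop_cm = 8.5) {
  structure(list(min_age = min_age,
                 manual_exclusions = manual_exclusions,
                 bw_outlier_abs_sds = bw_outlier_abs_sds,
                 bw_cutoffs = bw_cutoffs,
                 adult_age = adult_age,
                 correction_cm = correction_cm,
                 drop_cm = drop_cm),
            class = "analysis_config")
}

# Stable hash of an R object for the run manifest: md5 of its deparsed form.
config_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

exclusion_reasons <- c("age_at_or_below_min", "no_height", "manual_exclusion")

# One cohort row -> girl_record + target_range; errors carry the row number.
row_to_record <- function(row, i) {
  tryCatch({
    parents <- parental_heights(
      mother_cm = row$mother_cm, father_cm = row$father_cm,
      mother_source = row$mother_source, father_source = row$father_source)
    girl_record(id = row$id,
                age_first_measurement = row$age_years,
                height_cm = row$height_cm, height_sds = row$height_sds,
                birthweight_g = row$birthweight_g,
                gestation_weeks = row$gestation_weeks,
                karyotype = row$karyotype,
                parents = parents)
  }, error = function(e) {
    if (inherits(e, "excluded_record")) stop(e)
    stop(sprintf("row %d (id %s): %s", i, row$id, conditionMessage(e)),
         call. = FALSE)
  })
}

# Measurement stratum from provenance flags: both / one / neither measured.
measurement_stratum <- function(mother_source, father_source) {
  n_measured <- (mother_source == "measured") + (father_source == "measured")
  c("neither", "one", "both")[n_measured + 1L]
}

#' Run the full screening analysis on a cohort
#'
#' Orchestrates reference-based SDS computation, parental target ranges,
#' classification against population and family thresholds, the age-banded
#' sensitivity table for the both-parents-measured stratum, birthweight
#' cut-off sensitivities with the configured outlier rule, per-stratum
#' LTR-minus-height SDS differences, and a run manifest accounting for
#' every input record (analysed, excluded with reason, or lacking a
#' computable target range).
#'
#' @param cohort a cohort data.frame (schema of [simulate_cohort()]) or a
#'   path to a cohort CSV.
#' @param height_ref female height-for-age [lms_reference].
#' @param bw_ref female birthweight-for-gestation [lms_reference], or
#'   `NULL` to skip birthweight analysis.
#' @param config an [analysis_config].
#' @return list of class `turner_analysis` with elements:
#'   \describe{
#'     \item{classified}{data.frame of classified records (one per analysed
#'       girl).}
#'     \item{sensitivity}{[sensitivity_table] for the both-parents-measured
#'       stratum, or `NULL` if that stratum is empty.}
#'     \item{birthweight}{birthweight cut-off sensitivities, or `NULL`.}
#'     \item{stratum_summary}{per-provenance-stratum n, mean height SDS,
#'       mean LTR SDS and mean(LTR - height) SDS.}
#'     \item{measurement_census}{counts and percentages of girls with both /
#'       one / neither parent measured.}
#'     \item{manifest}{run manifest: input, config hash, exclusion log,
#'       reconciliation counts, timestamp.}
#'   }
#' @export
run_analysis <- function(cohort, height_ref, bw_ref = NULL,
                         config = analysis_config()) {
  input_path <- NA_character_
  if (is.character(cohort)) {
    input_path <- cohort
    cohort <- read_cohort(cohort)
  }
  check_cohort_schema(cohort)
  stopifnot(inherits(config, "analysis_config"))
  n_input <- nrow(cohort)

  exclusions <- data.frame(id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  exclude <- function(id, reason) {
    stopifnot(reason %in% exclusion_reasons)
    exclusions <<- rbind(exclusions,
                         data.frame(id = id, reason = reason,
                                    stringsAsFactors = FALSE))
  }

  classified <- NULL
  census_stratum <- character()
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    if (row$id %in% config$manual_exclusions) {
      exclude(row$id, "manual_exclusion")
      next
    }
    if (is.na(row$height_cm) && is.na(row$height_sds)) {
      exclude(row$id, "no_height")
      next
    }
    if (row$age_years <= config$min_age) {
      exclude(row$id, "age_at_or_below_min")
      next
    }
    g <- row_to_record(row, i)
    tr <- target_range_sds(g$parents, height_ref,
                           adult_age = config$adult_age,
                           correction_cm = config$correction_cm,
                           drop_cm = config$drop_cm)
    rec <- withCallingHandlers(
      classify(g, height_ref = height_ref, bw_ref = bw_ref, tr = tr,
               bw_cutoffs = config$bw_cutoffs),
      warning = function(w) {
        message("note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    classified <- rbind(classified, rec)
    census_stratum <- c(census_stratum,
                        measurement_stratum(row$mother_source,
                                            row$father_source))
  }

  if (is.null(classified))
    stop("no analysable records in cohort", call. = FALSE)
  classified$measurement_stratum <- census_stratum

  both <- classified[classified$completeness == "both_measured", ]
  sens <- if (nrow(both)) sensitivity_table(both) else NULL

  bw <- NULL
  bw_outliers <- character()
  has_bw <- !is.na(classified$bw_sds)
  if (any(has_bw)) {
    out_idx <- has_bw & abs(classified$bw_sds) > config$bw_outlier_abs_sds
    bw_outliers <- classified$id[out_idx]
    keep <- classified[has_bw & !out_idx, ]
    if (nrow(keep))
      bw <- birthweight_sensitivity(keep, cutoffs = config$bw_cutoffs)
  }

  strata <- c("both_measured", "one_measured", "both_reported")
  stratum_summary <- do.call(rbind, lapply(strata, function(s) {
    sub <- classified[classified$completeness == s, ]
    data.frame(stratum = s, n = nrow(sub),
               mean_ht_sds = if (nrow(sub)) mean(sub$ht_sds) else NA_real_,
               mean_ltr_sds = if (nrow(sub)) mean(sub$ltr_sds) else NA_real_,
               mean_ltr_minus_ht = if (nrow(sub))
                 mean(sub$ltr_sds - sub$ht_sds) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  census_all <- measurement_stratum(cohort$mother_source, cohort$father_source)
  census <- data.frame(
    stratum = c("both", "one", "neither"),
    n = vapply(c("both", "one", "neither"),
               function(s) sum(census_all == s), integer(1)),
    stringsAsFactors = FALSE)
  census$percent <- percent_format(100 * census$n / n_input, 1)

  manifest <- list(
    input_path = input_path,
    n_input = n_input,
    n_analysed = nrow(classified),
    n_excluded = nrow(exclusions),
    exclusions = exclusions,
    bw_outliers_excluded = bw_outliers,
    config_hash = config_hash(unclass(config)),
    config = unclass(config),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  stopifnot(manifest$n_analysed + manifest$n_excluded == n_input)

  structure(list(classified = classified, sensitivity = sens,
                 birthweight = bw, stratum_summary = stratum_summary,
                 measurement_census = census, manifest = manifest),
            class = "turner_analysis")
}

#' @export
print.turner_analysis <- function(x, ...) {
  cat(sprintf("<turner_analysis> %d input, %d analysed, %d excluded\n",
              x$manifest$n_input, x$manifest$n_analysed,
              x$manifest$n_excluded))
  if (!is.null(x$sensitivity)) {
    ov <- x$sensitivity[x$sensitivity$band == "overall", ]
    cat(sprintf("  below LTR: %d/%d (%.0f%%); short (< -2 SDS): %d/%d (%.0f%%) [both parents measured]\n",
                ov$n_below_ltr, ov$n_total, ov$pct_below_ltr,
                ov$n_short_population, ov$n_total, ov$pct_short))
  }
  invisible(x)
}

#' Write analysis outputs
#'
#' Emits the machine-readable long-format classification CSV, the
#' wide-layout sensitivity table (age bands as columns, count and percent
#' rows), the birthweight and stratum tables, and the manifest as JSON.
#'
#' @param res a `turner_analysis` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths written, invisibly.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "turner_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(classified = file.path(dir, "classified_long.csv"),
             sensitivity = file.path(dir, "sensitivity_by_age_band.csv"),
             birthweight = file.path(dir, "birthweight_sensitivity.csv"),
             strata = file.path(dir, "stratum_summary.csv"),
             census = file.path(dir, "measurement_census.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(res$classified, paths[["classified"]], row.names = FALSE,
                   na = "")
  if (!is.null(res$sensitivity)) {
    wide <- as.data.frame(t(res$sensitivity[, -1]))
    names(wide) <- res$sensitivity$band
    wide <- cbind(quantity = rownames(wide), wide)
    utils::write.csv(wide, paths[["sensitivity"]], row.names = FALSE, na = "")
  }
  if (!is.null(res$birthweight))
    utils::write.csv(res$birthweight, paths[["birthweight"]],
                     row.names = FALSE, na = "")
  utils::write.csv(res$stratum_summary, paths[["strata"]],
                   row.names = FALSE, na = "")
  utils::write.csv(res$measurement_census, paths[["census"]],
                   row.names = FALSE, na = "")
  jsonlite::write_json(res$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(paths)
}

# Frozen md5 of the shipped Table 3 fixture CSV.
.TABLE3_MD5 <- "641428e428108bbf8ad70f109463807a"

#' Load the 14-girl fixture with precomputed SDS values
#'
#' The packaged fixture reproduces, verbatim, a published table of the 14
#' girls in a Turner clinic cohort whose first accurate height measurement
#' after age 1 fell at or above the lower end of the parental target range:
#' karyotype, age at first accurate measurement, height SDS, LTR SDS and
#' birthweight SDS (missing where not available). It is the
#' at-or-above-LTR stratum used to pin the classifier: every record
#' classifies as `below_family = FALSE`.
#'
#' @return data.frame with 14 rows and columns `id`, `karyotype`,
#'   `age_years`, `ht_sds`, `ltr_sds`, `bw_sds`, `comment`.
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_girls.csv",
                      package = "turnerscreen", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .TABLE3_MD5))
    stop("packaged fixture ", path, " failed its integrity check",
         call. = FALSE)
  fix <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  stopifnot(nrow(fix) == 14)
  fix$comment[is.na(fix$comment)] <- ""
  fix
}

#' Classify the fixture records
#'
#' Convenience wrapper: converts each fixture row (which carries height and
#' LTR SDS directly) into a classified record.
#'
#' @param fix output of [load_table3_fixture()].
#' @return `classified_record` data.frame with 14 rows.
#' @export
classify_table3 <- function(fix = load_table3_fixture()) {
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    g <- girl_record(id = fix$id[i],
                     age_first_measurement = fix$age_years[i],
                     height_sds = fix$ht_sds[i],
                     bw_sds = fix$bw_sds[i],
                     karyotype = fix$karyotype[i],
                     parents = parental_heights(160, 175))
    # fixture carries the LTR SDS directly; build a bare target range
    tr <- structure(list(mph_cm = NA_real_, ltr_cm = NA_real_,
                         mph_sds = NA_real_, ltr_sds = fix$ltr_sds[i],
                         completeness = "both_measured"),
                    class = "target_range")
    classify(g, tr = tr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("classified_record", "data.frame")
  out
}
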