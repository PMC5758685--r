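# Shared analytic references and small constructors for the tests.

href <- synthetic_height_reference()
bwref <- synthetic_birthweight_reference()

# A minimal hand-built reference with known rows for closed-form checks.
flat_ref <- function(L = 1, M = 100, S = 0.1, ages = c(1, 10, 20),
                     sex = "female") {
  lms_reference(ages, L = L, M = M, S = S, sex = sex,
                measurement = "height_for_age")
}

# Independent oracle: linear interpolation of L, M, S then the closed form,
# written without touching the package's interpolation path.
oracle_z <- function(x, age, grid) {
  i <- findInterval(age, grid$age, rightmost.closed = TRUE)
  a0 <- grid$age[i]; a1 <- grid$age[i + 1]
  w <- if (a1 > a0) (age - a0) / (a1 - a0) else 0
  L <- (1 - w) * grid$L[i] + w * grid$L[i + 1]
  M <- (1 - w) * grid$M[i] + w * grid$M[i + 1]
  S <- (1 - w) * grid$S[i] + w * grid$S[i + 1]
  if (abs(L) < 1e-7) log(x / M) / S else ((x / M)^L - 1) / (L * S)
}

# Build a classified_record data.frame directly from flags, for table-level
# tests that start from published counts rather than raw measurements.
make_classified <- function(age, ht_sds, ltr_sds) {
  n <- max(length(age), length(ht_sds), length(ltr_sds))
  age <- rep_len(age, n); ht_sds <- rep_len(ht_sds, n)
  ltr_sds <- rep_len(ltr_sds, n)
  out <- data.frame(id = sprintf("r%03d", seq_len(n)),
                    age = age,
                    age_band = as.character(age_band(age)),
                    ht_sds = ht_sds, ltr_sds = ltr_sds,
                    bw_sds = NA_real_,
                    short_population = ht_sds < -2,
                    below_family = ht_sds < ltr_sds,
                    completeness = "both_measured",
                    karyotype = "45X",
                    stringsAsFactors = FALSE)
  for (cut in c(-2, -1.5, -1)) out[[paste0("bw_below_", cut)]] <- NA

  class(out) <- c("classified_record", "data.frame")
  out
}
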