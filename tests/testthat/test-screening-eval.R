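test_that("classification applies strict thresholds to both references", {
  mk <- function(ht_sds, ltr_sds, age = 3) {
    g <- girl_record("g1", age, height_sds = ht_sds,
                     parents = parental_heights(160, 175))
    tr <- structure(list(mph_cm = NA_real_, ltr_cm = NA_real_,
                         mph_sds = NA_real_, ltr_sds = ltr_sds,
                         completeness = "both_measured"),
                    class = "target_range")
    classify(g, tr = tr)
  }
  # a girl taller than her family floor and the population floor
  r <- mk(-1.52, -2.45)
  expect_false(r$below_family)
  expect_false(r$short_population)
  # short for the population but within her family's range
  r <- mk(-2.15, -2.78)
  expect_false(r$below_family)
  expect_true(r$short_population)
  # below both
  r <- mk(-2.9, -2.1)
  expect_true(r$below_family)
  expect_true(r$short_population)
  # exactly -2.00 is not short: the comparison is strict
  expect_false(mk(-2.00, -3)$short_population)
  # exactly at the LTR is not below family
  expect_false(mk(-1.5, -1.5)$below_family)
})

test_that("age banding and the excluded-record signal", {
  expect_equal(as.character(age_band(c(1.5, 5, 5.1, 10, 10.1, 16, 16.5))),
               c("band_1_5", "band_1_5", "band_5_10", "band_5_10",
                 "band_10_16", "band_10_16", "out_of_band"))
  g <- girl_record("tooyoung", 0.9, height_sds = -2)
  expect_error(classify(g), class = "excluded_record")
  cnd <- tryCatch(classify(g), condition = function(c) c)
  expect_equal(cnd$id, "tooyoung")
  # records need a reference if they only carry raw height
  g2 <- girl_record("raw", 4, height_cm = 95)
  expect_error(classify(g2), "height_ref")
  expect_equal(classify(g2, height_ref = href)$ht_sds,
               lms_zscore(95, 4, href))
})

test_that("height_sds wins over height_cm with a warning", {
  g <- girl_record("both", 4, height_cm = 95, height_sds = -1.23)
  expect_warning(r <- classify(g, height_ref = href), "using height_sds")
  expect_equal(r$ht_sds, -1.23)
})

test_that("sensitivity table reproduces published per-band counts", {
  # counts 28/38, 27/30, 21/24 below the LTR per band; 27/25/22 below -2
  set.seed(1)
  band_spec <- list(
    list(ages = c(2, 4.5), n = 38, below = 28, short = 27),
    list(ages = c(6, 9.5), n = 30, below = 27, short = 25),
    list(ages = c(11, 15), n = 24, below = 21, short = 22))
  recs <- do.call(rbind, lapply(band_spec, function(b) {
    ht <- numeric(b$n)
    # place records so that below-family and short counts are as specified,
    # allowing the two flags to overlap arbitrarily
    below <- seq_len(b$n) <= b$below
    short <- seq_len(b$n) <= b$short
    ht[below & short] <- -3
    ht[below & !short] <- -1.9   # below LTR, not short
    ht[!below & short] <- -2.1   # short, above LTR
    ht[!below & !short] <- -1
    ltr <- ifelse(below, ht + 0.5, ht - 0.5)
    ltr[below & !short] <- -1.5
    ltr[!below & short] <- -2.5
    make_classified(age = rep(b$ages, length.out = b$n), ht_sds = ht,
                    ltr_sds = ltr)
  }))
  tab <- sensitivity_table(recs)
  ov <- tab[tab$band == "overall", ]
  expect_equal(tab$n_below_ltr[1:3], c(28, 27, 21))
  expect_equal(ov$n_below_ltr, 76)
  expect_equal(ov$n_total, 92)
  expect_equal(tab$pct_below_ltr[1:3], c(74, 90, 88))
  expect_equal(ov$pct_below_ltr, 83)
  expect_equal(ov$n_short_population, 74)
  expect_equal(ov$pct_short, 80)
  # partition identities, per band and overall
  expect_equal(tab$n_below_ltr + tab$n_at_or_above_ltr, tab$n_total)
  expect_equal(tab$n_short_population + tab$n_not_short, tab$n_total)
  expect_equal(sum(tab$n_total[tab$band != "overall"]), ov$n_total)
  # order independence: shuffling records leaves the table unchanged
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(sensitivity_table(shuffled), tab)
})

test_that("sensitivity table edge cases", {
  all_below <- make_classified(age = rep(c(2, 7, 12), 4), ht_sds = -3,
                               ltr_sds = -2)
  tab <- sensitivity_table(all_below)
  expect_equal(tab$pct_below_ltr[tab$band == "overall"], 100)
  expect_error(sensitivity_table(all_below[0, ]), "zero records")
  no_ltr <- make_classified(2, -3, NA_real_)
  expect_error(sensitivity_table(no_ltr), "ltr_sds")
})

test_that("birthweight cut-off sensitivities count strictly below", {
  bw <- c(-2.5, -2.1, -1.9, -1.6, -1.4, -0.5, 0.2, 1.1)
  res <- birthweight_sensitivity(bw)
  expect_equal(res$n_below, c(2, 4, 5))
  expect_equal(res$denominator, rep(8, 3))
  expect_equal(res$percent, round(100 * c(2, 4, 5) / 8, 1))
  # monotonicity: lowering a cut-off never increases the count
  set.seed(3)
  r <- birthweight_sensitivity(rnorm(500, -1, 1.2),
                               cutoffs = seq(-3, 1, by = 0.25))
  expect_true(all(diff(r$n_below) >= 0))
  # uniform draws match the empirical CDF at each cut-off (brute force)
  u <- runif(400, -4, 2)
  r2 <- birthweight_sensitivity(u, cutoffs = c(-3, -2, -1, 0))
  expect_equal(r2$n_below, vapply(c(-3, -2, -1, 0),
                                  function(cut) sum(u < cut), integer(1)))
  expect_equal(birthweight_sensitivity(bw, cutoffs = -10)$n_below, 0)
  expect_error(birthweight_sensitivity(numeric(0)), "no records")
})

test_that("crude screening yield: compatibility and exact modes", {
  y <- crude_screening_yield(53802, 0.5, 1 / 2000, 3)
  expect_equal(y$n_short_girls, 800)
  expect_equal(y$n_ts_girls, 13)
  expect_equal(y$ppv_percent, 1.6)
  # exact mode: direct arithmetic, no rounding
  e <- crude_screening_yield(53802, 0.5, 1 / 2000, 3, paper_compat = FALSE)
  expect_equal(e$n_short_girls, 53802 * 0.5 * 0.03)     # 807.03
  expect_equal(e$n_ts_girls, 53802 * 0.5 / 2000)        # 13.4505
  expect_equal(e$ppv_percent, 100 * e$n_ts_girls / e$n_short_girls)
  expect_equal(round(e$n_short_girls), 807)
  expect_equal(round(e$n_ts_girls, 2), 13.45)
  # zero prevalence gives zero PPV
  expect_equal(crude_screening_yield(50000, 0.5, 0, 3)$ppv_percent, 0)
  expect_error(crude_screening_yield(50000, 0.5, 1e-3, 0), "strictly between")
})

test_that("percentage formatting pins the display conventions", {
  expect_equal(percent_format(100 * 78 / 92), 85)      # 84.78 -> 85
  expect_equal(percent_format(100 * 13 / 800, 1), 1.6) # 1.625 -> 1.6 (half-even)
  expect_equal(percent_format(100 * 36 / 135, 1), 26.7)
  expect_equal(percent_format(100 * 142 / 172, 1), 82.6)
  expect_equal(percent_format(100 * 94 / 172, 1), 54.7)          # rounded
  expect_equal(percent_format(100 * 94 / 172, 1, "truncate"), 54.6)
})
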