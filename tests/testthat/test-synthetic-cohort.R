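test_that("the deficit curve is a continuous plateau-then-decline", {
  par <- c(deficit_at_1y = -1.8, slope_after_plateau = -0.1, plateau_age = 4)
  expect_equal(turner_deficit(c(1, 2.5, 4), par), rep(-1.8, 3))
  expect_equal(turner_deficit(5, par), -1.9)
  expect_equal(turner_deficit(4 + 1e-9, par), -1.8, tolerance = 1e-8)
  ages <- seq(1, 18, by = 0.25)
  expect_true(all(diff(turner_deficit(ages, par)) <= 0))
})

test_that("config invariants are enforced before any sampling", {
  expect_error(sim_config(0), "n_girls")
  expect_error(sim_config(10, karyotype_mix = c(`45X` = 0.5, other = 0.4)),
               "sum to 1")
  expect_error(sim_config(10, residual_sd = -0.1), "residual_sd")
  expect_error(sim_config(10, parental_measurement_missingness =
                            c(both = 0.5, one = 0.5, neither = 0.5)),
               "sum to 1")
  expect_error(sim_config(10, age_distribution = c(mean = 7, sd = 4,
                                                   min = 5, max = 2)),
               "age min")
  expect_error(sim_config(10, turner_deficit_params =
                            c(deficit_at_1y = -2, slope_after_plateau = -0.1,
                              plateau_age = 0.5)),
               "plateau_age")
  expect_silent(sim_config(10, residual_sd = 0))
})

test_that("simulation is reproducible and seed-isolated", {
  cfg <- default_sim_config(href, n_girls = 60, seed = 9)
  a <- simulate_cohort(cfg, href, bwref)
  b <- simulate_cohort(cfg, href, bwref)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(simulate_cohort(cfg2, href, bwref), a))
  # the caller's RNG stream is not disturbed
  set.seed(123); x1 <- rnorm(3)
  set.seed(123); invisible(simulate_cohort(cfg, href, bwref)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("degenerate noise: height SDS equals the deficit exactly", {
  cfg <- sim_config(40, seed = 2, residual_sd = 0, parent_child_coupling = 0,
                    karyotype_mix = c(`45X` = 1),
                    parental_measurement_missingness =
                      c(both = 1, one = 0, neither = 0))
  coh <- simulate_cohort(cfg, href, bwref)
  z <- lms_zscore(coh$height_cm, coh$age_years, href)
  expect_equal(z, turner_deficit(coh$age_years, cfg$turner_deficit_params),
               tolerance = 1e-9)
  expect_true(all(coh$karyotype == "45X"))
  expect_true(all(coh$age_years >= 1.31 & coh$age_years <= 18.5))
})

test_that("cohort CSV round-trips losslessly, including missing parents", {
  cfg <- default_sim_config(href, n_girls = 50, seed = 4)
  coh <- simulate_cohort(cfg, href, bwref)
  expect_true(any(coh$mother_source == "missing"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$id, coh$id)
  expect_equal(back$mother_source, coh$mother_source)
  expect_true(all(is.na(back$father_cm[back$father_source == "missing"])))
  for (col in c("age_years", "height_cm", "birthweight_g", "mother_cm",
                "father_cm"))
    expect_equal(back[[col]], coh[[col]], tolerance = 1e-12)
  # a 0-girl cohort writes a header-only file and reads back empty
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh[0, ], f0)
  expect_equal(readLines(f0)[1],
               "id,age_years,height_cm,height_sds,birthweight_g,gestation_weeks,karyotype,mother_cm,mother_source,father_cm,father_source")
  expect_equal(nrow(read_cohort(f0)), 0)
  # schema violations are caught
  expect_error(write_cohort(coh[, -2], f), "missing columns")
  bad <- coh; bad$karyotype[1] <- "47XXY"
  expect_error(write_cohort(bad, f), "karyotype")
})

test_that("large cohorts recover the configured statistical structure", {
  cfg <- default_sim_config(href, n_girls = 10000, seed = 31)
  coh <- simulate_cohort(cfg, href, bwref)
  m <- sim_expected_moments(cfg, href)
  z <- lms_zscore(coh$height_cm, coh$age_years, href)

  se_mean <- m$ht_sd / sqrt(cfg$n_girls)
  expect_lt(abs(mean(z) - m$ht_mean), 3 * se_mean)
  expect_lt(abs(sd(z) - m$ht_sd), 0.05)

  # LTR SDS moments in the both-measured stratum (recorded = true heights)
  both <- coh$mother_source == "measured" & coh$father_source == "measured"
  mph <- (coh$mother_cm[both] + coh$father_cm[both] - 12.5) / 2
  ltr_sds <- lms_zscore(mph - 8.5, rep(20, sum(both)), href)
  expect_lt(abs(mean(ltr_sds) - m$ltr_mean), 3 * m$ltr_sd / sqrt(sum(both)))

  # below-LTR rate against the mixture closed form
  below <- lms_zscore(coh$height_cm[both], coh$age_years[both], href) < ltr_sds
  p <- m$below_ltr_rate
  expect_lt(abs(mean(below) - p), 3 * sqrt(p * (1 - p) / sum(both)))

  # karyotype frequencies converge to the configured mix
  obs <- table(factor(coh$karyotype, levels = names(cfg$karyotype_mix)))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$karyotype_mix))
  expect_gt(gof$p.value, 0.01)

  # birthweight SDS recovered through the reference round-trip
  bw <- lms_zscore(coh$birthweight_g, coh$gestation_weeks, bwref)
  expect_lt(abs(mean(bw) - cfg$bw_sds_distribution[["mean"]]),
            3 * cfg$bw_sds_distribution[["sd"]] / sqrt(cfg$n_girls))
  expect_true(all(coh$gestation_weeks >= 27 & coh$gestation_weeks <= 44))
})

test_that("family-referenced sensitivity rises across the age bands", {
  cfg <- default_sim_config(href, n_girls = 8000, seed = 17)
  coh <- simulate_cohort(cfg, href, bwref)
  res <- run_analysis(coh, href, bwref)
  tab <- res$sensitivity
  pct <- tab$pct_below_ltr[match(c("band_1_5", "band_5_10", "band_10_16"),
                                 tab$band)]
  expect_true(all(diff(pct) > 0))
})
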