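test_that("LMS tables read, validate and normalise row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "1,1,80,0.04", "10,1,140,0.04", "20,1,163,0.04"),
             f)
  ref <- read_lms_table(f, sex = "female", measurement = "height_for_age")
  expect_s3_class(ref, "lms_reference")
  expect_equal(nrow(ref$grid), 3)
  expect_equal(ref$age_min, 1)
  expect_equal(ref$age_max, 20)

  # unsorted input yields the same reference as sorted input, field by field
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "20,1,163,0.04", "1,1,80,0.04", "10,1,140,0.04"),
             f2)
  ref2 <- read_lms_table(f2, sex = "female", measurement = "height_for_age")
  expect_identical(ref2, ref)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "1,1,0,0.04", "10,1,140,0.04"), f3)
  expect_error(read_lms_table(f3, "female", "height_for_age"), "M > 0")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "1,1,80,0.04", "1,1,81,0.04"), f4)
  expect_error(read_lms_table(f4, "female", "height_for_age"), "duplicate")

  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "1,1,80,0.04"), f5)
  expect_error(read_lms_table(f5, "female", "height_for_age"), "at least 2")

  f6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("years,L,M,S", "1,1,80,0.04", "2,1,85,0.04"), f6)
  expect_error(read_lms_table(f6, "female", "height_for_age"), "header")

  # write/read round-trip preserves the grid
  f7 <- withr::local_tempfile(fileext = ".csv")
  write_lms_table(ref, f7)
  expect_equal(read_lms_table(f7, "female", "height_for_age")$grid, ref$grid)
})

test_that("z-score formula: median, power branch, log branch", {
  ref <- flat_ref(L = 1, M = 100, S = 0.1)
  expect_equal(lms_zscore(100, 10, ref), 0)
  expect_equal(lms_zscore(110, 10, ref), 1)

  log_ref <- flat_ref(L = 0, M = 3.5, S = 0.12)
  expect_equal(lms_zscore(3.5 * exp(0.12), 10, log_ref), 1)
  expect_equal(lms_zscore(3.5, 1, log_ref), 0)

  # with L = 1 everywhere the transform reduces to (x - M)/(M*S) exactly
  x <- c(85, 100, 123.4)
  expect_equal(lms_zscore(x, 10, ref), (x - 100) / (100 * 0.1))
})

test_that("interpolation between grid rows matches an independent oracle", {
  set.seed(11)
  grid <- data.frame(age = c(2, 6, 9, 15),
                     L = c(1.2, 0.7, -0.3, 0.1),
                     M = c(90, 115, 132, 158),
                     S = c(0.035, 0.04, 0.045, 0.05))
  ref <- lms_reference(grid$age, grid$L, grid$M, grid$S, "female",
                       "height_for_age")
  for (k in 1:25) {
    age <- runif(1, 2, 15)
    x <- runif(1, 70, 170)
    expect_equal(lms_zscore(x, age, ref), oracle_z(x, age, grid),
                 tolerance = 1e-12)
  }
  # at a grid age the interpolated conversion equals the direct row formula
  expect_equal(lms_zscore(120, 6, ref),
               ((120 / 115)^0.7 - 1) / (0.7 * 0.04))
})

test_that("value/z-score round-trip is the identity and monotone", {
  refs <- list(flat_ref(L = 1), flat_ref(L = 0, M = 120, S = 0.05),
               flat_ref(L = -0.8, M = 140, S = 0.04), href)
  set.seed(7)
  for (ref in refs) {
    ages <- c(ref$grid$age[1], 10,
              runif(5, ref$age_min, ref$age_max))
    for (age in ages) {
      z <- seq(-4, 4, by = 0.5)
      x <- lms_value(z, age, ref)
      expect_equal(lms_zscore(x, age, ref), z, tolerance = 1e-9)
      expect_true(all(diff(x) > 0))  # monotone increasing in z
    }
  }
  expect_equal(lms_value(0, 10, flat_ref(M = 100)), 100)
  expect_equal(lms_value(1, 10, flat_ref(L = 1, M = 100, S = 0.1)), 110)
})

test_that("the two L branches agree at the switch threshold", {
  near0 <- flat_ref(L = 1e-8, M = 120, S = 0.05)
  at0 <- flat_ref(L = 0, M = 120, S = 0.05)
  x <- c(90, 120, 150)
  expect_equal(lms_zscore(x, 10, near0), lms_zscore(x, 10, at0),
               tolerance = 1e-6)
  # continuity from above the threshold too
  tiny <- flat_ref(L = 1e-6, M = 120, S = 0.05)
  expect_equal(lms_zscore(x, 10, tiny), lms_zscore(x, 10, at0),
               tolerance = 1e-5)
})

test_that("out-of-grid ages, sex mismatch and inverse domain errors", {
  ref <- flat_ref()
  expect_error(lms_zscore(100, 0.5, ref), "outside reference grid")
  expect_error(lms_zscore(100, 25, ref), "outside reference grid")
  expect_error(lms_value(0, 30, ref), "outside reference grid")
  expect_error(lms_zscore(100, 10, ref, sex = "male"), "sex mismatch")
  expect_silent(lms_zscore(100, 10, ref, sex = "female"))
  expect_error(lms_zscore(-5, 10, ref), "positive")

  # for L < 0 the admissible z range is bounded above at 1/(|L|*S)
  neg <- flat_ref(L = -2, M = 100, S = 0.1)
  expect_error(lms_value(6, 10, neg), "admissible")
  expect_silent(lms_value(4.9, 10, neg))  # bound is 1/(2*0.1) = 5
})

test_that("centile/z conversion is the standard normal quantile", {
  expect_equal(centile_to_z(50), 0)
  expect_equal(round(centile_to_z(2.5), 2), -1.96)
  expect_equal(round(centile_to_z(3), 2), -1.88)
  for (c in c(1, 2.5, 10, 37, 50))
    expect_equal(centile_to_z(100 - c), -centile_to_z(c))
  expect_error(centile_to_z(0), "strictly between")
  expect_error(centile_to_z(100), "strictly between")
  expect_equal(z_to_centile(centile_to_z(2.5)), 2.5)
})
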