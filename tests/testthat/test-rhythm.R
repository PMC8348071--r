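test_that("cv_rr matches hand arithmetic and exposes both SD conventions", {
  expect_equal(cv_rr(c(800, 1000, 1200)), 20)           # sample SD 200, mean 1000
  expect_equal(cv_rr(c(800, 800, 800)), 0)
  expect_equal(cv_rr(c(800, 1000, 1200), sd_type = "population"),
               100 * 200 * sqrt(2 / 3) / 1000)
  expect_error(cv_rr(1000), class = "cscine_insufficient_data")
})

test_that("cv_rr is scale invariant", {
  set.seed(101)
  for (i in 1:20) {
    x <- runif(sample(5:50, 1), 400, 1600)
    k <- runif(1, 0.1, 10)
    expect_equal(cv_rr(k * x), cv_rr(x))
  }
})

test_that("irregularity classification uses a strict threshold", {
  expect_false(classify_irregular(c(900, 900, 900)))
  # series engineered to CV exactly 10%: mean 1000, sample SD 100
  x <- c(1000 - 100 / sqrt(2), 1000 + 100 / sqrt(2))
  expect_equal(cv_rr(x), 10)
  expect_false(classify_irregular(x))
  # minimum enrolled irregularity (10.2%) and the cohort mean (25%) both classify
  x102 <- c(1000 - 102 / sqrt(2), 1000 + 102 / sqrt(2))
  expect_true(classify_irregular(x102))
  x25 <- c(1000 - 250 / sqrt(2), 1000 + 250 / sqrt(2))
  expect_equal(cv_rr(x25), 25)
  expect_true(classify_irregular(x25))
})

test_that("generate_rr honours its contract for every pattern", {
  # zero target variability collapses to a constant series
  for (pat in c("afib", "ectopy", "pauses")) {
    rr <- generate_rr(arrhythmia_spec(850, pat, 0, 64, seed = 1))
    expect_true(all(rr$rr_ms == 850))
    expect_equal(cv_rr(rr), 0)
  }
  # fixed seed is bitwise reproducible
  a <- generate_rr(arrhythmia_spec(850, "afib", 25, 256, seed = 1))
  b <- generate_rr(arrhythmia_spec(850, "afib", 25, 256, seed = 1))
  expect_identical(a$rr_ms, b$rr_ms)
  # realised CV within +/-20% relative of target for n >= 64
  expect_gt(cv_rr(a), 20)
  expect_lt(cv_rr(a), 30)
  # dropped-beat pattern produces near-doubled cycles
  rp <- generate_rr(arrhythmia_spec(1000, "pauses", 30, 128, seed = 7))
  expect_gte(max(rp$rr_ms), 1800)
  # ectopy produces short-coupled beats below the baseline
  re <- generate_rr(arrhythmia_spec(900, "ectopy", 30, 128, seed = 3))
  expect_lt(min(re$rr_ms), 0.75 * 900)
  # invalid specifications are rejected
  expect_error(arrhythmia_spec(-10, "afib", 20, 64, seed = 1), class = "cscine_invalid_spec")
  expect_error(arrhythmia_spec(800, "afib", 120, 64, seed = 1), class = "cscine_invalid_spec")
  expect_error(arrhythmia_spec(800, "afib", 20, 1, seed = 1), class = "cscine_invalid_spec")
  expect_error(arrhythmia_spec(800, "afib", 20, 64), class = "cscine_invalid_spec")
})

test_that("the generators are calibrated in the mean across seeds", {
  for (pat in c("afib", "ectopy", "pauses")) {
    for (target in c(15, 25, 40)) {
      cvs <- vapply(1:100, function(s)
        cv_rr(generate_rr(arrhythmia_spec(850, pat, target, 256, seed = s))),
        numeric(1))
      expect_lt(abs(mean(cvs) - target) / target, 0.05)
    }
  }
})

test_that("trigger-time differencing recovers RR intervals", {
  expect_equal(rr_from_dicom_fields(c(0, 800, 1600))$rr_ms, c(800, 800))
  expect_equal(rr_from_dicom_fields(c(0, 700, 1700, 2300))$rr_ms, c(700, 1000, 600))
  expect_error(rr_from_dicom_fields(c(0, 800, 750)), class = "cscine_corrupt_timing")
  expect_error(rr_from_dicom_fields(c(0, 800)), class = "cscine_insufficient_data")
})

test_that("RR series round-trip through CSV and summarise tidily", {
  rr <- generate_rr(arrhythmia_spec(900, "afib", 20, 32, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, f)
  expect_equal(read_rr_csv(f)$rr_ms, rr$rr_ms)
  g <- glance(rr)
  expect_equal(g$n_beats, 32)
  expect_equal(g$cv_rr_pct, cv_rr(rr))
  expect_equal(g$mean_hr_bpm, 60000 / mean(rr$rr_ms))
})
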