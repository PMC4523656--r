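test_that("descriptive statistics are exact order statistics", {
  amp <- array(c(1, 2, 3, 4, 5), c(5, 1, 1))
  mask <- array(TRUE, c(5, 1, 1))
  st <- tissue_descriptive_stats(amp, mask, "t")
  expect_equal(st$median, 3)
  expect_equal(st$min, 1)
  expect_equal(st$max, 5)
  expect_equal(st$voxel_count, 5L)
  # constant field: every statistic equals the constant
  stc <- tissue_descriptive_stats(array(2.5, c(4, 4, 1)),
                                  array(TRUE, c(4, 4, 1)))
  expect_true(all(unlist(stc[c("median", "q25", "q75", "min", "max",
                               "peak")]) == 2.5))
  expect_error(tissue_descriptive_stats(amp, array(FALSE, c(5, 1, 1))),
               "empty")
})

test_that("percentiles match a brute-force sort computation", {
  set.seed(101)
  v <- rexp(1000)
  amp <- array(v, c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  st <- tissue_descriptive_stats(amp, mask)
  # independent linear-interpolation quantile on the sorted sample
  s <- sort(v)
  manual_q <- function(p) {
    k <- (length(s) - 1) * p
    lo <- floor(k)
    s[lo + 1] * (1 - (k - lo)) + s[lo + 2 - (k == lo)] * (k - lo)
  }
  expect_equal(st$q25, manual_q(0.25), tolerance = 1e-12)
  expect_equal(st$median, manual_q(0.5), tolerance = 1e-12)
  expect_equal(st$q75, manual_q(0.75), tolerance = 1e-12)
  expect_true(st$min <= st$q25 && st$q25 <= st$median &&
                st$median <= st$q75 && st$q75 <= st$max)
})

test_that("focality fractions count strictly above the threshold", {
  amp <- array(c(1.0, 0.8, 0.6, 0.4), c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  expect_equal(focality_volume_fraction(amp, mask, 0.7), 50)
  expect_equal(focality_volume_fraction(amp, mask, 0.5), 75)
  # constant field: the peak itself is not strictly above any fraction
  # of itself times < 1... every voxel equals the peak, so all qualify
  cst <- array(2, c(3, 3, 1)); mk <- array(TRUE, c(3, 3, 1))
  expect_equal(focality_volume_fraction(cst, mk, 0.7), 100)
  expect_equal(focality_volume_fraction(cst, mk, 0.5), 100)
  expect_error(focality_volume_fraction(amp, mask, 1.2), "in \\(0, 1\\)")
  expect_error(focality_volume_fraction(amp, array(FALSE, c(4, 1, 1)), 0.5),
               "empty")
})

test_that("focality obeys nesting, monotonicity and scale invariance", {
  set.seed(55)
  for (rep in 1:20) {
    v <- rexp(200) + 0.01
    amp <- array(v, c(200, 1, 1)); mask <- array(TRUE, c(200, 1, 1))
    v70 <- focality_volume_fraction(amp, mask, 0.7)
    v50 <- focality_volume_fraction(amp, mask, 0.5)
    expect_lte(v70, v50)
    expect_gt(v70, 0)
    expect_lte(v50, 100)
    # scale invariance
    c0 <- runif(1, 0.1, 10)
    expect_equal(focality_volume_fraction(amp * c0, mask, 0.7), v70)
    # monotone in the threshold
    fr <- vapply(c(0.3, 0.5, 0.7, 0.9), function(t)
      focality_volume_fraction(amp, mask, t), 0)
    expect_true(all(diff(fr) <= 0))
    # brute-force counting oracle
    expect_equal(v70, 100 * sum(v > 0.7 * max(v)) / length(v))
  }
})

test_that("cv_db follows the 20 log10(1 + sd/mean) convention", {
  expect_equal(cv_db(c(3, 3, 3)), 0)
  # sd = mean (CV = 1) maps to ~6.02 dB
  v <- c(1, 2, 3)  # mean 2, sample sd 1, CV 0.5
  expect_equal(cv_db(v), 20 * log10(1.5), tolerance = 1e-12)
  expect_equal(cv_db(v), 3.5218, tolerance = 1e-4)
  # sd = mean (CV = 1) maps to 20 log10(2) ~ 6.02 dB
  expect_equal(cv_db(c(1, 3 + 2 * sqrt(2))), 20 * log10(2),
               tolerance = 1e-9)
  # alternative raw convention
  expect_equal(cv_db(v, convention = "raw"), 20 * log10(0.5))
  # population sd option
  expect_equal(cv_db(v, sd_denominator = "n"),
               20 * log10(1 + sqrt(2 / 3) / 2), tolerance = 1e-12)
  expect_error(cv_db(c(1, -3)), "mean must be positive")
  expect_error(cv_db(3), "at least 2")
})

test_that("cv_db is scale- and permutation-invariant", {
  set.seed(77)
  for (rep in 1:20) {
    v <- rlnorm(5)
    expect_equal(cv_db(v * runif(1, 0.01, 100)), cv_db(v),
                 tolerance = 1e-12)
    expect_equal(cv_db(sample(v)), cv_db(v), tolerance = 1e-12)
    expect_gte(cv_db(v), 0)
  }
})

test_that("threshold fractions translate to the conventional dB reductions", {
  expect_equal(round(db_reduction(0.7)), 3)
  expect_equal(round(db_reduction(0.5)), 6)
  expect_equal(db_reduction(0.7), 3.098, tolerance = 1e-3)
  expect_equal(db_reduction(0.5), 6.021, tolerance = 1e-3)
  expect_equal(db_reduction(1), 0)
  expect_error(db_reduction(0), "positive")
  expect_error(db_reduction(-1), "positive")
})

test_that("the robust peak option uses the 99.9th percentile", {
  set.seed(9)
  v <- c(runif(999), 100)  # one outlier
  amp <- array(v, c(1000, 1, 1)); mask <- array(TRUE, c(1000, 1, 1))
  st <- tissue_descriptive_stats(amp, mask, robust_peak = TRUE)
  expect_lt(st$peak, 100)
  expect_equal(st$max, 100)
  v70r <- focality_volume_fraction(amp, mask, 0.7, robust_peak = TRUE)
  v70 <- focality_volume_fraction(amp, mask, 0.7)
  expect_gt(v70r, v70)
})
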