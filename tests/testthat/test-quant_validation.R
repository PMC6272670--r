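test_that("calibration fitting recovers generating lines", {
  ng <- c(10, 50, 100, 500, 1000)
  cv <- fit_calibration(ng, 0.9845 * ng - 3.0467, compound_id = 1)
  expect_equal(cv$slope, 0.9845, tolerance = 1e-10)
  expect_equal(cv$intercept, -3.0467, tolerance = 1e-8)
  expect_equal(cv$r2, 1)
  # flat response: zero slope, zero r2
  cv0 <- fit_calibration(c(1, 2, 3), c(5, 5, 5))
  expect_equal(cv0$slope, 0)
  expect_equal(cv0$r2, 0)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  # noisy fit lands within 3 standard errors of the truth
  set.seed(41)
  ok <- vapply(1:50, function(i) {
    x <- c(1, 2, 3, 5, 10, 15, 20, 25, 35) * 40
    y <- 1.2 * x + 5 + rnorm(length(x), 0, 10)
    fit <- stats::lm(y ~ x)
    abs(stats::coef(fit)[2] - 1.2) < 3 * summary(fit)$coefficients[2, 2]
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("quantification inverts the line and converts to content", {
  cv <- fit_calibration(c(10, 100, 1000), 1.8986 * c(10, 100, 1000) + 12.2728)
  expect_equal(quantify(1.8986 * 100 + 12.2728, cv), 100, tolerance = 1e-9)
  expect_warning(quantify(1e7, cv), "outside the calibrated range")
  expect_error(quantify(5, fit_calibration(c(1, 2, 3), c(7, 7, 7))), "zero")
  # the study constants give 0.0025 mg/g per ng
  expect_equal(content_mg_per_g(2894.8), 7.237)
  expect_equal(content_mg_per_g(0), 0)
  expect_equal(content_mg_per_g(1000, sample_mg = 200), 5)
})

test_that("LOD and LOQ come from the 3:1 and 10:1 signal-to-noise rule", {
  series <- data.frame(ng = 1:40, signal = 1:40, noise = 1)
  ll <- lod_loq(series)
  expect_equal(ll$lod_ng, 3)
  expect_equal(ll$loq_ng, 10)
  # a series that never reaches 10:1 has an absent LOQ, not zero
  low <- data.frame(ng = 1:5, signal = (1:5) * 1.2, noise = 1)
  expect_equal(lod_loq(low)$loq_ng, NA_real_)
  expect_error(lod_loq(data.frame(ng = c(2, 1), signal = 1:2, noise = 1)),
               "sorted")
  # analytic check against a known generator: S/N = k*ng/sigma
  k <- 0.8; sigma <- 12
  ser <- data.frame(ng = seq(10, 200, by = 10))
  ser$signal <- k * ser$ng; ser$noise <- sigma
  ll2 <- lod_loq(ser)
  expect_lte(abs(ll2$lod_ng - 3 * sigma / k), 10)   # one dilution step
  expect_lte(abs(ll2$loq_ng - 10 * sigma / k), 10)
})

test_that("RSD uses the sample standard deviation and printed rounding", {
  contents <- reference_table("content")
  expect_equal(rsd(contents$c1), 30.54)
  expect_equal(rsd(rep(4.2, 6)), 0)
  set.seed(42)
  x <- runif(10, 1, 5)
  expect_equal(rsd(x, digits = NULL), rsd(3.7 * x, digits = NULL))
  expect_error(rsd(1), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("spike recovery reproduces the published accuracy table", {
  rec <- reference_table("recovery")
  computed <- recovery(rec$original_ug, rec$spiked_ug, rec$observed_ug)
  for (cmp in c(1, 2, 3, 5)) {
    expect_equal(computed[rec$compound == cmp],
                 rec$recovery_mean[rec$compound == cmp])
  }
  # exactness property: observing exactly original + spike is 100%
  set.seed(43)
  x <- runif(10, 0, 500); s <- runif(10, 1, 500)
  expect_true(all(recovery(x, s, x + s) == 100))
  expect_error(recovery(1, 0, 2), "positive")
})

test_that("batch summaries recompute means, RSDs and totals", {
  contents <- reference_table("content")
  m <- contents[, paste0("c", 1:14)]
  sm <- summarize_batches(m, declared_total = 28.531)
  # per-batch totals agree with the printed Sum column
  # printed Sums are consistent with their cells to the 0.001 rounding unit
  expect_true(all(abs(sm$batch_sum - contents$sum_printed) <= 0.001 + 1e-9))
  expect_equal(round_half_up(unname(sm$compound_average[7]), 3), 7.237)
  expect_equal(unname(sm$compound_rsd[7]), 36.79)
  # the declared grand total disagrees with the recomputed one and is flagged
  expect_length(sm$flags, 1)
  expect_match(sm$flags, "disagrees")
  # single-batch table: sums fine, RSD undefined
  one <- summarize_batches(m[1, , drop = FALSE])
  expect_equal(unname(one$batch_sum), contents$sum_printed[1],
               tolerance = 0.001)
  expect_true(all(is.na(one$compound_rsd)))
  expect_error(summarize_batches(m[0, ]), "empty")
})

test_that("validation_report assembles per-compound metrics", {
  set.seed(44)
  intraday <- data.frame(compound = rep(1:2, each = 6),
                         value = c(rnorm(6, 100, 0.5), rnorm(6, 200, 2)))
  dilution <- data.frame(compound = 1, ng = 1:20, signal = 1:20, noise = 1)
  rec <- data.frame(compound = 1, original_ug = 163.01, spiked_ug = 164.02,
                    observed_ug = 329.03)
  rep_df <- validation_report(dilution = dilution, intraday = intraday,
                              recovery_data = rec)
  expect_equal(rep_df$compound, 1:2)
  expect_equal(rep_df$lod_ng[1], 3)
  expect_equal(rep_df$loq_ng[1], 10)
  expect_equal(rep_df$recovery_mean[1], 101.22)
  expect_true(is.na(rep_df$lod_ng[2]))
  expect_true(all(rep_df$intraday_rsd >= 0))
  expect_error(validation_report(), "no validation inputs")
})

test_that("full quantification pipeline inverts the synthetic generator", {
  curves <- reference_table("calibration")
  contents <- reference_table("content")
  truth <- as.matrix(contents[, paste0("c", 1:14)])
  sim <- simulate_quant_dataset(curves, truth,
                                sim_config(seed = 7, sigma_area = 0))
  for (j in 1:14) {
    cal <- sim$calibration[sim$calibration$compound == j, ]
    cv <- fit_calibration(cal$ng, cal$area, j)
    ar <- sim$sample_areas[sim$sample_areas$compound == j, ]
    got <- content_mg_per_g(quantify(ar$area, cv))
    expect_equal(got, unname(truth[, j]), tolerance = 1e-8)
  }
})
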