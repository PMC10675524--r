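test_that("EMG resampling to the frame grid uses bin means", {
  const <- c(rep(0, 100), rep(2.5, 3003))
  fr <- resample_emg_to_frames(const, 1000, 100L)
  expect_length(fr, 90)
  expect_true(all(fr == 2.5))
  # ramp input: per-bin means recomputed by direct summation
  amp <- c(rep(0, 100), seq(0, 2.999, by = 0.001))
  fr2 <- resample_emg_to_frames(amp, 1000, 100L)
  post <- amp[101:length(amp)]
  oracle <- vapply(0:89, function(i) {
    idx <- which(floor((seq_along(post) - 1) / 1000 * 29.97) == i)
    mean(post[idx])
  }, numeric(1))
  expect_equal(fr2, oracle)
  expect_error(resample_emg_to_frames(stats::rnorm(500), 1000, 100L),
               "too short")
})

test_that("quality masking excludes trials per software and policy", {
  d <- small_design()
  p <- quiet_params()
  tr <- simulate_trial(d, p, "positive", "video",
                       software_tag = "facereader_like", seed = 2)
  tr$quality <- rep(1, length(tr$quality))
  clean <- apply_quality_mask(tr)
  expect_false(clean$excluded)
  expect_equal(clean$au12, tr$au12)
  # one sub-threshold frame under any_frame policy excludes the trial
  tr_dip <- tr
  tr_dip$quality[40] <- 0.5
  masked <- apply_quality_mask(tr_dip)
  expect_true(masked$excluded)
  expect_equal(masked$reason, "low_quality")
  expect_true(is.na(masked$au12[40]))
  # the fraction policy tolerates it
  frac <- quality_thresholds(exclusion_policy = "fraction",
                             max_bad_fraction = 0.1)
  kept <- apply_quality_mask(tr_dip, frac)
  expect_false(kept$excluded)
  expect_true(is.na(kept$au12[40]))
  # all-zero openface output is excluded as zero_output
  tr_zero <- tr
  tr_zero$software_tag <- "openface_like"
  tr_zero$au12 <- rep(0, length(tr_zero$au12))
  z <- apply_quality_mask(tr_zero)
  expect_true(z$excluded)
  expect_equal(z$reason, "zero_output")
  # unknown software tag is an error
  tr_bad <- tr
  tr_bad$software_tag <- "affdex"
  expect_error(apply_quality_mask(tr_bad), "software_tag")
})

test_that("zero anchoring shifts by the first (non-missing) value", {
  expect_equal(zero_anchor(c(3, 4, 5)), c(0, 1, 2))
  anchored <- c(0, 0.5, -0.2)
  expect_equal(zero_anchor(anchored), anchored) # idempotent
  set.seed(5)
  x <- stats::rnorm(20)
  out <- zero_anchor(x)
  expect_equal(out[1], 0)
  expect_equal(diff(out), diff(x))
  expect_message(out_na <- zero_anchor(c(NA, 2, 3)), "non-missing")
  expect_equal(out_na, c(NA, 0, 1))
})

test_that("group averaging returns per-frame means and standard errors", {
  same <- list(c(1, 2, 3), c(1, 2, 3))
  g <- group_average_timeseries(same)
  expect_true(all(g$se == 0))
  two <- list(c(0, 2), c(0, 4))
  expect_equal(group_average_timeseries(two)$mean, c(0, 3))
  # anchoring happens before averaging
  offset <- list(c(1, 3), c(2, 6))
  expect_equal(group_average_timeseries(offset)$mean, c(0, 3))
  expect_error(group_average_timeseries(list(c(1, 2))), "at least 2")
})

test_that("group-average AU12 follows the generator's drive curve", {
  d <- small_design()
  p <- quiet_params(au_noise_sd = 0.05, au_latency_frames = 0)
  trials <- lapply(seq_len(100), function(i)
    simulate_trial(d, p, "positive", "video", seed = 3000 + i)$au12)
  g <- group_average_timeseries(trials)
  centres <- (seq_len(90) - 0.5) / d$au_fps
  expected <- drive(centres, p) * p$au_scale * p$zm_gain_pos_video
  expected <- expected - expected[1]
  ok <- abs(g$mean - expected) <= 3 * pmax(g$se, 1e-6)
  expect_gte(mean(ok), 0.9)
})

test_that("cross-correlation satisfies its identities and bounds", {
  set.seed(41)
  x <- stats::rnorm(90)
  auto <- cross_correlation(x, x)
  expect_equal(auto$peak_lag, 0L)
  expect_equal(auto$r[auto$lags == 0], 1, tolerance = 1e-9)
  y <- stats::rnorm(90)
  fwd <- cross_correlation(x, y, peak_search = "full")
  bwd <- cross_correlation(y, x, peak_search = "full")
  expect_equal(fwd$r, rev(bwd$r), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(fwd$r) <= 1 + 1e-9))
  expect_warning(z <- cross_correlation(rep(1, 90), y), "zero-variance")
  expect_true(z$degenerate)
  expect_error(cross_correlation(x, y[1:50]), "equal length")
  expect_error(cross_correlation(x[1:60], y[1:60], max_lag = 45),
               "too short")
})

test_that("an injected shift is recovered by the per-lag Pearson variant", {
  fps <- 29.97
  p <- ground_truth_params()
  centres <- (seq_len(90) - 0.5) / fps
  x <- drive(centres, p)
  y <- drive(centres - 4 / fps, p)
  pear <- cross_correlation(x, y, normalization = "pearson")
  expect_identical(pear$peak_lag, 4L)
  expect_equal(pear$peak_r, 1, tolerance = 1e-9)
  expect_identical(pear$latency_ms, lag_to_ms(4L))
  # the standardized (full-N) convention tapers r away from lag 0 on this
  # ramp-plateau drive, so its peak cannot exceed the injected shift
  std <- cross_correlation(x, y)
  expect_lte(std$peak_lag, 4L)
})

test_that("aggregation averages trials within subject before the group", {
  set.seed(51)
  x <- stats::rnorm(90)
  y <- c(stats::rnorm(3), x)[1:90]
  one <- cross_correlation(x, y)
  same <- aggregate_xcorr(list(one, one, one),
                          subject = c("a", "a", "b"),
                          condition = rep("positive_live", 3))
  expect_equal(same$curves$r, one$r, ignore_attr = TRUE)
  # coarser rounding can only widen a reported peak plateau
  fine <- aggregate_xcorr(list(one), "a", "positive_live", digits = 6)
  coarse <- aggregate_xcorr(list(one), "a", "positive_live", digits = 1)
  width <- function(p) p$peaks$peak_lag_max - p$peaks$peak_lag_min
  expect_gte(width(coarse), width(fine))
  # balanced opposite shifts: full-search group peak near zero
  p <- ground_truth_params()
  centres <- (seq_len(90) - 0.5) / 29.97
  base <- drive(centres, p)
  plus <- cross_correlation(base, drive(centres - 2 / 29.97, p),
                            peak_search = "full",
                            normalization = "pearson")
  minus <- cross_correlation(base, drive(centres + 2 / 29.97, p),
                             peak_search = "full",
                             normalization = "pearson")
  bal <- aggregate_xcorr(list(plus, minus), c("a", "b"),
                         rep("positive_video", 2), peak_search = "full")
  expect_lte(abs(bal$peaks$peak_lag_min), 2)
  expect_lte(abs(bal$peaks$peak_lag_max), 2)
})

test_that("lag-to-milliseconds conversion rounds to the nearest integer", {
  expect_identical(lag_to_ms(0), 0L)
  expect_identical(lag_to_ms(1), 33L)
  expect_identical(lag_to_ms(5), 167L)
  expect_identical(lag_to_ms(c(6, 9)), c(200L, 300L))
  # 45 lags at 29.97 fps span just over 1.5 s
  expect_gte(45 / 29.97, 1.50)
  expect_lte(45 / 29.97, 1.51)
})
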