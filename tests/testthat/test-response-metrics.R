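test_that("trial response is the maximal-window minus neutral-window mean", {
  w <- response_windows()
  expect_equal(trial_response(rep(2.5, 300), 100, w), 0)
  # step of height h at 1.5 s
  t <- (0:299) / 100
  h <- 0.8
  expect_equal(trial_response(ifelse(t < 1.5, 0, h), 100, w), h)
  # frame-series oracle at 29.97 fps: direct window-mean recomputation
  fps <- 29.97
  s <- c(rep(0, 30), seq(0, 1, length.out = 45), rep(1, 15))
  expect_equal(trial_response(s, fps, w),
               mean(s[76:90]) - mean(s[1:30]))
  expect_error(trial_response(rnorm(50), fps, w), "outside")
})

test_that("sign congruence counts matching signs with zero as negative", {
  all_same <- data.frame(au_response = c(1, 2, -1), emg_response = c(3, 1, -2))
  expect_equal(sign_congruence_accuracy(all_same), 1)
  four <- data.frame(au_response = c(1, 1, -1, -1),
                     emg_response = c(1, -1, -1, 1))
  expect_equal(sign_congruence_accuracy(four), 0.5)
  # null AU response is grouped with the negative sign
  zeros <- data.frame(au_response = c(0, 0), emg_response = c(1, -1))
  expect_equal(sign_congruence_accuracy(zeros), 0.5)
  # brute-force enumeration oracle on random pairs
  set.seed(9)
  au <- stats::rnorm(20)
  emg <- stats::rnorm(20)
  hand <- 0
  for (i in 1:20) if ((au[i] > 0) == (emg[i] > 0)) hand <- hand + 1
  expect_equal(sign_congruence_accuracy(
    data.frame(au_response = au, emg_response = emg)), hand / 20)
})

test_that("excluded trials leave the congruence denominator unless requested", {
  pairs <- data.frame(au_response = c(1, 0, -1),
                      emg_response = c(1, 1, 1),
                      excluded = c(FALSE, TRUE, FALSE),
                      reason = c("none", "zero_output", "none"))
  expect_equal(sign_congruence_accuracy(pairs), 0.5)
  expect_equal(sign_congruence_accuracy(pairs, include_zero_output = TRUE),
               1 / 3)
  all_out <- data.frame(au_response = 1, emg_response = 1,
                        excluded = TRUE, reason = "artifact")
  expect_error(sign_congruence_accuracy(all_out), "no trials")
})

test_that("mimicry classification follows the detection taxonomy", {
  expect_equal(classify_mimicry_trial(0.05, zm_resp = 0.1), "TP")
  expect_equal(classify_mimicry_trial(0, zm_resp = 0.1), "FN")
  expect_equal(classify_mimicry_trial(-0.2, zm_resp = -0.1), "TN")
  expect_equal(classify_mimicry_trial(0.3, zm_resp = -0.1), "FP")
  # compound mode: mimicking response = ZM contraction with CS relaxation
  expect_equal(classify_mimicry_trial(1, 0, 1, -1, mode = "compound"), "TP")
  # both AUs positive is outside the taxonomy: maps to non-detection
  expect_equal(classify_mimicry_trial(1, 0.5, 1, -1, mode = "compound"), "FN")
  expect_equal(classify_mimicry_trial(-1, 1, 1, 1, mode = "compound"), "TN")
  expect_error(classify_mimicry_trial(1, zm_resp = 1, mode = "compound"),
               "compound")
})

test_that("detection metrics implement the confusion arithmetic", {
  even <- detection_metrics(list(tp = 10, fp = 10, tn = 10, fn = 10))
  expect_equal(even$sensitivity, 0.5)
  expect_equal(even$specificity, 0.5)
  expect_equal(even$ppv, 0.5)
  expect_equal(even$npv, 0.5)
  hand <- detection_metrics(list(tp = 6, fp = 2, fn = 4, tn = 8))
  expect_equal(hand$sensitivity, 0.6)
  expect_equal(hand$specificity, 0.8)
  expect_equal(hand$ppv, 0.75)
  expect_equal(hand$f1, 2 * 6 / (2 * 6 + 2 + 4))
  perfect <- detection_metrics(list(tp = 5, fp = 0, tn = 7, fn = 0))
  expect_true(all(unlist(unclass(perfect)) == 1))
  # undefined metrics are missing, never zero
  nopos <- detection_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$ppv))
})

test_that("confusion tallies match per-trial enumeration on random instances", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    zm <- stats::rnorm(n)
    au <- stats::rnorm(n)
    cc <- confusion_counts(classify_mimicry_trial(au, zm_resp = zm))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
    bf <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (i in seq_len(n)) {
      lab <- if (zm[i] > 0 && au[i] > 0) "TP" else if (zm[i] > 0) "FN"
             else if (au[i] > 0) "FP" else "TN"
      bf[lab] <- bf[lab] + 1
    }
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn),
                 unname(bf[c("TP", "FP", "TN", "FN")]))
  }
})

test_that("zero-output reporting counts all-zero AU12 series", {
  series <- c(replicate(1360, numeric(2), simplify = FALSE),
              replicate(1636, c(0, 0.4), simplify = FALSE))
  rep1 <- zero_output_report(series)
  expect_equal(rep1$n_zero, 1360)
  expect_equal(rep1$n_total, 2996)
  expect_equal(rep1$proportion_display, 0.454)
  expect_equal(zero_output_report(list(c(0, 1), c(1, 1)))$proportion, 0)
})

test_that("strong AU-EMG coupling yields near-perfect smile detection, zero
          coupling tracks the base rate", {
  rc <- simulate_response_cohort(15, 6, au_slope = 1, au_noise_sd = 0.01,
                                 seed = 3)
  pos <- rc[rc$emotion == "positive", ]
  m <- detection_metrics(confusion_counts(
    classify_mimicry_trial(pos$au12_response, zm_resp = pos$zm_response)))
  expect_gt(m$f1, 0.95)
  rc0 <- simulate_response_cohort(40, 8, au_slope = 0, au_noise_sd = 1,
                                  seed = 4)
  pos0 <- rc0[rc0$emotion == "positive", ]
  m0 <- detection_metrics(confusion_counts(
    classify_mimicry_trial(pos0$au12_response, zm_resp = pos0$zm_response)))
  expect_lt(abs(m0$sensitivity - mean(pos0$au12_response > 0)), 0.1)
})

test_that("cohort response extraction records exclusions and validation
          metrics summarise them", {
  d <- small_design(n_subjects = 3, trials_per_condition = 2)
  p <- quiet_params(au_noise_sd = 0.02, seed = 8L)
  coh <- simulate_cohort(d, p, software_tag = "openface_like")
  # force one zero-output trial deterministically
  coh[[1]]$au12 <- rep(0, length(coh[[1]]$au12))
  resp <- cohort_responses(coh)
  expect_equal(nrow(resp), length(coh))
  expect_equal(resp$reason[1], "zero_output")
  expect_true(all(resp$reason %in%
                    c("none", "zero_output", "low_quality", "artifact")))
  vm <- validation_metrics(resp, channel = "AU12")
  expect_equal(vm$n_mimicry,
               sum(resp$emotion == "positive" & !resp$excluded))
  expect_gte(vm$response_accuracy, 0)
  expect_lte(vm$response_accuracy, 1)
})
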