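test_that("rmcorr is exact on perfect within-subject linearity", {
  set.seed(21)
  subject <- rep(1:5, each = 6)
  x <- stats::rnorm(30)
  y <- x + 2 * subject # subject-specific offsets, no noise
  fit <- rmcorr(x, y, subject, n_boot = 50, seed = 1)
  expect_equal(fit$r, 1)
  expect_equal(as.numeric(fit$ci95), c(1, 1))
  expect_lt(fit$p, 1e-10)
})

test_that("rmcorr equals the subject-centred Pearson correlation", {
  set.seed(2)
  subject <- rep(1:3, each = 8)
  x <- stats::rnorm(24)
  y <- 0.4 * x + stats::rnorm(24) + subject
  fit <- rmcorr(x, y, subject)
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  expect_equal(fit$r, stats::cor(xc, yc), tolerance = 1e-10)
  expect_identical(fit$df, 24L - 3L - 1L)
  expect_identical(fit$n_subjects, 3L)
})

test_that("subjects with fewer than two trials are dropped with a warning", {
  set.seed(3)
  subject <- c(rep(1:3, each = 5), 99)
  x <- stats::rnorm(16)
  y <- stats::rnorm(16)
  expect_warning(fit <- rmcorr(x, y, subject), "fewer than 2")
  expect_identical(fit$n_obs, 15L)
  expect_error(suppressWarnings(rmcorr(1:4, 1:4, c(1, 1, 2, 3))),
               "at least 2 subjects")
})

test_that("cluster bootstrap is reproducible and covers the true correlation", {
  make_data <- function(seed, S = 20, Tn = 10, rho = 0.5) {
    set.seed(seed)
    subject <- rep(seq_len(S), each = Tn)
    x <- stats::rnorm(S * Tn)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(S * Tn) +
      stats::rnorm(S)[subject]
    list(x = x, y = y, subject = subject)
  }
  d <- make_data(1)
  ci1 <- rmcorr_bootstrap_ci(d$x, d$y, d$subject, n_boot = 100, seed = 5)
  ci2 <- rmcorr_bootstrap_ci(d$x, d$y, d$subject, n_boot = 100, seed = 5)
  expect_identical(ci1, ci2)
  # coverage of the true within-subject correlation (0.5) across
  # independent replications of data + bootstrap
  hits <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    d <- make_data(100 + r)
    ci <- rmcorr_bootstrap_ci(d$x, d$y, d$subject, n_boot = 120,
                              seed = 200 + r)
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("random-structure selection stops where the data say so", {
  # no subject-level emotion slope: intercept-only should win mostly
  sel0 <- vapply(1:6, function(r) {
    d <- simulate_response_cohort(15, 6, re_emotion_sd = 0,
                                  seed = 400 + r)
    fit_condition_model(d, response = "zm_response")$selected
  }, character(1))
  expect_gte(sum(sel0 == "intercept"), 4)
  # a strong emotion slope should be adopted mostly
  sel1 <- vapply(1:6, function(r) {
    d <- simulate_response_cohort(15, 6, re_emotion_sd = 0.6,
                                  seed = 500 + r)
    fit_condition_model(d, response = "zm_response")$selected
  }, character(1))
  expect_gte(sum(sel1 != "intercept"), 4)
})

test_that("the condition model uses negative/video reference levels and
          finds the live amplification", {
  d <- simulate_response_cohort(25, 10, seed = 61)
  cm <- fit_condition_model(d, response = "zm_response")
  expect_setequal(cm$fixed_effects$term,
                  c("(Intercept)", "emotionpositive", "presentationlive",
                    "emotionpositive:presentationlive"))
  i <- cm$fixed_effects$term == "emotionpositive:presentationlive"
  expect_gt(cm$fixed_effects$estimate[i], 0)
  expect_lt(cm$fixed_effects$p[i], 0.05)
})

test_that("influence exclusion removes forced outliers and nothing when
          disabled", {
  d <- simulate_response_cohort(12, 4, seed = 71)
  d$zm_response[5] <- d$zm_response[5] + 20 * stats::sd(d$zm_response)
  cm <- fit_condition_model(d, response = "zm_response")
  ie <- influence_exclude(cm)
  expect_true("residual" %in% sub("\\+.*", "", ie$excluded_trials$reason) ||
                any(grepl("residual", ie$excluded_trials$reason)))
  # the contaminated trial itself is flagged
  expect_true(any(abs(ie$excluded_trials$std_resid) > 3))
  off <- exclusion_rule(resid_abs_threshold = Inf, iqr_multiplier = Inf)
  ie_off <- influence_exclude(cm, off)
  expect_identical(ie_off$n_excluded, 0L)
  # clean Gaussian cohorts lose only a modest share of trials to the
  # boxplot rule (Cook's distances are right-skewed by construction)
  d2 <- simulate_response_cohort(15, 8, seed = 72)
  ie2 <- influence_exclude(fit_condition_model(d2, response = "zm_response"),
                           exclusion_rule(subject_level_check = FALSE))
  expect_lt(ie2$n_excluded / nrow(d2), 0.15)
})

test_that("simple effects recover the generator's cell structure", {
  # null generator: contrasts centred on zero
  d0 <- simulate_response_cohort(20, 8, zm_gain = 0, seed = 81)
  se0 <- simple_effects(fit_condition_model(d0, response = "zm_response"))
  expect_true(all(abs(se0$contrasts$estimate) <
                    5 * se0$contrasts$SE))
  # live amplification in positive trials only: PL-PV large, NL-NV null
  cover <- 0
  total <- 0
  truth <- c(nv = 0, nl = 0, pv = log(2), pl = log(2.5))
  for (r in 1:8) {
    d <- simulate_response_cohort(20, 8, seed = 900 + r)
    se <- simple_effects(fit_condition_model(d, response = "zm_response"))
    cells <- se$cell_means
    for (i in seq_len(nrow(cells))) {
      key <- paste0(substr(cells$emotion[i], 1, 1),
                    substr(cells$presentation[i], 1, 1))
      total <- total + 1
      if (cells$lower.CL[i] <= truth[key] && truth[key] <= cells$upper.CL[i])
        cover <- cover + 1
    }
  }
  expect_gte(cover / total, 0.8)
})

test_that("a very large effect saturates simulated power at small n", {
  ps <- power_by_simulation(n_grid = 10, reps = 25,
                            trials_per_condition = 15, seed = 17,
                            zm_gain = 4, live_amplification = 2.5)
  expect_gte(ps$power$power[1], 0.99)
  expect_identical(ps$minimal_n, 10L)
  ps0 <- power_by_simulation(n_grid = 10, reps = 30,
                             trials_per_condition = 8, seed = 19,
                             zm_gain = 0)
  expect_lte(ps0$power$power[1], 0.2)
})
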