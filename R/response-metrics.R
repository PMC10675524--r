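#' Response windows of the dynamic-expression trial
#'
#' The neutral phase (0-1 s after stimulus onset) and the maximal phase
#' (2.5-3.0 s) of the 3 s dynamic facial expression. Windows are half-open
#' `[start, end)` in seconds.
#'
#' @param neutral_s,maximal_s `c(start, end)` pairs in seconds.
#' @return An object of class `response_windows`.
#' @export
response_windows <- function(neutral_s = c(0, 1), maximal_s = c(2.5, 3)) {
  check <- function(w, nm) {
    if (length(w) != 2 || w[1] >= w[2])
      stop(nm, " must be c(start, end) with start < end")
  }
  check(neutral_s, "neutral_s")
  check(maximal_s, "maximal_s")
  if (max(neutral_s[1], maximal_s[1]) < min(neutral_s[2], maximal_s[2]))
    stop("neutral and maximal windows must be disjoint")
  w <- list(neutral_s = neutral_s, maximal_s = maximal_s)
  class(w) <- "response_windows"
  w
}

#' Trial-wise response of a signal
#'
#' The mean of the signal over the maximal-phase window minus its mean
#' over the neutral-phase window. Works for any uniformly sampled series:
#' log EMG amplitude at the EMG rate, or an AU intensity series at the
#' video frame rate. Sample `i` (1-based) is assigned time
#' `(i - 1 - onset_index) / rate_hz` and windows are half-open.
#'
#' @param series Numeric vector.
#' @param rate_hz Sampling rate of `series` in Hz (the frame rate for AU
#'   series).
#' @param windows A [response_windows()].
#' @param onset_index Number of pre-onset samples in `series` (0 for AU
#'   series that start at stimulus onset).
#' @return The scalar response.
#' @export
trial_response <- function(series, rate_hz, windows = response_windows(),
                           onset_index = 0L) {
  t_rel <- (seq_along(series) - 1L - onset_index) / rate_hz
  pick <- function(w) {
    idx <- which(t_rel >= w[1] & t_rel < w[2])
    if (length(idx) == 0)
      stop("window [", w[1], ", ", w[2], ") lies outside the series")
    idx
  }
  i_max <- pick(windows$maximal_s)
  i_neu <- pick(windows$neutral_s)
  mean(series[i_max]) - mean(series[i_neu])
}

#' Sign-congruence accuracy of AU responses against EMG responses
#'
#' The proportion of trials whose AU response has the same sign as the
#' EMG response of the corresponding muscle, using the EMG sign as ground
#' truth. A response of exactly zero is grouped with the negative sign
#' (software that emits nothing has not detected a response). Excluded
#' trials are dropped from the denominator unless `include_zero_output`
#' is set, in which case trials excluded for all-zero AU output are kept
#' (their AU response counts as non-positive).
#'
#' @param pairs Data frame with columns `au_response`, `emg_response` and
#'   optionally `excluded` (logical) and `reason` (character).
#' @param include_zero_output Keep trials excluded for reason
#'   `"zero_output"` in the denominator.
#' @return Proportion in `[0, 1]`.
#' @export
sign_congruence_accuracy <- function(pairs, include_zero_output = FALSE) {
  keep <- if (is.null(pairs$excluded)) rep(TRUE, nrow(pairs)) else !pairs$excluded
  if (include_zero_output && !is.null(pairs$reason))
    keep <- keep | (pairs$reason == "zero_output")
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no trials left after exclusion")
  mean((pairs$au_response > 0) == (pairs$emg_response > 0))
}

#' Classify one trial's mimicry detection outcome
#'
#' Compares the automated detection of a mimicking response against the
#' EMG ground truth and returns the confusion-matrix label. In
#' `single_channel` mode the ground truth is a positive EMG response of
#' the congruent muscle (`zm_resp > 0`) and the prediction is a positive
#' AU response (`au12_resp > 0`). In `compound` mode a mimicking response
#' additionally requires relaxation of the antagonist: ground truth
#' `zm_resp > 0 & cs_resp <= 0`, prediction `au12_resp > 0 & au4_resp <=
#' 0`. Null (exactly zero) responses count as non-detection. Combinations
#' not covered by the compound taxonomy (e.g. both AUs positive) map to
#' "not detected".
#'
#' For the analogous analysis of frown mimicry on negative-condition
#' trials, pass the AU4 response as `au12_resp` and the CS response as
#' `zm_resp` (the roles, not the names, matter).
#'
#' @param au12_resp,zm_resp Numeric vectors of AU and EMG responses.
#' @param au4_resp,cs_resp Antagonist responses, required in compound
#'   mode.
#' @param mode `"single_channel"` (default) or `"compound"`.
#' @return Character vector of labels in `{"TP", "FP", "TN", "FN"}`.
#' @export
classify_mimicry_trial <- function(au12_resp, au4_resp = NULL,
                                   zm_resp, cs_resp = NULL,
                                   mode = c("single_channel", "compound")) {
  mode <- match.arg(mode)
  if (mode == "compound" && (is.null(au4_resp) || is.null(cs_resp)))
    stop("compound mode requires au4_resp and cs_resp")
  truth <- if (mode == "single_channel") zm_resp > 0
           else zm_resp > 0 & cs_resp <= 0
  pred <- if (mode == "single_channel") au12_resp > 0
          else au12_resp > 0 & au4_resp <= 0
  ifelse(truth & pred, "TP",
         ifelse(truth & !pred, "FN",
                ifelse(!truth & pred, "FP", "TN")))
}

#' Tally confusion counts
#'
#' @param labels Character vector of `"TP"/"FP"/"TN"/"FN"` labels.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(labels) {
  stopifnot(all(labels %in% c("TP", "FP", "TN", "FN")))
  counts <- list(tp = sum(labels == "TP"), fp = sum(labels == "FP"),
                 tn = sum(labels == "TN"), fn = sum(labels == "FN"))
  class(counts) <- "confusion_counts"
  counts
}

#' Detection metrics from confusion counts
#'
#' Sensitivity (recall), specificity, positive and negative predictive
#' value, and F1 score. A metric whose denominator is zero is reported as
#' `NA` (undefined), never as 0.
#'
#' @param counts A [confusion_counts()] object (or a list with fields
#'   `tp`, `fp`, `tn`, `fn`).
#' @return An object of class `detection_metrics`.
#' @export
detection_metrics <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
    specificity = safe_div(counts$tn, counts$tn + counts$fp),
    ppv = safe_div(counts$tp, counts$tp + counts$fp),
    npv = safe_div(counts$tn, counts$tn + counts$fn),
    f1 = safe_div(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  )
  class(m) <- "detection_metrics"
  m
}

#' Report whole-trial zero AU12 output
#'
#' Counts trials whose entire AU12 series is exactly zero, the pathology
#' observed in some automated FACS output, and the proportion among all
#' trials (rounded to 3 significant figures for display).
#'
#' @param trials A `trial_cohort`, a list of numeric AU12 vectors, or a
#'   long data frame with columns `subject`, `trial` and `au12`.
#' @return A list with `n_zero`, `n_total`, `proportion` and
#'   `proportion_display`.
#' @export
zero_output_report <- function(trials) {
  series <- if (inherits(trials, "trial_cohort")) {
    lapply(trials, `[[`, "au12")
  } else if (is.data.frame(trials)) {
    split(trials$au12, interaction(trials$subject, trials$trial, drop = TRUE))
  } else {
    trials
  }
  n_total <- length(series)
  n_zero <- sum(vapply(series, function(x) all(x == 0), logical(1)))
  p <- if (n_total > 0) n_zero / n_total else NA_real_
  list(n_zero = n_zero, n_total = n_total, proportion = p,
       proportion_display = signif(p, 3))
}

#' Extract trial-wise responses from a simulated cohort
#'
#' Preprocesses both EMG channels of every trial, computes the four
#' trial-wise responses (ZM, CS, AU12, AU4) over the neutral and maximal
#' windows, and records exclusions: all-zero AU12 output (`zero_output`),
#' low-quality frames under the chosen policy (`low_quality`), and the
#' automated artifact flag (`artifact`) when enabled.
#'
#' @param cohort A `trial_cohort` from [simulate_cohort()].
#' @param preproc A [preproc_params()].
#' @param windows A [response_windows()].
#' @param thresholds A [quality_thresholds()] used for the low-quality
#'   exclusion; `NULL` disables quality screening.
#' @return A data frame with one row per trial: identifiers, condition
#'   labels, `zm_response`, `cs_response`, `au12_response`,
#'   `au4_response`, `excluded`, `reason`.
#' @export
cohort_responses <- function(cohort, preproc = preproc_params(),
                             windows = response_windows(),
                             thresholds = quality_thresholds()) {
  rows <- lapply(cohort, function(tr) {
    zm <- preprocess_emg(tr$emg_zm, tr$onset_index, tr$emg_rate_hz,
                         preproc, channel = "ZM")
    cs <- preprocess_emg(tr$emg_cs, tr$onset_index, tr$emg_rate_hz,
                         preproc, channel = "CS")
    reason <- "none"
    if (tr$software_tag == "openface_like" && all(tr$au12 == 0)) {
      reason <- "zero_output"
    } else if (!is.null(thresholds)) {
      thr <- threshold_for(tr$software_tag, thresholds)
      bad <- tr$quality < thr
      if ((thresholds$exclusion_policy == "any_frame" && any(bad)) ||
          (thresholds$exclusion_policy == "fraction" &&
           mean(bad) > thresholds$max_bad_fraction)) {
        reason <- "low_quality"
      }
    }
    if (reason == "none" && (zm$artifact_flag || cs$artifact_flag))
      reason <- "artifact"
    data.frame(
      subject = tr$subject, trial = tr$trial,
      emotion = tr$emotion, presentation = tr$presentation,
      software_tag = tr$software_tag,
      zm_response = trial_response(zm$amplitude, tr$emg_rate_hz, windows,
                                   tr$onset_index),
      cs_response = trial_response(cs$amplitude, tr$emg_rate_hz, windows,
                                   tr$onset_index),
      au12_response = trial_response(tr$au12, tr$au_fps, windows),
      au4_response = trial_response(tr$au4, tr$au_fps, windows),
      excluded = reason != "none",
      reason = reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation metrics table for a response set
#'
#' Computes, for one channel pairing (AU12 vs ZM on positive trials by
#' default, or AU4 vs CS on negative trials), the response accuracy
#' (sign congruence over all non-excluded trials) and the mimicry
#' detection metrics on the condition-congruent trials, optionally both
#' including and excluding zero-output trials.
#'
#' @param responses Output of [cohort_responses()].
#' @param channel `"AU12"` (smile mimicry, positive trials) or `"AU4"`
#'   (frown mimicry, negative trials).
#' @param mode Classification mode, see [classify_mimicry_trial()].
#' @param include_zero_output Treat zero-output trials as valid (their AU
#'   response is 0, i.e. non-detection) instead of dropping them.
#' @return A one-row data frame of metrics.
#' @export
validation_metrics <- function(responses, channel = c("AU12", "AU4"),
                               mode = c("single_channel", "compound"),
                               include_zero_output = FALSE) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  if (channel == "AU12") {
    pairs <- data.frame(au_response = responses$au12_response,
                        emg_response = responses$zm_response,
                        au2 = responses$au4_response,
                        emg2 = responses$cs_response,
                        emotion = responses$emotion,
                        excluded = responses$excluded,
                        reason = responses$reason)
    congruent_emotion <- "positive"
  } else {
    pairs <- data.frame(au_response = responses$au4_response,
                        emg_response = responses$cs_response,
                        au2 = responses$au12_response,
                        emg2 = responses$zm_response,
                        emotion = responses$emotion,
                        excluded = responses$excluded,
                        reason = responses$reason)
    congruent_emotion <- "negative"
  }
  acc <- sign_congruence_accuracy(pairs, include_zero_output)
  mim <- pairs[pairs$emotion == congruent_emotion, , drop = FALSE]
  keep <- !mim$excluded
  if (include_zero_output) keep <- keep | (mim$reason == "zero_output")
  mim <- mim[keep, , drop = FALSE]
  labels <- classify_mimicry_trial(mim$au_response, mim$au2,
                                   mim$emg_response, mim$emg2, mode)
  met <- detection_metrics(confusion_counts(labels))
  data.frame(channel = channel, mode = mode,
             include_zero_output = include_zero_output,
             n_response = sum(!pairs$excluded |
                                (include_zero_output &
                                   pairs$reason == "zero_output")),
             n_mimicry = nrow(mim),
             response_accuracy = acc,
             sensitivity = met$sensitivity, specificity = met$specificity,
             ppv = met$ppv, npv = met$npv, f1 = met$f1)
}
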