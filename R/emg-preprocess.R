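#' EMG preprocessing parameters
#'
#' Parameters of the surface-EMG preprocessing chain: mains notch filters
#' at the base frequency and its harmonics, a 20-500 Hz band-pass,
#' per-trial linear detrending, baseline correction over a window spanning
#' 3 s before to 1 s after stimulus onset (the end of the model's neutral
#' expression), rectification and `log(1 + x)` transform.
#'
#' The nominal 500 Hz low-pass equals the Nyquist frequency at the default
#' 1000 Hz sampling rate; the effective low-pass cutoff is therefore capped
#' at 90% of Nyquist (450 Hz at 1000 Hz), which leaves the 20-450 Hz
#' surface-EMG band untouched. Notch filters are placed at multiples of
#' `notch_base_hz` up to the nominal low-pass cutoff (and below Nyquist).
#'
#' @param notch_base_hz Mains frequency in Hz.
#' @param notch_q Quality factor of the second-order IIR notches.
#' @param highpass_hz,lowpass_hz Band-pass corner frequencies in Hz.
#' @param baseline_window_s Baseline window relative to stimulus onset,
#'   `c(start, end)` in seconds (half-open `[start, end)`).
#' @param artifact_sd_threshold Threshold (in within-trial SDs) for the
#'   automated artifact flag, or `NULL` to disable screening (the
#'   default; screening of real recordings is typically manual).
#' @return An object of class `preproc_params`.
#' @export
preproc_params <- function(notch_base_hz = 60,
                           notch_q = 30,
                           highpass_hz = 20,
                           lowpass_hz = 500,
                           baseline_window_s = c(-3, 1),
                           artifact_sd_threshold = NULL) {
  if (highpass_hz >= lowpass_hz)
    stop("highpass_hz must be below lowpass_hz")
  if (length(baseline_window_s) != 2 ||
      baseline_window_s[1] >= baseline_window_s[2])
    stop("baseline_window_s must be c(start, end) with start < end")
  p <- list(notch_base_hz = notch_base_hz, notch_q = notch_q,
            highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
            baseline_window_s = baseline_window_s,
            artifact_sd_threshold = artifact_sd_threshold)
  class(p) <- "preproc_params"
  p
}

# Zero-phase filtering with odd reflection padding at both ends, which
# keeps filtfilt edge transients out of the analysed segment.
padded_filtfilt <- function(b, a, x, pad = 1000L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(signal::filtfilt(b, a, x))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(b, a, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

# RBJ-cookbook second-order IIR notch coefficients.
notch_coefficients <- function(f0, rate_hz, q) {
  w0 <- 2 * pi * f0 / rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch and band-pass filter a raw EMG trace
#'
#' Applies, in order: second-order IIR notch filters (quality factor
#' `notch_q`) at the mains frequency and all its multiples up to the
#' low-pass cutoff, a 4th-order Butterworth high-pass at `highpass_hz` and
#' a 4th-order Butterworth low-pass at the effective low-pass cutoff. All
#' filters run forward-backward (zero phase) over a reflection-padded
#' copy of the trace, so the length is preserved and the passband has
#' approximately unity gain.
#'
#' @param raw Numeric vector, one trial's raw EMG samples.
#' @param rate_hz Sampling rate in Hz.
#' @param params A [preproc_params()].
#' @return Filtered trace, same length as `raw`.
#' @export
apply_filters <- function(raw, rate_hz, params = preproc_params()) {
  nyq <- rate_hz / 2
  if (params$highpass_hz >= nyq)
    stop("sampling rate ", rate_hz, " Hz is too low for a ",
         params$highpass_hz, " Hz high-pass filter")
  eff_lowpass <- min(params$lowpass_hz, 0.9 * nyq)
  if (eff_lowpass <= params$highpass_hz)
    stop("effective band-pass is empty at rate ", rate_hz, " Hz")
  x <- as.numeric(raw)
  harmonics <- seq(params$notch_base_hz,
                   min(params$lowpass_hz, nyq - 1e-9),
                   by = params$notch_base_hz)
  harmonics <- harmonics[harmonics < nyq]
  for (f0 in harmonics) {
    nc <- notch_coefficients(f0, rate_hz, params$notch_q)
    x <- padded_filtfilt(nc$b, nc$a, x)
  }
  hp <- signal::butter(4, params$highpass_hz / nyq, "high")
  lp <- signal::butter(4, eff_lowpass / nyq, "low")
  x <- padded_filtfilt(hp$b, hp$a, x)
  x <- padded_filtfilt(lp$b, lp$a, x)
  x
}

#' Detrend and baseline-correct a filtered trial
#'
#' Removes the per-trial linear trend (least squares over the whole
#' segment) and then shifts all samples by the mean over the baseline
#' window (3 s before to 1 s after stimulus onset by default), so the
#' baseline-window mean of the result is zero.
#'
#' @param filtered Numeric vector (output of [apply_filters()]).
#' @param onset_index Number of pre-stimulus samples; sample `i` (1-based)
#'   has time `(i - 1 - onset_index) / rate_hz` relative to onset.
#' @param rate_hz Sampling rate in Hz.
#' @param params A [preproc_params()].
#' @return Detrended, baseline-corrected trace.
#' @export
detrend_baseline <- function(filtered, onset_index, rate_hz,
                             params = preproc_params()) {
  n <- length(filtered)
  t_rel <- (seq_len(n) - 1L - onset_index) / rate_hz
  w <- params$baseline_window_s
  need_pre <- -w[1]
  if (onset_index / rate_hz < need_pre - 1e-9)
    stop("baseline window needs ", need_pre, " s of pre-stimulus padding, ",
         "but only ", onset_index / rate_hz, " s are available")
  # linear detrend over the full per-trial segment
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), filtered)
  x <- filtered - cbind(1, tt) %*% fit$coefficients
  x <- as.numeric(x)
  in_base <- t_rel >= w[1] & t_rel < w[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  x - mean(x[in_base])
}

#' Rectify and log-transform
#'
#' Converts a zero-centred EMG trace to log oscillation amplitudes:
#' `log(1 + |x|)`, the standard right-skew correction for rectified
#' surface EMG. Output is non-negative and monotone in `|x|`.
#'
#' @param x Numeric vector.
#' @return `log1p(abs(x))`.
#' @export
rectify_log <- function(x) {
  log1p(abs(x))
}

#' Automated movement-artifact flag
#'
#' Surrogate for manual artifact screening: flags a trial whose absolute
#' deviation from the trial mean exceeds `artifact_sd_threshold` trial
#' SDs anywhere. Disabled (always `FALSE`) when the threshold is `NULL`.
#'
#' @param x Numeric vector (filtered trial).
#' @param params A [preproc_params()].
#' @return Logical flag.
#' @export
screen_artifacts <- function(x, params = preproc_params()) {
  thr <- params$artifact_sd_threshold
  if (is.null(thr)) return(FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(FALSE)
  any(abs(x - mean(x)) > thr * s)
}

#' Preprocess one EMG channel of a trial
#'
#' Runs the full chain in its fixed order: filters, detrend plus baseline
#' correction, rectification, log transform. The artifact flag is computed
#' on the filtered (pre-rectification) trace.
#'
#' @inheritParams detrend_baseline
#' @param raw Numeric vector of raw samples (including the pre-stimulus
#'   pad).
#' @param channel `"ZM"` or `"CS"` (stored with the output).
#' @return An object of class `preproc_emg_trace` with fields `amplitude`
#'   (log-transformed rectified amplitude, all values >= 0),
#'   `onset_index`, `rate_hz`, `channel` and `artifact_flag`.
#' @export
preprocess_emg <- function(raw, onset_index, rate_hz,
                           params = preproc_params(), channel = "ZM") {
  filtered <- apply_filters(raw, rate_hz, params)
  corrected <- detrend_baseline(filtered, onset_index, rate_hz, params)
  out <- list(
    amplitude = rectify_log(corrected),
    onset_index = onset_index,
    rate_hz = rate_hz,
    channel = channel,
    artifact_flag = screen_artifacts(corrected, params)
  )
  class(out) <- "preproc_emg_trace"
  out
}
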