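#' Quality-score thresholds for automated FACS output
#'
#' Frames whose software quality/confidence score falls below the
#' software-specific threshold are treated as missing; trials are then
#' excluded either when any frame is missing (`any_frame`, the default)
#' or when the missing fraction exceeds `max_bad_fraction` (`fraction`).
#'
#' @param facereader_min,pyfeat_min,openface_min,generic_min Minimum
#'   acceptable quality score per software family.
#' @param exclusion_policy `"any_frame"` or `"fraction"`.
#' @param max_bad_fraction Tolerated fraction of sub-threshold frames
#'   under the `fraction` policy.
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(facereader_min = 0.6,
                               pyfeat_min = 0.75,
                               openface_min = 0.75,
                               generic_min = 0.75,
                               exclusion_policy = c("any_frame", "fraction"),
                               max_bad_fraction = 0.1) {
  exclusion_policy <- match.arg(exclusion_policy)
  vals <- c(facereader_min, pyfeat_min, openface_min, generic_min)
  stopifnot(all(vals >= 0 & vals <= 1))
  q <- list(facereader_min = facereader_min, pyfeat_min = pyfeat_min,
            openface_min = openface_min, generic_min = generic_min,
            exclusion_policy = exclusion_policy,
            max_bad_fraction = max_bad_fraction)
  class(q) <- "quality_thresholds"
  q
}

threshold_for <- function(software_tag, thresholds) {
  switch(software_tag,
         facereader_like = thresholds$facereader_min,
         pyfeat_like = thresholds$pyfeat_min,
         openface_like = thresholds$openface_min,
         generic = thresholds$generic_min,
         stop("unknown software_tag: ", software_tag))
}

#' Resample a preprocessed EMG trace to the video frame grid
#'
#' Aggregates post-onset EMG samples into video frames by bin means:
#' frame `i` (0-based) is the mean of the samples whose post-onset time
#' falls in `[i/fps, (i+1)/fps)`. The last frame may be served by a
#' partially covered bin when the frame grid slightly overhangs the trial
#' (90 frames at 29.97 fps span 3.003 s).
#'
#' @param amplitude Numeric vector (e.g. log EMG amplitude including the
#'   pre-stimulus pad).
#' @param rate_hz Sampling rate of `amplitude`.
#' @param onset_index Number of pre-onset samples.
#' @param fps Target frame rate.
#' @param n_frames Number of frames to produce.
#' @param method `"bin_mean"` (default) or `"interp"` (linear
#'   interpolation at frame-bin centres).
#' @return Numeric vector of length `n_frames`.
#' @export
resample_emg_to_frames <- function(amplitude, rate_hz, onset_index,
                                   fps = 29.97, n_frames = 90,
                                   method = c("bin_mean", "interp")) {
  method <- match.arg(method)
  post <- amplitude[(onset_index + 1L):length(amplitude)]
  n_post <- length(post)
  t_post <- (seq_len(n_post) - 1L) / rate_hz
  # the first n_frames - 1 bins must be fully covered
  if (n_post < floor((n_frames - 1) / fps * rate_hz) + 1)
    stop("trace too short: ", n_post, " post-onset samples cannot fill ",
         n_frames, " frames at ", fps, " fps")
  if (method == "interp") {
    centres <- (seq_len(n_frames) - 0.5) / fps
    return(stats::approx(t_post, post, xout = pmin(centres, max(t_post)),
                         rule = 2)$y)
  }
  frame <- floor(t_post * fps)
  keep <- frame < n_frames
  out <- vapply(split(post[keep], frame[keep]), mean, numeric(1))
  idx <- as.integer(names(out))
  res <- rep(NA_real_, n_frames)
  res[idx + 1L] <- out
  if (anyNA(res)) stop("empty frame bins while resampling")
  unname(res)
}

#' Mask low-quality frames and flag excluded trials
#'
#' Sets AU frames whose quality score is below the software-specific
#' threshold to `NA` and decides whether the trial is excluded: always for
#' an all-zero AU12 series from `openface_like` software (reason
#' `zero_output`), otherwise under the configured policy for
#' sub-threshold frames (reason `low_quality`).
#'
#' @param trial A `trial_recording`.
#' @param thresholds A [quality_thresholds()].
#' @return The trial with masked `au12`/`au4` plus fields `excluded` and
#'   `reason`.
#' @export
apply_quality_mask <- function(trial, thresholds = quality_thresholds()) {
  thr <- threshold_for(trial$software_tag, thresholds)
  if (trial$software_tag == "openface_like" && all(trial$au12 == 0)) {
    trial$excluded <- TRUE
    trial$reason <- "zero_output"
    return(trial)
  }
  bad <- trial$quality < thr
  trial$au12[bad] <- NA_real_
  trial$au4[bad] <- NA_real_
  excluded <- if (thresholds$exclusion_policy == "any_frame") any(bad)
              else mean(bad) > thresholds$max_bad_fraction
  trial$excluded <- excluded
  trial$reason <- if (excluded) "low_quality" else "none"
  trial
}

#' Anchor a time series at zero
#'
#' Shifts a per-trial series so that its first value is 0 (used before
#' group averaging, so trials with different resting offsets are
#' comparable). If the first value is missing, the first non-missing
#' value is used as the anchor and a message is emitted.
#'
#' @param x Numeric vector.
#' @return `x` minus its (first non-missing) first value.
#' @export
zero_anchor <- function(x) {
  if (length(x) == 0) stop("cannot anchor an empty series")
  if (is.na(x[1])) {
    i <- which(!is.na(x))[1]
    if (is.na(i)) stop("cannot anchor an all-missing series")
    message("first value missing; anchoring at first non-missing value (index ",
            i, ")")
    return(x - x[i])
  }
  x - x[1]
}

#' Group-average time series with standard errors
#'
#' Per-frame mean and standard error over a set of equal-length trials,
#' after anchoring each trial at zero. Missing frames are omitted
#' pairwise (per frame).
#'
#' @param trial_series List of numeric vectors of equal length (one per
#'   trial).
#' @param anchor Anchor each trial at zero first.
#' @return A data frame with columns `frame` (0-based), `mean`, `se`,
#'   `n`.
#' @export
group_average_timeseries <- function(trial_series, anchor = TRUE) {
  if (length(trial_series) < 2)
    stop("group averaging needs at least 2 trials")
  if (length(unique(lengths(trial_series))) != 1)
    stop("all trials must have the same number of frames")
  if (anchor) trial_series <- lapply(trial_series, zero_anchor)
  m <- do.call(rbind, trial_series)
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 0, sdv / sqrt(n), NA_real_)
  data.frame(frame = seq_len(ncol(m)) - 1L, mean = mu, se = se, n = n)
}

#' Cross-correlation between two frame series
#'
#' The standardized cross-correlation used for latency estimation: both
#' series are centred by their full-series means and scaled by their
#' full-series standard deviations (population convention, denominator
#' N), and `r(k)` is the sum of lagged products over the overlapping
#' segment divided by the series length. With `x` the ZM series and `y`
#' the AU series, a positive peak lag means the AU series trails the
#' EMG. An alternative per-lag Pearson normalisation (each lag's
#' overlapping segments re-centred and re-scaled) is available via
#' `normalization = "pearson"`.
#'
#' @param x,y Numeric vectors of equal length (at least `2 * max_lag`).
#' @param max_lag Maximum lag in frames (both directions).
#' @param fps Frame rate, used to convert the peak lag to milliseconds.
#' @param peak_search `"nonnegative"` (default; the working hypothesis is
#'   that the AU output lags the muscle) or `"full"`.
#' @param normalization `"standardized"` (default) or `"pearson"`.
#' @return An object of class `xcorr_result`: `lags` (-max_lag..max_lag),
#'   `r`, `peak_lag`, `peak_r`, `latency_ms`, `degenerate` (`TRUE` when a
#'   series has zero variance, in which case `r` is `NA`).
#' @export
cross_correlation <- function(x, y, max_lag = 45, fps = 29.97,
                              peak_search = c("nonnegative", "full"),
                              normalization = c("standardized", "pearson")) {
  peak_search <- match.arg(peak_search)
  normalization <- match.arg(normalization)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2 * max_lag)
    stop("series of length ", n, " is too short for max_lag ", max_lag)
  if (anyNA(x) || anyNA(y))
    stop("cross_correlation does not accept missing values; ",
         "exclude masked trials first")
  lags <- seq.int(-max_lag, max_lag)
  sx <- stats::sd(x) * sqrt((n - 1) / n)
  sy <- stats::sd(y) * sqrt((n - 1) / n)
  if (sx == 0 || sy == 0) {
    warning("zero-variance series; cross-correlation undefined")
    out <- list(lags = lags, r = rep(NA_real_, length(lags)),
                peak_lag = NA_integer_, peak_r = NA_real_,
                latency_ms = NA_real_, degenerate = TRUE)
    class(out) <- "xcorr_result"
    return(out)
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- vapply(lags, function(k) {
    if (normalization == "standardized") {
      if (k >= 0) sum(xc[1:(n - k)] * yc[(1 + k):n]) / (n * sx * sy)
      else sum(xc[(1 - k):n] * yc[1:(n + k)]) / (n * sx * sy)
    } else {
      if (k >= 0) stats::cor(x[1:(n - k)], y[(1 + k):n])
      else stats::cor(x[(1 - k):n], y[1:(n + k)])
    }
  }, numeric(1))
  search <- if (peak_search == "nonnegative") which(lags >= 0) else seq_along(lags)
  pk <- search[which.max(r[search])]
  out <- list(lags = lags, r = r,
              peak_lag = lags[pk], peak_r = r[pk],
              latency_ms = lag_to_ms(lags[pk], fps),
              degenerate = FALSE)
  class(out) <- "xcorr_result"
  out
}

#' Aggregate trial-wise cross-correlations to subject and group curves
#'
#' Two-stage averaging of cross-correlograms: trial curves are averaged
#' within subject, subject curves are averaged per condition. The peak of
#' each group curve is reported over the non-negative lags (by default),
#' including a plateau range when adjacent lags tie at the reported
#' precision (3 decimal places).
#'
#' @param trial_results List of `xcorr_result` objects.
#' @param subject,condition Vectors (one element per trial result) giving
#'   the subject id and the condition of each trial.
#' @param peak_search `"nonnegative"` or `"full"`.
#' @param digits Rounding used to detect peak plateaus.
#' @param fps Frame rate for latency conversion.
#' @return A list with `curves` (data frame condition, lag, r) and
#'   `peaks` (one row per condition: peak lag range, peak r, latency
#'   range in ms).
#' @export
aggregate_xcorr <- function(trial_results, subject, condition,
                            peak_search = c("nonnegative", "full"),
                            digits = 3, fps = 29.97) {
  peak_search <- match.arg(peak_search)
  ok <- !vapply(trial_results, `[[`, logical(1), "degenerate")
  trial_results <- trial_results[ok]
  subject <- subject[ok]
  condition <- condition[ok]
  if (length(trial_results) == 0) stop("no valid cross-correlation results")
  lags <- trial_results[[1]]$lags
  rmat <- do.call(rbind, lapply(trial_results, `[[`, "r"))
  curves <- list(); peaks <- list()
  for (cond in unique(condition)) {
    in_cond <- condition == cond
    subj_means <- do.call(rbind, lapply(unique(subject[in_cond]), function(s) {
      colMeans(rmat[in_cond & subject == s, , drop = FALSE])
    }))
    g <- colMeans(subj_means)
    curves[[cond]] <- data.frame(condition = cond, lag = lags, r = g)
    search <- if (peak_search == "nonnegative") which(lags >= 0) else seq_along(lags)
    rr <- round(g[search], digits)
    at_max <- search[rr == max(rr)]
    peaks[[cond]] <- data.frame(
      condition = cond,
      peak_lag_min = min(lags[at_max]), peak_lag_max = max(lags[at_max]),
      peak_r = max(g[search]),
      latency_ms_min = lag_to_ms(min(lags[at_max]), fps),
      latency_ms_max = lag_to_ms(max(lags[at_max]), fps)
    )
  }
  list(curves = do.call(rbind, curves), peaks = do.call(rbind, peaks))
}

#' Convert a lag in frames to milliseconds
#'
#' `round(lag * 1000 / fps)` to the nearest integer millisecond; at
#' 29.97 fps, lags 1, 5, 6 and 9 map to 33, 167, 200 and 300 ms.
#'
#' @param lag Lag in frames (may be a vector).
#' @param fps Frame rate.
#' @return Integer milliseconds.
#' @export
lag_to_ms <- function(lag, fps = 29.97) {
  stopifnot(fps > 0)
  as.integer(round(lag * 1000 / fps))
}
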