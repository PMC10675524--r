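#' Session design for a 2 x 2 passive-viewing mimicry experiment
#'
#' Describes the experimental layout that the rest of the package assumes:
#' a within-subject design crossing emotion (positive/negative) with
#' presentation (live/video), a fixed number of passive-viewing trials per
#' condition, EMG sampled continuously with a pre-stimulus pad, and facial
#' video analysed at the camera frame rate.
#'
#' The number of action-unit frames per trial is derived from the trial
#' duration and frame rate by nearest-integer rounding, so the default
#' 3 s trial at 29.97 fps yields 90 frames.
#'
#' @param n_subjects Number of participants.
#' @param trials_per_condition Passive-viewing trials in each of the four
#'   conditions.
#' @param trial_duration_s Trial length in seconds (stimulus onset is t = 0).
#' @param prestimulus_pad_s Seconds of EMG recorded before stimulus onset.
#'   Must cover the baseline window (3 s).
#' @param emg_rate_hz EMG sampling rate in Hz.
#' @param au_fps Frame rate of the facial video, frames per second.
#' @return An object of class `session_design`.
#' @examples
#' d <- session_design()
#' d$n_frames # 90
#' @export
session_design <- function(n_subjects = 50,
                           trials_per_condition = 15,
                           trial_duration_s = 3,
                           prestimulus_pad_s = 3,
                           emg_rate_hz = 1000,
                           au_fps = 29.97) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            trial_duration_s > 0, emg_rate_hz > 0, au_fps > 0)
  if (prestimulus_pad_s < 3)
    stop("prestimulus_pad_s must be at least 3 s to cover the baseline window")
  design <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    conditions = expand.grid(emotion = c("negative", "positive"),
                             presentation = c("video", "live"),
                             stringsAsFactors = FALSE),
    trial_duration_s = trial_duration_s,
    prestimulus_pad_s = prestimulus_pad_s,
    emg_rate_hz = emg_rate_hz,
    au_fps = au_fps,
    n_frames = as.integer(floor(trial_duration_s * au_fps + 0.5))
  )
  class(design) <- "session_design"
  design
}

#' Ground-truth parameters of the synthetic session generator
#'
#' Controls the signal structure injected into synthetic trials: the
#' strength of the zygomaticus (ZM) amplitude modulation in positive
#' trials, its amplification under live presentation, the corrugator (CS)
#' modulation in negative trials, the scaling, latency, drift and noise of
#' the action-unit (AU) intensity series, and the rates of the software
#' pathologies that the generator emulates (whole-trial zero AU12 output
#' and low-quality frames).
#'
#' Amplitude units of raw surface EMG are hardware-dependent; the defaults
#' express the modulated envelope in multiples of the resting-noise SD
#' (`emg_baseline_sd`), so `zm_gain_pos_video = 1` means the oscillation SD
#' doubles at the expression maximum of a positive-video trial.
#'
#' Subject-level heterogeneity enters as log-normal multipliers on the
#' condition-congruent gain: a random intercept (`re_intercept_sd`) shared
#' by all of a subject's trials and a random emotion slope
#' (`re_emotion_sd`) applied in positive trials only, so mixed-model
#' recovery of the design is testable.
#'
#' @param zm_gain_pos_video Relative ZM envelope gain at expression maximum
#'   for positive-video trials.
#' @param live_amplification Multiplier (>= 1) on the positive-trial gain
#'   under live presentation.
#' @param cs_gain_neg Relative CS envelope gain for negative trials.
#' @param au_scale AU intensity at expression maximum per unit of effective
#'   gain.
#' @param au_latency_frames Latency of the AU series relative to the muscle
#'   drive, in frames (>= 0).
#' @param au_noise_sd SD of the frame-wise AU noise (before smoothing).
#' @param au_drift_per_frame Linear drift added to the AU series per frame
#'   (emulates the positive drift seen in some software output).
#' @param emg_baseline_sd Resting EMG oscillation SD in recording units.
#' @param p_zero_output Probability that an `openface_like` trial emits an
#'   all-zero AU12 series.
#' @param p_lowquality_frame Per-frame probability of a quality-score dip
#'   below the software's exclusion threshold.
#' @param ramp_start_s,ramp_end_s Start and end of the expression ramp, in
#'   seconds after stimulus onset.
#' @param re_intercept_sd,re_emotion_sd SDs of the subject-level random
#'   intercept and emotion slope on the log-gain scale.
#' @param au_smoothing Smoothing applied to the AU noise: `"ma3"` (3-frame
#'   centred moving average) or `"exp"` (heavier causal exponential
#'   smoothing, as seen in temporally smoothed commercial output).
#' @param seed Integer seed making cohort generation reproducible.
#' @return An object of class `ground_truth_params`.
#' @export
ground_truth_params <- function(zm_gain_pos_video = 1,
                                live_amplification = 1.5,
                                cs_gain_neg = 1,
                                au_scale = 1,
                                au_latency_frames = 3L,
                                au_noise_sd = 0.05,
                                au_drift_per_frame = 0,
                                emg_baseline_sd = 1,
                                p_zero_output = 0,
                                p_lowquality_frame = 0.01,
                                ramp_start_s = 1.0,
                                ramp_end_s = 2.5,
                                re_intercept_sd = 0.1,
                                re_emotion_sd = 0.35,
                                au_smoothing = c("ma3", "exp"),
                                seed = 1L) {
  au_smoothing <- match.arg(au_smoothing)
  stopifnot(live_amplification >= 1, au_latency_frames >= 0,
            p_zero_output >= 0, p_zero_output <= 1,
            p_lowquality_frame >= 0, p_lowquality_frame <= 1,
            emg_baseline_sd >= 0, au_noise_sd >= 0)
  if (!(ramp_start_s < ramp_end_s))
    stop("ramp_start_s must be smaller than ramp_end_s")
  params <- list(
    zm_gain_pos_video = zm_gain_pos_video,
    live_amplification = live_amplification,
    cs_gain_neg = cs_gain_neg,
    au_scale = au_scale,
    au_latency_frames = as.integer(au_latency_frames),
    au_noise_sd = au_noise_sd,
    au_drift_per_frame = au_drift_per_frame,
    emg_baseline_sd = emg_baseline_sd,
    p_zero_output = p_zero_output,
    p_lowquality_frame = p_lowquality_frame,
    ramp_start_s = ramp_start_s,
    ramp_end_s = ramp_end_s,
    re_intercept_sd = re_intercept_sd,
    re_emotion_sd = re_emotion_sd,
    au_smoothing = au_smoothing,
    seed = as.integer(seed)
  )
  class(params) <- "ground_truth_params"
  params
}

#' Software-specific generator presets
#'
#' Returns `ground_truth_params` adjusted to emulate the output
#' characteristics of a given class of automated FACS software:
#' `"openface_like"` emits whole-trial zero AU12 series at a 45.4% rate and
#' a positive drift; `"facereader_like"` applies heavier temporal smoothing
#' to the AU series; `"pyfeat_like"` and `"generic"` use the defaults.
#'
#' @param software_tag One of `"generic"`, `"facereader_like"`,
#'   `"pyfeat_like"`, `"openface_like"`.
#' @param ... Overrides passed on to [ground_truth_params()].
#' @return A `ground_truth_params` object.
#' @export
software_preset <- function(software_tag = c("generic", "facereader_like",
                                             "pyfeat_like", "openface_like"),
                            ...) {
  software_tag <- match.arg(software_tag)
  overrides <- list(...)
  base <- switch(software_tag,
    openface_like = list(p_zero_output = 0.454, au_drift_per_frame = 0.002),
    facereader_like = list(au_smoothing = "exp"),
    list()
  )
  base[names(overrides)] <- overrides
  do.call(ground_truth_params, base)
}

#' Expression drive as a function of trial time
#'
#' The normalised intensity of the model's dynamic facial expression:
#' neutral (0) before the ramp, a smooth monotone raised-cosine increase
#' between `ramp_start_s` and `ramp_end_s`, and the sustained maximal
#' expression (1) thereafter.
#'
#' @param t Time in seconds after stimulus onset; may be a vector.
#' @param params A [ground_truth_params()] object.
#' @return Drive values in `[0, 1]`, same length as `t`.
#' @examples
#' p <- ground_truth_params()
#' drive(c(0.5, 1.75, 2.9), p) # 0, 0.5, 1
#' @export
drive <- function(t, params = ground_truth_params()) {
  r0 <- params$ramp_start_s
  r1 <- params$ramp_end_s
  u <- (t - r0) / (r1 - r0)
  u <- pmin(pmax(u, 0), 1)
  0.5 * (1 - cos(pi * u))
}

# Band-limited Gaussian carrier for the EMG channels: white noise
# band-passed to the surface-EMG band so that downstream preprocessing
# filters are near-transparent to the signal of interest.
emg_carrier <- function(n, rate_hz, low_hz = 20, high_hz = 450) {
  x <- stats::rnorm(n)
  nyq <- rate_hz / 2
  high_hz <- min(high_hz, 0.9 * nyq)
  hp <- signal::butter(4, low_hz / nyq, "high")
  lp <- signal::butter(4, high_hz / nyq, "low")
  x <- padded_filtfilt(hp$b, hp$a, x)
  x <- padded_filtfilt(lp$b, lp$a, x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

smooth_au_noise <- function(noise, method) {
  if (length(noise) < 3L) return(noise)
  if (method == "ma3") {
    sm <- stats::filter(noise, rep(1 / 3, 3), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm)] <- noise[is.na(sm)]
    sm
  } else {
    # causal exponential smoothing; heavier memory emulates software-side
    # temporal smoothing and adds a little latency of its own
    alpha <- 0.3
    out <- numeric(length(noise))
    out[1] <- noise[1]
    for (i in 2:length(noise)) out[i] <- alpha * noise[i] + (1 - alpha) * out[i - 1]
    out
  }
}

#' Simulate one passive-viewing trial
#'
#' Generates the raw signals of a single trial: two EMG channels (ZM, CS)
#' as zero-mean band-limited noise whose instantaneous SD follows
#' `emg_baseline_sd * (1 + g * drive(t))`, where the gain `g` is the
#' condition-congruent envelope gain (ZM in positive trials, amplified
#' under live presentation; CS in negative trials; zero otherwise), and the
#' frame-wise AU intensity series (AU12, AU4) as a scaled, latency-shifted
#' copy of the drive plus linear drift and smoothed Gaussian noise,
#' together with per-frame quality scores.
#'
#' For `software_tag = "openface_like"`, the whole AU12 series is replaced
#' by zeros with probability `p_zero_output`, emulating the documented
#' software pathology.
#'
#' @param design A [session_design()].
#' @param params A [ground_truth_params()].
#' @param emotion `"positive"` or `"negative"`.
#' @param presentation `"live"` or `"video"`.
#' @param software_tag Which software's output characteristics to emulate.
#' @param subject_effects Named numeric vector with elements `intercept`
#'   and `emotion`: subject-level log-gain multipliers (see
#'   [ground_truth_params()]).
#' @param subject,trial Identifiers stored with the trial.
#' @param seed Optional integer; when given, the trial is generated from
#'   its own seeded RNG state so repeated calls are identical.
#' @return An object of class `trial_recording` with fields `emg_zm`,
#'   `emg_cs`, `au12`, `au4`, `quality`, `onset_index` (number of
#'   pre-stimulus samples), condition labels and `software_tag`.
#' @export
simulate_trial <- function(design, params, emotion, presentation,
                           software_tag = "generic",
                           subject_effects = c(intercept = 0, emotion = 0),
                           subject = "s1", trial = 1L, seed = NULL) {
  if (!emotion %in% c("positive", "negative"))
    stop("invalid emotion label: ", emotion)
  if (!presentation %in% c("live", "video"))
    stop("invalid presentation label: ", presentation)
  if (!software_tag %in% c("generic", "facereader_like", "pyfeat_like",
                           "openface_like"))
    stop("unknown software_tag: ", software_tag)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  rate <- design$emg_rate_hz
  n_emg <- as.integer(round((design$prestimulus_pad_s + design$trial_duration_s) * rate))
  onset_index <- as.integer(round(design$prestimulus_pad_s * rate))
  # time of EMG sample i (1-based): (i - 1 - onset_index) / rate
  t_emg <- (seq_len(n_emg) - 1L - onset_index) / rate

  u0 <- unname(subject_effects["intercept"])
  u1 <- unname(subject_effects["emotion"])
  is_pos <- emotion == "positive"
  subj_mult <- exp(u0 + if (is_pos) u1 else 0)
  g_zm <- if (is_pos) {
    params$zm_gain_pos_video *
      (if (presentation == "live") params$live_amplification else 1) * subj_mult
  } else 0
  g_cs <- if (!is_pos) params$cs_gain_neg * subj_mult else 0

  d_emg <- ifelse(t_emg < 0, 0, drive(t_emg, params))
  env_zm <- params$emg_baseline_sd * (1 + g_zm * d_emg)
  env_cs <- params$emg_baseline_sd * (1 + g_cs * d_emg)
  emg_zm <- emg_carrier(n_emg, rate) * env_zm
  emg_cs <- emg_carrier(n_emg, rate) * env_cs

  nf <- design$n_frames
  fps <- design$au_fps
  t_frame <- (seq_len(nf) - 0.5) / fps # frame-bin centres
  lat_s <- params$au_latency_frames / fps
  drift <- params$au_drift_per_frame * (seq_len(nf) - 1L)
  au12 <- params$au_scale * g_zm * drive(t_frame - lat_s, params) + drift +
    smooth_au_noise(stats::rnorm(nf, 0, params$au_noise_sd), params$au_smoothing)
  au4 <- params$au_scale * g_cs * drive(t_frame - lat_s, params) + drift +
    smooth_au_noise(stats::rnorm(nf, 0, params$au_noise_sd), params$au_smoothing)

  if (software_tag == "openface_like" &&
      stats::runif(1) < params$p_zero_output) {
    au12 <- rep(0, nf)
  }

  quality <- pmin(1, pmax(0, 1 - abs(stats::rnorm(nf, 0, 0.02))))
  dips <- stats::runif(nf) < params$p_lowquality_frame
  if (any(dips)) quality[dips] <- stats::runif(sum(dips), 0.1, 0.5)

  rec <- list(
    subject = subject, trial = trial,
    emotion = emotion, presentation = presentation,
    emg_zm = emg_zm, emg_cs = emg_cs,
    au12 = au12, au4 = au4, quality = quality,
    onset_index = onset_index, emg_rate_hz = rate, au_fps = fps,
    software_tag = software_tag
  )
  class(rec) <- "trial_recording"
  rec
}

#' Enumerate the trials of a cohort
#'
#' Builds the trial-level metadata table implied by a design: every subject
#' contributes `trials_per_condition` trials in each of the four
#' emotion-by-presentation conditions, in a pseudo-randomised order.
#' Optionally removes the four live trials excluded in the validation study
#' after visual inspection of the model's live performances (one positive
#' trial for each of two subjects and one negative trial for each of two
#' others), taking the default cohort from 3000 to 2996 trials.
#'
#' @param design A [session_design()].
#' @param mimic_live_exclusions Apply the four live-performance exclusions.
#' @param seed Integer seed for the per-subject condition order.
#' @return A data frame with columns `subject`, `trial`, `emotion`,
#'   `presentation`.
#' @export
cohort_trial_table <- function(design, mimic_live_exclusions = FALSE,
                               seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conds <- design$conditions
  per_subject <- conds[rep(seq_len(nrow(conds)), each = design$trials_per_condition), ]
  rows <- do.call(rbind, lapply(seq_len(design$n_subjects), function(s) {
    ord <- sample.int(nrow(per_subject))
    data.frame(subject = sprintf("s%02d", s),
               trial = seq_len(nrow(per_subject)),
               emotion = per_subject$emotion[ord],
               presentation = per_subject$presentation[ord],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (mimic_live_exclusions) {
    subjects <- unique(rows$subject)
    if (length(subjects) < 4)
      stop("live-performance exclusions need at least 4 subjects")
    drop_one <- function(rows, subj, emo) {
      idx <- which(rows$subject == subj & rows$emotion == emo &
                     rows$presentation == "live")[1]
      if (is.na(idx)) stop("no live trial available to exclude for ", subj)
      rows[-idx, ]
    }
    rows <- drop_one(rows, subjects[1], "positive")
    rows <- drop_one(rows, subjects[2], "positive")
    rows <- drop_one(rows, subjects[3], "negative")
    rows <- drop_one(rows, subjects[4], "negative")
    rownames(rows) <- NULL
  }
  rows
}

#' Simulate a full cohort of trials
#'
#' Draws subject-level random effects (intercept and emotion slope on the
#' log-gain scale) and generates every trial of the design with
#' [simulate_trial()]. The whole cohort is reproducible from
#' `params$seed`.
#'
#' @inheritParams cohort_trial_table
#' @param params A [ground_truth_params()].
#' @param software_tag Passed to [simulate_trial()].
#' @return A list of `trial_recording` objects with the trial table
#'   attached as attribute `"trial_table"` and class `trial_cohort`.
#' @export
simulate_cohort <- function(design, params, software_tag = "generic",
                            mimic_live_exclusions = FALSE) {
  tab <- cohort_trial_table(design, mimic_live_exclusions,
                            seed = params$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed + 1L)
  subjects <- unique(tab$subject)
  eff <- data.frame(
    subject = subjects,
    intercept = stats::rnorm(length(subjects), 0, params$re_intercept_sd),
    emotion = stats::rnorm(length(subjects), 0, params$re_emotion_sd)
  )
  trials <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    e <- eff[eff$subject == tab$subject[i], ]
    trials[[i]] <- simulate_trial(
      design, params, tab$emotion[i], tab$presentation[i],
      software_tag = software_tag,
      subject_effects = c(intercept = e$intercept, emotion = e$emotion),
      subject = tab$subject[i], trial = tab$trial[i]
    )
  }
  attr(trials, "trial_table") <- tab
  attr(trials, "subject_effects") <- eff
  class(trials) <- "trial_cohort"
  trials
}

#' Simulate trial-wise responses directly
#'
#' Trial-level reduction of the signal generator: instead of synthesising
#' raw EMG and AU series, draws the scalar trial responses from the linear
#' model that the signal generator induces. The expected log-amplitude ZM
#' response of a trial is `log(1 + g)` with `g` the condition-congruent
#' envelope gain (`zm_gain` in positive-video trials, `zm_gain *
#' live_amplification` in positive-live trials, 0 in negative trials);
#' subject-level random intercepts and emotion slopes and trial-level
#' Gaussian noise are added, and the AU12 response is a noisy linear
#' function of the ZM response. This is the generator used for
#' mixed-model calibration and power simulations, where thousands of
#' cohorts would make raw-signal synthesis pointless.
#'
#' @param n_subjects,trials_per_condition Cohort size.
#' @param zm_gain,live_amplification Envelope gains as in
#'   [ground_truth_params()]; setting both so that all cell means are equal
#'   (e.g. `zm_gain = 0`) gives a null cohort.
#' @param re_intercept_sd,re_emotion_sd SDs of the subject random intercept
#'   and emotion slope on the response scale. Defaults are 50% of the
#'   corresponding fixed effect (emotion effect `log(1 + zm_gain)`), with a
#'   small fixed intercept SD since the fixed intercept is zero.
#' @param resid_sd Trial-level residual SD of the ZM response.
#' @param au_slope,au_noise_sd Linear coupling of the AU12 response to the
#'   ZM response and the SD of its independent noise.
#' @param mimic_live_exclusions Drop the four live trials excluded in the
#'   validation study (3000 -> 2996 rows at the default size).
#' @param seed Integer seed.
#' @return A data frame with one row per trial: `subject`, `trial`,
#'   `emotion`, `presentation` (factors with reference levels negative and
#'   video), `zm_response`, `au12_response`.
#' @export
simulate_response_cohort <- function(n_subjects = 50,
                                     trials_per_condition = 15,
                                     zm_gain = 1,
                                     live_amplification = 1.5,
                                     re_intercept_sd = 0.1,
                                     re_emotion_sd = 0.5 * log1p(zm_gain),
                                     resid_sd = 0.35,
                                     au_slope = 0.5,
                                     au_noise_sd = 0.35,
                                     mimic_live_exclusions = FALSE,
                                     seed = 1L) {
  design <- session_design(n_subjects = n_subjects,
                           trials_per_condition = trials_per_condition)
  tab <- cohort_trial_table(design, mimic_live_exclusions, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  subjects <- unique(tab$subject)
  u0 <- stats::rnorm(length(subjects), 0, re_intercept_sd)
  u1 <- stats::rnorm(length(subjects), 0, re_emotion_sd)
  names(u0) <- names(u1) <- subjects
  is_pos <- tab$emotion == "positive"
  is_live <- tab$presentation == "live"
  g <- ifelse(is_pos, zm_gain * ifelse(is_live, live_amplification, 1), 0)
  mu <- log1p(g)
  zm <- mu + u0[tab$subject] + u1[tab$subject] * is_pos +
    stats::rnorm(nrow(tab), 0, resid_sd)
  au <- au_slope * zm + stats::rnorm(nrow(tab), 0, au_noise_sd)
  data.frame(
    subject = factor(tab$subject),
    trial = tab$trial,
    emotion = factor(tab$emotion, levels = c("negative", "positive")),
    presentation = factor(tab$presentation, levels = c("video", "live")),
    zm_response = unname(zm),
    au12_response = unname(au)
  )
}

#' Write a cohort to long-format CSV files
#'
#' Writes the EMG channels and AU frame series of a cohort as two tidy CSV
#' files (`emg.csv`: subject, trial, emotion, presentation, sample_index,
#' zm, cs; `au.csv`: subject, trial, emotion, presentation, frame, au12,
#' au4, quality) plus a YAML manifest recording the design and seed.
#'
#' @param cohort A `trial_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param design,params The objects used to generate the cohort; stored in
#'   the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, design = NULL, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emg <- do.call(rbind, lapply(cohort, function(tr) {
    data.frame(subject = tr$subject, trial = tr$trial,
               emotion = tr$emotion, presentation = tr$presentation,
               sample_index = seq_along(tr$emg_zm) - 1L,
               zm = tr$emg_zm, cs = tr$emg_cs)
  }))
  au <- do.call(rbind, lapply(cohort, function(tr) {
    data.frame(subject = tr$subject, trial = tr$trial,
               emotion = tr$emotion, presentation = tr$presentation,
               frame = seq_along(tr$au12) - 1L,
               au12 = tr$au12, au4 = tr$au4, quality = tr$quality)
  }))
  utils::write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(au, file.path(dir, "au.csv"), row.names = FALSE)
  manifest <- list(
    n_trials = length(cohort),
    software_tag = cohort[[1]]$software_tag,
    design = if (!is.null(design)) unclass(design)[c(
      "n_subjects", "trials_per_condition", "trial_duration_s",
      "prestimulus_pad_s", "emg_rate_hz", "au_fps", "n_frames")],
    seed = if (!is.null(params)) params$seed
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort from long-format CSV files
#'
#' Inverse of [write_cohort_csv()]: reconstructs `trial_recording` objects
#' from the long-format EMG and AU tables.
#'
#' @param dir Directory containing `emg.csv`, `au.csv` and
#'   `manifest.yaml`.
#' @param emg_rate_hz,au_fps,prestimulus_pad_s Signal timing; read from the
#'   manifest when present.
#' @return A `trial_cohort` list.
#' @export
read_cohort_csv <- function(dir, emg_rate_hz = 1000, au_fps = 29.97,
                            prestimulus_pad_s = 3) {
  man_path <- file.path(dir, "manifest.yaml")
  software_tag <- "generic"
  if (file.exists(man_path)) {
    man <- yaml::read_yaml(man_path)
    if (!is.null(man$design)) {
      emg_rate_hz <- man$design$emg_rate_hz %||% emg_rate_hz
      au_fps <- man$design$au_fps %||% au_fps
      prestimulus_pad_s <- man$design$prestimulus_pad_s %||% prestimulus_pad_s
    }
    software_tag <- man$software_tag %||% software_tag
  }
  emg <- utils::read.csv(file.path(dir, "emg.csv"))
  au <- utils::read.csv(file.path(dir, "au.csv"))
  keys <- unique(emg[c("subject", "trial", "emotion", "presentation")])
  onset_index <- as.integer(round(prestimulus_pad_s * emg_rate_hz))
  trials <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    ei <- emg$subject == k$subject & emg$trial == k$trial
    ai <- au$subject == k$subject & au$trial == k$trial
    rec <- list(subject = k$subject, trial = k$trial,
                emotion = k$emotion, presentation = k$presentation,
                emg_zm = emg$zm[ei], emg_cs = emg$cs[ei],
                au12 = au$au12[ai], au4 = au$au4[ai],
                quality = au$quality[ai],
                onset_index = onset_index, emg_rate_hz = emg_rate_hz,
                au_fps = au_fps, software_tag = software_tag)
    class(rec) <- "trial_recording"
    rec
  })
  attr(trials, "trial_table") <- keys
  class(trials) <- "trial_cohort"
  trials
}

`%||%` <- function(a, b) if (is.null(a)) b else a
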