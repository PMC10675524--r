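#' Default run configuration
#'
#' Aggregates every tunable of the pipeline with its reference default:
#' response windows 0-1 s and 2.5-3 s, quality thresholds 0.6 (FaceReader
#' family) and 0.75 (others), cross-correlation up to 45 lags, 10,000
#' bootstrap resamples, standardized-residual cutoff 3, and the 2 x 2
#' session design of 50 subjects with 15 trials per condition.
#'
#' @param ... Overrides for any top-level section: `design`, `params`,
#'   `preproc`, `windows`, `quality`, `exclusion`, `alpha`, `max_lag`,
#'   `n_boot`, `seed`, `software_tag`, `mimic_live_exclusions`,
#'   `write_raw`.
#' @return An object of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    design = session_design(),
    params = ground_truth_params(),
    preproc = preproc_params(),
    windows = response_windows(),
    quality = quality_thresholds(),
    exclusion = exclusion_rule(),
    alpha = 0.05,
    max_lag = 45L,
    n_boot = 10000L,
    seed = 1L,
    software_tag = "generic",
    mimic_live_exclusions = FALSE,
    write_raw = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  w <- cfg$windows
  if (!inherits(w, "response_windows"))
    w <- do.call(response_windows, w)
  cfg$windows <- w
  if (cfg$max_lag < 1) stop("max_lag must be positive")
  if (cfg$n_boot < 0) stop("n_boot must be non-negative")
  if (!cfg$software_tag %in% c("generic", "facereader_like", "pyfeat_like",
                               "openface_like"))
    stop("unknown software_tag: ", cfg$software_tag)
  cfg
}

# Sections of the YAML config file and the constructors validating them.
config_sections <- function() {
  list(design = session_design, params = ground_truth_params,
       preproc = preproc_params, windows = response_windows,
       quality = quality_thresholds, exclusion = exclusion_rule)
}

#' Load a run configuration from a YAML file
#'
#' Reads a key-value config file and merges it over the defaults of
#' [default_config()]. An empty (or missing-key) file therefore yields
#' the full default configuration. Unknown keys, at the top level or
#' inside a section, are rejected, and section values are passed through
#' the corresponding constructor, so invariant violations (e.g. a
#' reversed response window) surface as errors naming the key.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  sections <- config_sections()
  scalar_keys <- c("alpha", "max_lag", "n_boot", "seed", "software_tag",
                   "mimic_live_exclusions", "write_raw")
  unknown <- setdiff(names(raw), c(names(sections), scalar_keys))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(sections)) {
    if (is.null(raw[[sec]])) next
    ctor <- sections[[sec]]
    allowed <- names(formals(ctor))
    bad <- setdiff(names(raw[[sec]]), allowed)
    if (length(bad) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    defaults <- unclass(cfg[[sec]])
    args <- defaults[intersect(names(defaults), allowed)]
    args[names(raw[[sec]])] <- raw[[sec]]
    cfg[[sec]] <- tryCatch(do.call(ctor, args), error = function(e)
      stop("config section '", sec, "': ", conditionMessage(e), call. = FALSE))
  }
  for (key in scalar_keys) if (!is.null(raw[[key]])) cfg[[key]] <- raw[[key]]
  validate_config(cfg)
}

#' Write a run configuration to a YAML file
#'
#' Serialises the sections and scalars of a `run_config` so that
#' [load_config()] reads back an equivalent configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  ctors <- config_sections()
  sections <- names(ctors)
  out <- lapply(sections, function(nm) {
    s <- unclass(cfg[[nm]])
    # only constructor arguments are serialised; derived fields
    # (n_frames, the condition grid) are recomputed on load
    s <- s[intersect(names(s), names(formals(ctors[[nm]])))]
    s[!vapply(s, is.null, logical(1))]
  })
  names(out) <- sections
  scalars <- cfg[c("alpha", "max_lag", "n_boot", "seed", "software_tag",
                   "mimic_live_exclusions", "write_raw")]
  yaml::write_yaml(c(out, scalars), path)
  invisible(path)
}

log_event <- function(log_path, ...) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the validation pipeline
#'
#' Orchestrates the stages of the analysis on a synthetic cohort:
#' `simulate` (generate the cohort), `responses` (preprocess the EMG,
#' extract trial-wise responses, resample the ZM to the frame grid and
#' apply the quality mask), `validate` (sign-congruence and mimicry
#' detection metrics), `associate` (repeated-measures correlation with
#' bootstrap CI, condition mixed model with influence exclusion and
#' simple effects) and `xcorr` (group-average time series and
#' cross-correlation latency). Each stage writes tidy CSV artifacts into
#' `out_dir` and appends to a JSON-lines run log; `responses` artifacts
#' are reused from disk when a later stage is run on its own.
#'
#' Outputs are deterministic given `cfg$seed`.
#'
#' @param cfg A `run_config`.
#' @param out_dir Artifact directory (created if missing).
#' @param stages Ordered subset of
#'   `c("simulate", "responses", "validate", "associate", "xcorr")`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "responses", "validate",
                                    "associate", "xcorr")) {
  stopifnot(inherits(cfg, "run_config"))
  all_stages <- c("simulate", "responses", "validate", "associate", "xcorr")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  state <- list()
  write_config(cfg, file.path(out_dir, "manifest.yaml"))

  responses_path <- file.path(out_dir, "responses.csv")
  frames_path <- file.path(out_dir, "frames.csv")

  need_cohort <- any(c("simulate", "responses") %in% stages)
  if (need_cohort) {
    log_event(log_path, stage = "simulate", seed = cfg$params$seed)
    state$cohort <- simulate_cohort(cfg$design, cfg$params,
                                    software_tag = cfg$software_tag,
                                    mimic_live_exclusions = cfg$mimic_live_exclusions)
    if (isTRUE(cfg$write_raw))
      write_cohort_csv(state$cohort, out_dir, cfg$design, cfg$params)
  }

  if ("responses" %in% stages) {
    log_event(log_path, stage = "responses")
    resp <- cohort_responses(state$cohort, cfg$preproc, cfg$windows,
                             cfg$quality)
    state$responses <- resp
    utils::write.csv(resp, responses_path, row.names = FALSE)
    frames <- pipeline_frames(state$cohort, cfg)
    state$frames <- frames
    utils::write.csv(frames, frames_path, row.names = FALSE)
    log_event(log_path, stage = "responses",
              n_trials = nrow(resp), n_excluded = sum(resp$excluded))
  }

  load_cached <- function(path, what) {
    if (!file.exists(path))
      stop("stage needs cached ", what, " (", path,
           "); run the 'responses' stage first")
    utils::read.csv(path)
  }

  if ("validate" %in% stages) {
    if (is.null(state$responses))
      state$responses <- load_cached(responses_path, "responses")
    log_event(log_path, stage = "validate")
    combos <- expand.grid(channel = c("AU12", "AU4"),
                          include_zero_output = unique(c(FALSE,
                            cfg$software_tag == "openface_like")),
                          stringsAsFactors = FALSE)
    metrics <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      cbind(software_tag = cfg$software_tag,
            validation_metrics(state$responses,
                               channel = combos$channel[i],
                               include_zero_output = combos$include_zero_output[i]))
    }))
    state$validation <- metrics
    utils::write.csv(metrics, file.path(out_dir, "validation_metrics.csv"),
                     row.names = FALSE)
  }

  if ("associate" %in% stages) {
    if (is.null(state$responses))
      state$responses <- load_cached(responses_path, "responses")
    log_event(log_path, stage = "associate", seed = cfg$seed)
    resp <- state$responses[!state$responses$excluded, , drop = FALSE]
    rc <- rmcorr(resp$zm_response, resp$au12_response, resp$subject,
                 n_boot = cfg$n_boot, seed = cfg$seed)
    rmtab <- data.frame(software_tag = cfg$software_tag, r = rc$r,
                        df = rc$df, ci_lower = rc$ci95[1],
                        ci_upper = rc$ci95[2], p = rc$p,
                        n_obs = rc$n_obs, n_subjects = rc$n_subjects)
    utils::write.csv(rmtab, file.path(out_dir, "rmcorr.csv"),
                     row.names = FALSE)
    cm <- fit_condition_model(resp, response = "au12_response",
                              alpha = cfg$alpha)
    ie <- influence_exclude(cm, cfg$exclusion)
    se <- simple_effects(ie$fit)
    log_event(log_path, stage = "associate",
              selected_random_structure = cm$selected,
              n_trials_excluded = ie$n_excluded,
              subjects_excluded = length(ie$excluded_subjects))
    utils::write.csv(ie$fit$fixed_effects,
                     file.path(out_dir, "fixed_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(se$contrasts,
                     file.path(out_dir, "simple_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(se$cell_means,
                     file.path(out_dir, "cell_means.csv"),
                     row.names = FALSE)
    state$rmcorr <- rc
    state$model <- ie
    state$simple_effects <- se
  }

  if ("xcorr" %in% stages) {
    if (is.null(state$frames))
      state$frames <- load_cached(frames_path, "frame series")
    log_event(log_path, stage = "xcorr")
    fr <- state$frames[!state$frames$excluded, , drop = FALSE]
    key <- interaction(fr$subject, fr$trial, drop = TRUE)
    by_trial <- split(fr, key)
    # group-average time series per condition x measurement
    ts_rows <- list()
    for (meas in c("zm", "au12")) {
      for (cond in unique(paste(fr$emotion, fr$presentation, sep = "_"))) {
        tr <- Filter(function(d)
          paste(d$emotion[1], d$presentation[1], sep = "_") == cond, by_trial)
        if (length(tr) < 2) next
        gav <- group_average_timeseries(lapply(tr, `[[`, meas))
        ts_rows[[paste(meas, cond)]] <-
          cbind(measurement = meas, condition = cond, gav)
      }
    }
    ts <- do.call(rbind, ts_rows)
    rownames(ts) <- NULL
    utils::write.csv(ts, file.path(out_dir, "timeseries_group.csv"),
                     row.names = FALSE)
    # cross-correlation on positive trials: curves in the standardized
    # (crosscorr) convention, peak/latency estimation with the per-lag
    # Pearson variant (the standardized overlap taper biases peak lags
    # toward zero for ramp-plateau responses; see the methods vignette)
    pos <- Filter(function(d) d$emotion[1] == "positive", by_trial)
    if (length(pos) > 0) {
      subj <- vapply(pos, function(d) as.character(d$subject[1]), character(1))
      cond <- vapply(pos, function(d)
        paste0("positive_", d$presentation[1]), character(1))
      xr_std <- lapply(pos, function(d)
        cross_correlation(d$zm, d$au12, max_lag = cfg$max_lag,
                          fps = cfg$design$au_fps))
      xr_pear <- lapply(pos, function(d)
        cross_correlation(d$zm, d$au12, max_lag = cfg$max_lag,
                          fps = cfg$design$au_fps,
                          normalization = "pearson"))
      agg <- aggregate_xcorr(xr_std, subject = subj, condition = cond,
                             fps = cfg$design$au_fps)
      agg_pear <- aggregate_xcorr(xr_pear, subject = subj, condition = cond,
                                  fps = cfg$design$au_fps)
      utils::write.csv(agg$curves, file.path(out_dir, "xcorr_group.csv"),
                       row.names = FALSE)
      utils::write.csv(agg_pear$peaks, file.path(out_dir, "xcorr_peaks.csv"),
                       row.names = FALSE)
      state$xcorr <- agg
      state$xcorr_peaks <- agg_pear$peaks
      log_event(log_path, stage = "xcorr", n_trials = length(pos))
    }
    state$timeseries <- ts
  }

  invisible(state)
}

# Per-trial frame-grid series: resampled log ZM amplitude and the
# quality-masked AU12, long format.
pipeline_frames <- function(cohort, cfg) {
  rows <- lapply(cohort, function(tr) {
    zm <- preprocess_emg(tr$emg_zm, tr$onset_index, tr$emg_rate_hz,
                         cfg$preproc, channel = "ZM")
    zm_frames <- resample_emg_to_frames(zm$amplitude, tr$emg_rate_hz,
                                        tr$onset_index, tr$au_fps,
                                        length(tr$au12))
    masked <- apply_quality_mask(tr, cfg$quality)
    data.frame(subject = tr$subject, trial = tr$trial,
               emotion = tr$emotion, presentation = tr$presentation,
               frame = seq_along(tr$au12) - 1L,
               zm = zm_frames, au12 = masked$au12,
               excluded = masked$excluded, reason = masked$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
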