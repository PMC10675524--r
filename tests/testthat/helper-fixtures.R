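# Shared fixture builders: small designs keep signal synthesis fast while
# preserving the 2 x 2 structure the analysis assumes.

small_design <- function(n_subjects = 4, trials_per_condition = 2, ...) {
  session_design(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition, ...)
}

quiet_params <- function(...) {
  ground_truth_params(p_lowquality_frame = 0, ...)
}

rms <- function(x) sqrt(mean(x^2))

# Response of one synthetic trial's ZM channel after full preprocessing.
zm_trial_response <- function(trial, preproc = preproc_params(),
                              windows = response_windows()) {
  pe <- preprocess_emg(trial$emg_zm, trial$onset_index, trial$emg_rate_hz,
                       preproc)
  trial_response(pe$amplitude, trial$emg_rate_hz, windows,
                 onset_index = trial$onset_index)
}
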