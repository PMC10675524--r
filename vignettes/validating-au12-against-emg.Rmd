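---
title: "Methods: validating automated AU12 coding against zygomaticus EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating automated AU12 coding against zygomaticus EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemimic)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, what the synthetic generator
does and does not emulate, and where the design was genuinely open.

## The measurement problem

Spontaneous facial mimicry — the involuntary, low-amplitude mirroring of
an observed facial expression during passive viewing — is conventionally
measured with surface EMG over the zygomaticus major (ZM; smiling) and
corrugator supercilii (CS; frowning). Automated FACS software estimates
the intensity of the corresponding action units (AU12, lip corner puller;
AU4, brow lowerer) from video. The validation question is whether the
AU12 channel carries the same trial-wise information as the ZM channel in
a 2 × 2 within-subject design crossing emotion (positive/negative) with
presentation (live/video), where live presentation is expected to amplify
positive-condition mimicry.

## EMG preprocessing

The chain is fixed in this order: zero-phase filtering, per-trial linear
detrend, baseline correction, rectification, log transform.

* **Filters.** Second-order IIR notches (RBJ biquad, quality factor 30)
  at the mains frequency and its harmonics, followed by 4th-order
  Butterworth high-pass (20 Hz) and low-pass filters, all run
  forward–backward. The nominal 500 Hz low-pass equals Nyquist at the
  default 1000 Hz sampling rate, so the effective cutoff is capped at
  90 % of Nyquist (450 Hz at 1 kHz); this leaves the 20–450 Hz
  surface-EMG band untouched while keeping the filter well posed. Notches
  are placed at 60, 120, …, 480 Hz (multiples up to the nominal low-pass
  and below Nyquist).
* **Edge handling.** `signal::filtfilt` alone leaks substantial edge
  transients (a 4 s mains sine is attenuated only to a few percent RMS),
  so every filter runs over an odd-reflection-padded copy of the trace
  (1000 samples per side), after which steady-state attenuation at the
  notch frequencies is on the order of 10⁻⁴ RMS. A related subtlety
  shows up in testing: a sine truncated mid-cycle has spectral leakage
  that *no* notch can remove, so attenuation is asserted on the central
  steady-state portion of the trace.
* **Detrend and baseline.** The linear trend is removed by least squares
  over the whole per-trial segment (the method is unconstrained by the
  source description; least squares is the standard choice). All samples
  are then shifted by the mean over the baseline window, [−3 s, +1 s)
  around stimulus onset — the window ends where the expresser's neutral
  phase ends. After the shift the baseline-window mean is zero by
  construction.
* **Rectify + log.** `log(1 + |x|)` converts zero-centred oscillations to
  log amplitudes and corrects the right skew of rectified EMG. The
  transform is unit-sensitive (it treats "1" as a meaningful amplitude);
  the generator emits envelopes in multiples of the resting-noise SD, so
  the default scale is 1.
* **Artifact screening** is off by default (screening of real recordings
  is a manual step); an automated surrogate flags any sample beyond a
  configurable multiple of the trial SD.

## Trial responses and detection metrics

A trial response is the mean over the maximal expression phase
([2.5, 3.0) s) minus the mean over the neutral phase ([0, 1) s); all
windows are half-open and sample *i* (1-based) carries time
`(i − 1 − onset_index) / rate`. At 29.97 fps these windows select frames
0–29 and 75–89 of a 90-frame trial.

Sign congruence uses the EMG response sign as ground truth. A response of
exactly zero is grouped with the negative sign — software that emits
nothing has not detected anything. This tie-break also resolves the
detection taxonomy's "null or negative" phrasing. The compound
classification mode (AU12 up *and* AU4 down, against ZM up *and* CS down)
does not exhaust the 2×2×2 outcome space; uncovered combinations (e.g.
both AUs rising) map to "not detected", and the default mode is
single-channel (AU12 vs ZM on positive trials, AU4 vs CS on negative
trials), which matches how per-AU validation tables are laid out.
Metrics with zero denominators are reported as `NA`, never as 0 — a
generator whose positive trials always contain a true ZM response
produces no truth-negative trials, and a specificity of "0" there would
be a lie.

## Repeated-measures correlation

`rmcorr()` fits the ANCOVA `y ~ subject + x` and reports
`r = sign(b)·sqrt(SS_x / (SS_x + SS_err))` with the sums of squares taken
sequentially after the subject factor, `df = n_obs − n_subjects − 1`, and
the slope's F test. Algebraically this `r` equals the Pearson correlation
of the subject-mean-centred variables; the test suite exploits that
identity as an independent oracle (agreement to 1e−10 on random
instances) while the implementation keeps the ANCOVA route.

The 95 % CI is a **cluster bootstrap**: subjects are resampled with
replacement, trials kept intact within subject, and resampled copies of
the same subject receive distinct identities. The resampling unit was a
genuinely open choice — trial-level resampling would break the
repeated-measures structure that the statistic exists to respect.
Degenerate resamples (no estimable slope) are redrawn and counted. The
default is 10,000 resamples; the test suite uses 100–500 to stay within
desk-scale runtimes, which it states here as a problem-size choice, not a
recommendation for analyses.

## Condition contrasts

`fit_condition_model()` fits `response ~ emotion × presentation` with
subject as the random factor, reference levels *negative* and *video*,
REML estimation and the BOBYQA optimizer. The random structure is chosen
by parsimonious forward selection: starting from a random intercept,
by-subject slopes for emotion, presentation and the interaction are added
while the likelihood-ratio test (on ML refits) stays significant at α and
the richer model is neither singular nor non-convergent. Fixed-effect
tests and simple effects (cell means, live−video within each emotion,
positive−negative within each presentation) use Satterthwaite degrees of
freedom; Kenward–Roger is deliberately out of scope. No multiplicity
correction is applied anywhere.

**Influence exclusion.** Trials are excluded when the absolute
standardized conditional residual (residual over the estimated residual
SD) exceeds 3, or when the trial-level Cook's distance exceeds
Q3 + 1.5 × IQR of its distribution. Trial-level Cook's distances are
computed exactly by whitening: the marginal covariance
`V = Z D Zᵀ + σ²I` is block-diagonal by subject, each block is whitened
with its Cholesky factor, and OLS case-deletion Cook's distances in the
whitened model are the GLS ones. Subject-level Cook's distances come from
brute-force leave-one-subject-out refits, measured in the metric of the
fixed-effect precision; subjects beyond the same boxplot cutoff are
excluded, and the model is refit once. A caveat worth stating: Cook's
distances are right-skewed by construction (roughly χ²₁-shaped under
clean Gaussian data), so the Q3 + 1.5 × IQR rule flags several percent of
perfectly well-behaved trials. That is a property of the rule, not a bug;
the tests assert a modest exclusion rate rather than a near-zero one.
Exclusion of more than half the data aborts with a diagnostic.

**Power.** `power_by_simulation()` simulates response-level cohorts per
candidate sample size, fits the intercept + emotion-slope model (the
structure the ZM data select), and counts significant interactions. The
test suite runs 60 replicates per n on 8-trial-per-condition cohorts;
under a null generator the rejection rate is asserted to track α.

## Frame alignment, quality masking, cross-correlation

ZM log amplitudes are resampled to the frame grid by bin means over
half-open bins `[i/fps, (i+1)/fps)` (an interpolation alternative sits
behind a flag). The 90-frame grid at 29.97 fps spans 3.003 s, so the last
bin may be partially covered. Frames below the software-specific quality
threshold (0.6 for FaceReader-like, 0.75 for Py-Feat/OpenFace-like
output) become missing; the default policy excludes a trial on any
missing frame — "these trials were excluded" is most plausibly whole-trial
exclusion — with a fractional policy available for sensitivity analysis.
All-zero AU12 trials from OpenFace-like software are excluded as
`zero_output`. For group-average time series, each trial is first
anchored so its first value is 0.

**Cross-correlation conventions, and a bias worth knowing about.** The
default follows the full-series standardization convention (both series
centred by their overall means, scaled by their population SDs, lagged
products summed over the overlap and divided by the *full* length N).
This matches the convention of the numerical environment classically used
for such analyses, and it is what the package writes as correlogram
curves. It has, however, a structural consequence for latency
*estimation*: the implicit `(N − |k|)/N` taper multiplies the correlation
at lag k, and for ramp-plateau trials — whose autocorrelation is nearly
flat over small lags — the taper dominates, pulling the peak toward lag
0. In the noise-free limit a series cross-correlated with a pure
4-frame-delayed copy of itself peaks at lag 0 under this convention, and
monotonically *decreases* over lags 0…10. The per-lag Pearson variant
(`normalization = "pearson"`, each lag's overlapping segments re-centred
and re-scaled) recovers the shift exactly in that limit, so peak-lag and
latency estimation — in the pipeline and in the recovery tests — use the
Pearson variant, while curves remain available in both conventions. Peak
search is restricted to non-negative lags by default (the hypothesis is
AU output lagging muscle), with full-range search behind a flag.
Aggregation is two-stage (trials → subject, subjects → group), and group
peaks are reported with plateau ranges when adjacent lags tie at 3
decimal places. Lag-to-latency conversion rounds `lag · 1000 / fps` to
the nearest millisecond, giving 33/167/200/300 ms for lags 1/5/6/9 at
29.97 fps.

## The synthetic session generator

The generator produces what the analysis consumes, with known ground
truth:

* **EMG**: Gaussian white noise band-passed to the 20–450 Hz surface-EMG
  band (so the preprocessing filters are near-transparent to it), then
  amplitude-modulated as `emg_baseline_sd · (1 + g · drive(t))`. The
  drive is a raised-cosine ramp from 1.0 s to 2.5 s — the source design
  says only "gradual", and the raised cosine is smooth, monotone and
  parameterized so alternatives are pluggable. The gain g is
  condition-congruent: `zm_gain_pos_video` for ZM in positive trials
  (times `live_amplification` when live), `cs_gain_neg` for CS in
  negative trials, zero otherwise.
* **AU series**: `au_scale · g · drive(t − latency)` plus linear drift
  plus Gaussian frame noise smoothed with a 3-frame centred moving
  average (an exponential-smoothing preset emulates the heavier temporal
  smoothing of FaceReader-like output — a causal filter that adds a
  little latency of its own, as that software family appears to).
  Evaluation uses frame-bin centres, keeping the AU and resampled-EMG
  grids aligned.
* **Pathologies**: OpenFace-like trials emit an all-zero AU12 series with
  probability 0.454 (the observed rate) and a positive drift; quality
  scores sit near 1 with dips below every threshold at a configurable
  per-frame rate.
* **Subject heterogeneity**: log-normal multipliers on the
  condition-congruent gain — a random intercept and an emotion slope.
  No variance components are reported for the original recordings, so
  the SDs default to 50 % of the corresponding fixed effect on the
  log-gain scale (emotion slope SD 0.35 ≈ 0.5 · log(1 + zm_gain)), with
  a small fixed intercept SD of 0.1 since the fixed intercept is zero.
  These are stated in the configuration, not hidden.
* **Raw EMG amplitude units** are hardware-dependent and unreported;
  envelopes are therefore expressed in multiples of the resting-noise SD
  and exposed as configuration.

A **response-level reduction** (`simulate_response_cohort()`) draws the
scalar trial responses directly from the linear model the signal
generator induces (cell means `log(1 + g)`, subject random effects,
residual SD 0.35, AU response coupled to the ZM response with slope 0.5
and noise SD 0.35). Mixed-model calibration and power simulations run on
hundreds of cohorts; synthesising hundreds of thousands of 1 kHz EMG
traces for them would exercise nothing those tests check. The signal
path is exercised end-to-end where it matters: preprocessing, response
extraction, resampling and latency recovery all run on full synthetic
recordings.

**What passing tests do and do not show.** The generator emulates the
design's statistical structure, not faces: there is no video, no
landmark estimation, no AU model. Recovery results therefore validate
the *pipeline* — that it extracts what was injected — not any claim
about how real software behaves on real faces. Real AU output has
occlusion artifacts, identity-dependent biases and nonstationary noise
that the generator does not attempt; conclusions about a specific
software product require its actual output.

## Problem sizes used by the test suite

Chosen to keep the suite at desk scale while leaving the assertions
statistically meaningful, and fixed before the assertions were written:
latency recovery uses 50 cohorts of 5 subjects × 2 trials/condition at
low AU noise (0.01), cycling injected latencies 0–10; null calibration
uses 200 cohorts and the sign-pattern recovery 100 cohorts of
20 subjects × 8 trials/condition; bootstrap coverage uses 50
replications of 20 subjects × 10 trials with 120 resamples.

## Known limitations

* The exclusion bookkeeping of specific published analyses (e.g. exact
  retained-trial counts after zero-output removal) is not reproduced;
  the rules are, their interaction with any particular dataset is not.
* No statistical test compares live vs video latency (the group curves
  are descriptive, matching the scope of the analysis they mirror).
* The low-pass at Nyquist is resolved by capping, not by resampling; at
  sampling rates where 500 Hz sits comfortably below Nyquist the nominal
  cutoff is used as given.
* `lag 10` converts to 334 ms by nearest-integer rounding; sources that
  print 333 ms for it are using truncation for that one value, and the
  package does not special-case it.
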