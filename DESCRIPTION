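Package: facemimic
Title: Validating Automated Facial Action Coding Against Facial EMG for
    Spontaneous Mimicry Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate automated facial action coding system (FACS)
    output, in particular action unit 12 (lip corner puller), against
    zygomaticus major surface electromyography (EMG) as the reference
    measurement of spontaneous facial mimicry. Implements the full
    validation pipeline for a 2 x 2 within-subject passive-viewing design
    (emotion: positive/negative; presentation: live/video): zero-phase EMG
    filtering with mains notch and band-pass, per-trial detrending,
    baseline correction, rectification and log transform; trial-wise
    response extraction over neutral and maximal expression windows;
    sign-congruence and confusion-matrix detection metrics; repeated
    measures correlation with cluster bootstrap confidence intervals;
    linear mixed-effects condition contrasts with parsimonious random
    structure selection and influence-based case exclusion; frame-rate
    alignment, quality masking and cross-correlation latency estimation;
    and a synthetic session generator that emulates the design, including
    known software pathologies (whole-trial zero action-unit output,
    positive drift, low-quality frames), so that every stage is testable
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
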