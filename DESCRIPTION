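Package: icehrv
Title: Frequency-Domain Heart Rate Variability Analysis for Longitudinal
    Isolation and Confinement Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing the time course of cardiac
    autonomic modulation from beat-by-beat RR-interval recordings in small
    longitudinal cohorts, such as Antarctic overwintering crews. Covers
    editing of raw RR series to normal-to-normal (NN) series with a
    series-level discard rule, Welch-periodogram band powers (VLF, LF, HF)
    with normalized units and the LF/HF ratio, per-subject Tukey-fence
    outlier screening on log HF, and random-intercept linear mixed models
    with Satterthwaite degrees of freedom, adjusted means, pre-planned
    polynomial trend contrasts and trimester contrasts. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    emmeans,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
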