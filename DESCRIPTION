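Package: isopupil
Title: Iso-Luminant VR Pupillometry: Separating Light Reflex from Cognitive Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for iso-luminant virtual-reality pupillometry
    sessions that dissociate the pupillary light reflex (PLR) from the
    task-evoked pupillary response (TEPR). Builds three-phase protocol
    timelines (luminance alternation, washout/baseline, auditory cognitive
    load blocks), detects and interpolates blink and velocity artifacts,
    applies dual-pathway zero-phase Butterworth filtering (4 Hz for reflex
    dynamics, 0.5 Hz for sustained cognitive trends), extracts per-session
    PLR and cognitive-load outcome metrics including the velocity-ratio
    dissociation statistic, and computes cohort-level summary statistics
    (one-sample t, Cohen's d, Wilcoxon signed-rank). A ground-truthed
    session simulator with first-order pupil dynamics, hippus, blinks and
    sensor noise supports end-to-end validation without data collection.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
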