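Package: oddballkit
Title: Simulation and Analysis of Mobile Visual-Oddball EEG/fNIRS Validation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale replication of a mobile visual-oddball
    validation experiment with simultaneous EEG and fNIRS recording. Provides
    an oddball task-event engine with configurable timing and target-gap
    constraints, a synthetic participant that generates behavioral responses,
    multichannel EEG with a P300-bearing event-related potential, and
    two-wavelength fNIRS intensities with an event-locked hemodynamic
    response plus systemic, skin, and motion artifacts; and the full analysis
    pipeline: reaction-time/accuracy summaries with the paired Wilcoxon
    signed-rank test and effect size, ERP epoching and P300 extraction,
    modified Beer-Lambert conversion with scalp-coupling-index channel
    pruning, wavelet and spline motion correction, low-pass physiological
    filtering, short-channel regression, region-of-interest aggregation, and
    cohort-level grand averages and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
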