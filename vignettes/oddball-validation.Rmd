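---
title: "Simulating and analyzing a mobile visual-oddball EEG/fNIRS experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing a mobile visual-oddball EEG/fNIRS experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballkit)
```

## The experiment this package models

A visual oddball task presents a stream of frequent "standard" stimuli with
rare "target" stimuli interleaved. Healthy adults respond more slowly to
targets, targets evoke a larger P300 — a positive event-related potential
(ERP) deflection roughly 300 ms after stimulus onset, maximal over midline
central/parietal electrodes — and they drive an oxygenated-hemoglobin (HbO)
increase over right prefrontal cortex measurable with functional
near-infrared spectroscopy (fNIRS). A mobile, abbreviated form of this task
(4 minutes instead of the usual ~20) run on a tablet with wearable
32-channel EEG and 51-channel fNIRS reproduces all three effects at the
cohort level.

`oddballkit` re-implements that validation study as a fully synthetic,
desk-scale experiment: a task-event engine, a generative participant model,
and the complete analysis chain, so that every stage of the pipeline can be
tested end to end without human recordings.

## Task engine

The default timing is the validated protocol: onset-to-onset interstimulus
interval (ISI) 2 s, stimulus presentations 0.5 s, a 240 s task flanked by
two 10 s resting baselines, and between 7 and 21 standards between
consecutive targets. `floor(task_duration / isi)` onsets are laid on an
exact ISI grid starting at the end of the first baseline.

The protocol only *bounds* the inter-target gaps; the rule that generates
them is not part of the specification. We default to a uniform integer draw
on `[gap_min, gap_max]` — the maximum-entropy choice given the constraint —
and expose both bounds in `task_config()`. Published run statistics suggest
the original task used a narrower effective distribution; we deliberately do
not attempt to match it, since any such rule would be guesswork.

Task events are serialized as three JSON-lines record streams mirroring the
lab-streaming-layer outlets of the acquisition software: `metadata`
(configuration and task/baseline boundary records), `stimulus` (one record
per presentation), and `marker` (button presses). Timestamps are seconds on
a run-local monotonic clock; wall-clock synchronization across devices is
out of scope for a single-process simulation.

## The synthetic participant

### Behavior

Per-trial reaction times are lognormal, moment-matched to the configured
class means and SDs (defaults: target 718 (SD 148) ms, standard 542 (SD
122) ms). A lognormal is the standard positive, right-skewed RT model and is
fully determined here by the two printed moments. The button matches the
stimulus class with the class accuracy probability (defaults 0.9458 /
0.9912); a draw beyond the next onset becomes an omission. Between
participants, the standard-class mean and a *strictly positive* lognormal
target−standard difference (mean 176 ms, SD 20 ms) are drawn separately, so
every simulated participant's true effect has the expected sign — matching
the cohort in which all participants responded slower to targets.

### EEG

Each stimulus adds one Gaussian-bump ERP kernel per channel. The kernel SD
is 50 ms (total span ~200 ms); amplitudes and latencies per channel and
class live in a table defaulting to the reported midline values (Cz: 3.5397
µV at 356 ms for targets, 0.74667 µV at 372 ms for standards; Pz: 2.7219 µV
at 296 ms, 0.949 µV at 268 ms) with an ROI-weighted falloff elsewhere
(parietal 0.4, frontal 0.25, temporal 0.15 of the Cz amplitude). A single
positive bump suffices because only the P300 is analyzed; earlier components
(N1/P2) are an extension point, not modeled.

Noise is 1/f-shaped Gaussian background above 1 Hz with a flat shoulder
below it — recorded EEG is AC-coupled, so its power does not diverge toward
DC — scaled to 5 µV RMS by default, plus a 60 Hz line sinusoid (2 µV) and
occasional ±150 µV bursts standing in for blinks/EMG so that
amplitude-threshold epoch rejection has something to reject. Electrode
impedances are drawn around ~10 kΩ with a configurable fraction (default
5%) pushed above the 30 kΩ validity threshold. All noise magnitudes are
package defaults: the study published none, and none of these numbers
should be read as reported values.

### fNIRS

Long channels (30 mm source-detector separation) in the right-frontal ROI
carry a neural HbO response: the class amplitude (default 0.2 µM for
targets, 0 for standards) times a canonical double-gamma hemodynamic
response function (HRF) peaking at 9 s, convolved with the stimulus train.
Neural HbR follows at −⅓ of HbO, the fixed ratio that keeps the
two-wavelength inversion well-posed. Systemic physiology — cardiac 1.2 Hz
(0.8 µM), respiratory 0.25 Hz (0.3 µM), Mayer waves 0.1 Hz (0.2 µM) — and a
low-frequency skin component (0.3 µM) are added to every channel; the skin
signal of each 8 mm short channel reappears in its region's long channels
scaled by `skin_share` (default 0.8). Systemic components carry HbR at
+0.3 × HbO (blood-volume-driven, same sign as HbO); this is the
physiologically standard convention for pulsatile components and keeps the
760 nm wavelength responsive in the cardiac band, which the scalp coupling
index requires. Concentrations convert to two-wavelength intensities
through the *forward* modified Beer-Lambert model — the exact inverse of the
analysis-side conversion — after which optical-density measurement noise
(2 × 10⁻⁴), motion spikes (1/min) and baseline step shifts (0.3/min) are
injected, and a configurable fraction (5%) of channels is given broken
optode coupling (independent noise per wavelength, so their scalp coupling
index collapses).

## Analysis pipeline

### Behavior

Responses are attributed to the latest stimulus preceding them by more than
100 ms (anticipation floor) and at most one ISI; omissions are excluded from
RT summaries and counted as errors in the accuracy denominator (the
convention is configurable; with near-ceiling accuracy and sub-second RTs
the alternative changes accuracies by well under a point). The cohort test
is the paired Wilcoxon signed-rank on per-participant mean RTs with the
normal approximation: zero differences dropped, mid-ranks with the tie
variance correction, no continuity correction, effect size r = Z/√n. For 53
pairs with all-positive untied differences this gives W₊ = 1431, Z = 6.33,
r = 0.87 in closed form; with the continuity correction Z still rounds to
6.33 at n = 53, so the choice is immaterial at this cohort size (both are
exposed). The exactness of the implementation is checked against full 2ⁿ
sign enumeration for small n and against `stats::wilcox.test`.

### EEG

Channels with impedance strictly above 30 kΩ are masked. Filtering is a
zero-phase FIR low-pass at 45 Hz (order 100, unity DC gain — the band
starts at 0 Hz, so no high-pass is applied) plus a zero-phase second-order
Butterworth band-stop notch of ±2 Hz around the line frequency. Because the
FIR kernel is symmetric, applying it once and removing the group delay is
exactly zero phase; zero-phase filtering avoids biasing P300 latency.
Epochs span [−0.2, 1.0] s around onset (inclusive endpoints; 301 samples at
250 Hz); any epoch containing a sample beyond ±100 µV is rejected; baseline
correction subtracts the mean over [−0.2, 0) s. Class averages carry
per-sample SEM. The P300 is the maximum of the class-mean waveform in
[250, 400] ms, ties broken to the earliest sample; the same windowed-maximum
rule is applied to both classes.

### fNIRS

Processing order: intensities → optical density (ΔOD = −log(I/I₀), with I₀
the per-channel temporal mean; configurable to the first baseline) → scalp
coupling index mask → motion correction → modified Beer-Lambert → 0.08 Hz
low-pass → short-channel regression → event-locked epoching.

The scalp coupling index is the zero-lag Pearson correlation of the two
wavelengths' cardiac-band (0.5–2.5 Hz band-pass, order-3 Butterworth,
zero-phase) normalized intensities, computed after discarding 5 s edge
transients; channels below 0.4 (strictly) are masked, and zero-variance
channels are masked with an explicit reason.

Motion correction has two stages. Baseline step shifts are detected on the
first difference (|Δ| > 8 robust SDs) and re-leveled using spline-smoothed
estimates of the local baseline on each side of the shift; the level
estimator winsorizes its window at ±5 MADs so a spike cannot masquerade as a
shift. Re-leveling runs *before* wavelet despiking: the Haar transform
would otherwise smear a sharp step across a coarse coefficient block and
hide it from the detector. Despiking then zeroes Haar detail coefficients
outside the Tukey fences (1.5 × IQR per level, 4 levels) and reconstructs;
a single-sample spike loses a factor ~2 per level, i.e. ~94% at the default
depth.

The physiological low-pass is a linear-phase FIR (Hamming design, order
2·round(1.65·rate/(1.25·cutoff)) ≈ 330 at 10 Hz), normalized to exact unity
DC gain and applied zero-phase; its measured response leaves 0.01 Hz signals
within ±0.1% and attenuates 0.25 Hz (respiration) and 1.2 Hz (cardiac) by
more than 50 dB. The modified Beer-Lambert inversion solves the per-channel
2×2 system with compiled literature extinction coefficients (760 nm: 0.586 /
1.5485; 850 nm: 1.058 / 0.6913 mM⁻¹cm⁻¹ for HbO/HbR) and a differential
pathlength factor of 6.0 at both wavelengths — the study cites published
coefficients without printing numbers, so these values are the package's
documented choice. Short-channel regression removes, per long channel, the
ordinary-least-squares fit of its region's short channel (plus intercept);
an OLS residual never has more variance than the intercept-only fit, which
the tests assert. HbO epochs span [−1, 20] s with the [−1, 0) s mean
subtracted.

Because the ISI (2 s) is much shorter than the 20 s epoch, consecutive
epochs overlap heavily by design; the class mean is an *event-locked
average*, not a deconvolved response. Responses from neighboring stimuli
(and the previous target's undershoot) contaminate the tails; baseline
subtraction removes the constant part of that contamination, and with
standards carrying no response the target-vs-standard contrast remains
interpretable. This mirrors the abbreviated protocol's own analysis and is
a documented limitation, not an estimation error.

### Group level

Nine EEG ROIs and six fNIRS ROIs group the channels; midline ROIs exist for
EEG only, and the Cz midline is addressable both as "temporal midline" and
"central midline" because the source protocol uses both names. The
published channel-to-ROI table contains malformed run-together strings; the
shipped map is a best-effort tokenization, flagged in a data comment.
Grand averages are computed over participant ROI (or channel) means — not
pooled trials — with across-participant SEM. A participant is dropped from
a modality when more than half of that modality's channels are invalid; the
threshold is configurable, since the original exclusion rule ("poor
impedance") was not quantified. All exclusions are logged in the report.

## Reproducibility and problem sizes

A single master seed drives everything: participant i's profile uses
`child_seed(master, i)`, and that seed fans out again to the schedule,
marker, EEG, and fNIRS generators, so any participant can be regenerated in
isolation. `run_replication()` processes participants one at a time and
keeps only summaries, so memory stays flat in the cohort size.

The package's own validation runs use a 53-participant cohort (the study's
analyzed size) for the end-to-end replication, and pool three independently
seeded 53-participant cohorts for P300 parameter-recovery checks: with ~8
target trials per 4-minute run, a single cohort estimates the target P300
amplitude with a standard error near 8%, too coarse to judge a ±10%
calibration tolerance, while the pooled 159 participants bring it near 5%.
The short task is also why grand-average ERPs look jagged at realistic
noise — the abbreviated protocol yields roughly a fifth of the trials of a
conventional 20-minute oddball run, a property the synthetic data
reproduces faithfully.

## What passing tests do and do not show

The generator produces data with the *statistical structure the analyses
assume*: lognormal RTs, a single Gaussian P300 on a midline gradient,
canonical HRFs in a single ROI, sinusoidal systemics, shared-skin short
channels, and idealized spike/step motion artifacts. Real recordings
violate most of these idealizations — ERPs have multiple components and
inter-trial latency variability beyond a Gaussian jitter, hemodynamics vary
regionally, systemic physiology is nonstationary, and motion artifacts have
richer morphology. Green tests therefore demonstrate that the pipeline
correctly recovers known ground truth under its own model class and exact
forward/inverse consistency (e.g. the Beer-Lambert round trip at <10⁻⁹
relative error); they do not certify performance on human data.
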