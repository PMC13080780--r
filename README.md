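# oddballkit

Simulation and analysis of a mobile visual-oddball experiment with
simultaneous EEG and fNIRS recording.

## The scientific problem

A visual oddball task interleaves rare **target** stimuli among frequent
**standards**. In healthy adults it produces three robust cohort-level
signatures:

* **Behavior** — slower reaction times (RT) to targets than to standards,
  tested with the paired Wilcoxon signed-rank statistic
  *Z = (W₊ − n(n+1)/4) / √(n(n+1)(2n+1)/24)* and effect size *r = Z/√n*;
* **EEG** — a larger P300, the positive event-related potential (ERP)
  deflection in the 250–400 ms post-stimulus window, over midline
  central/parietal channels (Cz, Pz);
* **fNIRS** — an oxygenated-hemoglobin (HbO) increase over right prefrontal
  cortex, peaking ~9 s after the stimulus, obtained from two-wavelength
  intensities via the modified Beer-Lambert law
  *ΔOD(λ) = [ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR]·d·DPF(λ)* after
  scalp-coupling-index channel pruning, wavelet/spline motion correction, a
  0.08 Hz low-pass, and short-channel regression of scalp artifacts.

An abbreviated (4-minute) mobile version of the task reproduces all three
effects. `oddballkit` re-implements that validation study as a desk-scale
synthetic experiment for pipeline developers and methods researchers: a
task-event engine with the protocol's timing constraints (2 s ISI, 0.5 s
stimuli, 7–21 standards between targets, 10 s baselines), a generative
participant model (lognormal RTs, Gaussian-bump P300 topography, canonical
double-gamma HRF, systemic/skin/motion artifacts), and the full analysis
chain from raw arrays to a cohort report.

## Worked example

Simulate and analyze a small cohort end to end:

```r
library(oddballkit)
cfg <- run_config(n_participants = 6, seed = 11)
rep <- run_replication(cfg)
print(rep)
#> <cohort_report> n = 6 participants
#>   RT: target 724 (SD 84) ms vs standard 528 (SD 26) ms
#>   Accuracy: target 95.83%, standard 99.41%
#>   Wilcoxon: Z = 2.20, p = 0.0277, r = 0.90 (n = 6)
#>   P300 peaks (grand average):
#>     Cz target    2.059 uV at 336 ms
#>     Cz standard  0.751 uV at 380 ms
#>     Pz target    3.466 uV at 312 ms
#>     Pz standard  1.055 uV at 268 ms
#>   HbO (frontal_right ROI): target peak 0.146 uM at 9.6 s
```

Reading the output: all six simulated participants respond ~200 ms slower
to targets (Wilcoxon Z = 2.20 — at n = 6 the normal approximation is coarse,
but the effect direction is unanimous, hence r ≈ 0.9); the grand-average
P300 is larger for targets than standards at both midline channels (at this
cohort size the peak estimates are noisy — the 4-minute task yields only ~8
target trials per participant); and the right-frontal HbO event-locked
average peaks near the configured 9 s for targets only. With the default
53-participant cohort the report reproduces the closed-form Z = 6.33,
r = 0.87 (all differences positive) and P300/HbO contrasts at the
configured amplitudes.

Individual stages are exposed directly, e.g.:

```r
sched <- generate_oddball_schedule(task_config(), seed = 7)  # 120 events
prof  <- participant_profile()
eeg   <- simulate_eeg(sched, prof, noise_model(), seed = 1)
res   <- analyze_eeg(eeg, sched$events)
extract_p300(res$erp$target, "Cz")   # latency (ms) and amplitude (uV)
```

## Package layout

* `R/task_engine.R` — schedules, event streams, validation
* `R/synthetic_participant.R` — behavioral/EEG/fNIRS generators, cohorts
* `R/behavioral.R` — trial matching, summaries, Wilcoxon signed-rank
* `R/eeg_pipeline.R` — impedance masks, filtering, epoching, P300
* `R/fnirs_pipeline.R` — SCI, motion correction, MBLL, short-channel
  regression, HbO epochs
* `R/group_level.R` — ROI maps, grand averages, cohort report
* `R/run_config.R`, `R/run_replication.R` — configuration and the
  one-command replication
* `vignettes/oddball-validation.Rmd` — the methods vignette (models,
  parameter choices, numerical details, limitations)
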