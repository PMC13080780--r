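quiet_noise <- function(...) {
  noise_model(eeg_background_sd = 0, eeg_line_amp = 0, eeg_outlier_rate = 0,
              systemic_amps = c(cardiac = 0, resp = 0, mayer = 0),
              skin_amp = 0, od_noise_sd = 0, motion_spike_rate = 0,
              motion_shift_rate = 0, bad_channel_fraction_eeg = 0,
              bad_channel_fraction_fnirs = 0, ...)
}

test_that("EEG recording covers baselines + task at the sampling rate", {
  sched <- generate_oddball_schedule(task_config(), seed = 2)
  eeg <- simulate_eeg(sched, participant_profile(), quiet_noise(), seed = 1)
  expect_equal(ncol(eeg$samples), 250 * (10 + 240 + 10))
  expect_equal(nrow(eeg$samples), 32)
  expect_setequal(eeg$labels, eeg_channels())
})

test_that("zero noise and zero ERP amplitudes give an all-zero recording", {
  sched <- toy_schedule(c("standard", "target", "standard"))
  p <- participant_profile(p300_amp_target = 0, p300_amp_standard = 0)
  p$erp_table$amplitude <- 0
  eeg <- simulate_eeg(sched, p, quiet_noise(), seed = 1)
  expect_true(all(eeg$samples == 0))
})

test_that("noise-free forward ERP equals the extraction oracle at Cz", {
  sched <- toy_schedule(c("standard", "target", "standard"),
                        isi = 4, baseline = 10)
  p <- participant_profile()
  eeg <- simulate_eeg(sched, p, quiet_noise(), seed = 1)
  ep <- baseline_correct(epoch_eeg(eeg, sched$events))
  erp <- average_erp(ep, "target")
  pk <- extract_p300(erp, "Cz")
  expect_equal(pk$amplitude, 3.5397, tolerance = 1e-6)
  expect_equal(pk$latency_ms, 356)
})

test_that("EEG generation is linear in the ERP amplitudes", {
  sched <- toy_schedule(c("target", "standard", "target"))
  nm <- noise_model(bad_channel_fraction_eeg = 0)
  base <- participant_profile()
  scaled <- function(f) {
    p <- base
    p$erp_table$amplitude <- base$erp_table$amplitude * f
    p
  }
  out <- lapply(list(scaled(0), scaled(0.5), scaled(1), scaled(1.5)),
                function(p) simulate_eeg(sched, p, nm, seed = 6)$samples)
  expect_equal(out[[4]] + out[[1]], out[[2]] + out[[3]], tolerance = 1e-10)
})

test_that("extracted P300 amplitude increases with the configured amplitude", {
  sched <- generate_oddball_schedule(task_config(task_duration = 120),
                                     seed = 9)
  nm <- noise_model(eeg_background_sd = 2, bad_channel_fraction_eeg = 0,
                    eeg_outlier_rate = 0)
  amps <- c(1, 3, 6)
  got <- vapply(amps, function(a) {
    p <- participant_profile(p300_amp_target = a)
    eeg <- simulate_eeg(sched, p, nm, seed = 11)
    ep <- baseline_correct(epoch_eeg(preprocess_eeg(eeg), sched$events))
    extract_p300(average_erp(ep, "target"), "Cz")$amplitude
  }, 0)
  expect_true(all(diff(got) > 0))
})

test_that("hemodynamic response function peaks at the configured time", {
  t <- seq(0, 40, by = 0.1)
  h <- hrf_double_gamma(t, peak_time = 9)
  expect_equal(t[which.max(h)], 9, tolerance = 0.11)
  expect_equal(max(h), 1)
  h5 <- hrf_double_gamma(t, peak_time = 5)
  expect_equal(t[which.max(h5)], 5, tolerance = 0.11)
  # undershoot follows the peak
  expect_lt(min(h[t > 9]), 0)
})

test_that("noise-free fNIRS intensities invert exactly through the MBLL", {
  sched <- toy_schedule(c(rep("standard", 9), "target", rep("standard", 10)))
  p <- participant_profile(hbo_amp_target = 0.5)
  raw <- simulate_fnirs(sched, p, quiet_noise(), seed = 3)
  expect_true(all(raw$intensities > 0))
  hemo <- mbll(optical_density(raw))
  # right-frontal long channels carry the response; compare mean-centered
  # signals (the OD reference folds any constant into the baseline)
  g <- raw$geometry
  rf <- which(!g$is_short & g$region == "frontal_right")[1]
  kern_resp <- hemo$hbo[rf, ]
  n <- length(kern_resp)
  train <- numeric(n)
  train[round(sched$events$onset * 10) + 1] <-
    ifelse(sched$events$class == "target", 0.5, 0)
  kern <- hrf_double_gamma((seq_len(ceiling(32 * 9 / 5 * 10)) - 1) / 10, 9)
  truth <- stats::convolve(train, rev(kern), type = "open")[seq_len(n)]
  err <- (kern_resp - mean(kern_resp)) - (truth - mean(truth))
  expect_lt(max(abs(err)) / max(abs(truth)), 1e-9)
  # channels outside the response ROI and short channels stay flat
  other <- which(!g$is_short & g$region != "frontal_right")[1]
  expect_lt(stats::sd(hemo$hbo[other, ]), 1e-12)
  short <- which(g$is_short)[1]
  expect_lt(stats::sd(hemo$hbo[short, ]), 1e-12)
})

test_that("zero-amplitude noise-free fNIRS is constant with zero MBLL output", {
  sched <- toy_schedule(c("standard", "target"))
  p <- participant_profile(hbo_amp_target = 0, hbo_amp_standard = 0)
  raw <- simulate_fnirs(sched, p, quiet_noise(), seed = 5)
  # constant over time per channel/wavelength (channel gains differ)
  tvar <- apply(raw$intensities, c(1, 2), function(x) max(x) - min(x))
  expect_true(all(tvar < 1e-12))
  hemo <- mbll(optical_density(raw))
  expect_lt(max(abs(hemo$hbo)), 1e-12)
  expect_lt(max(abs(hemo$hbr)), 1e-12)
})

test_that("cohorts are reproducible and write one directory per participant", {
  out <- tempfile()
  res <- simulate_cohort(1, config = task_config(task_duration = 20,
                                                 gap_min = 2, gap_max = 5),
                         seed = 77, out_dir = out)
  d <- res$participants[[1]]$dir
  expect_setequal(list.files(d), c("events.jsonl", "eeg.bin", "eeg.json",
                                   "fnirs.bin", "fnirs.json"))
  a <- simulate_cohort(2, config = task_config(task_duration = 20,
                                               gap_min = 2, gap_max = 5),
                       seed = 5, modalities = "events")
  b <- simulate_cohort(2, config = task_config(task_duration = 20,
                                               gap_min = 2, gap_max = 5),
                       seed = 5, modalities = "events")
  expect_identical(a$participants[[2]]$streams, b$participants[[2]]$streams)
  unlink(out, recursive = TRUE)
})

test_that("every participant of a default cohort shows a positive RT effect", {
  res <- simulate_cohort(53, modalities = "events", seed = 19)
  diffs <- vapply(res$participants, function(pt) {
    tr <- match_responses(pt$streams$stimulus, pt$streams$marker)
    s <- summarize_behavior(tr)
    s$mean_rt[s$class == "target"] - s$mean_rt[s$class == "standard"]
  }, 0)
  expect_length(diffs, 53)
  expect_true(all(diffs > 0))
})
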