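task:
  isi: 2.0
  stim_duration: 0.5
  task_duration: 240.0
  baseline_duration: 10.0
  gap_min: 7
  gap_max: 21
  seed: 1
n_participants: 53
dist:
  rt_standard_between_sd: 30.0
  rt_diff_mean: 176.0
  rt_diff_between_sd: 20.0
  acc_target_between_sd: 0.07412
  acc_standard_between_sd: 0.01447
  erp_amp_between_sd:
    cz_target: 0.6258
    cz_standard: 0.4929
    pz_target: 0.4756
    pz_standard: 0.3637
  erp_latency_between_sd: 8.0
  hbo_amp_between_sd: 0.05
  hrf_peak_between_sd: 0.5
noise:
  eeg_background_sd: 5.0
  eeg_line_freq: 60.0
  eeg_line_amp: 2.0
  eeg_outlier_rate: 0.3
  eeg_outlier_amp: 150.0
  cardiac_freq: 1.2
  resp_freq: 0.25
  mayer_freq: 0.1
  systemic_amps:
    cardiac: 0.8
    resp: 0.3
    mayer: 0.2
  skin_amp: 0.3
  skin_share: 0.8
  od_noise_sd: 0.0002
  motion_spike_rate: 1.0
  motion_spike_amp: 0.05
  motion_shift_rate: 0.3
  motion_shift_amp: 0.02
  bad_channel_fraction_eeg: 0.05
  bad_channel_fraction_fnirs: 0.05
pipeline:
  impedance_threshold: 30.0
  sci_threshold: 0.4
  eeg_lowpass: 45.0
  fnirs_lowpass: 0.08
  erp_window:
  - -0.2
  - 1.0
  p300_window:
  - 250.0
  - 400.0
  hbo_window:
  - -1.0
  - 20.0
  response_floor: 100.0
  artifact_uv: 100.0
  exclusion_threshold: 0.5
seed: 1
output: ~
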