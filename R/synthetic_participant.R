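# Synthetic participant: behavioral responses plus raw EEG and fNIRS
# recordings with the statistical structure the analysis pipeline assumes.

#' Participant response/signal profile
#'
#' Ground-truth parameters of one simulated participant. Reaction-time and
#' accuracy defaults equal the cohort-level values reported for the validated
#' mobile oddball protocol (target RT 718 (SD 148) ms vs standard 542 (SD
#' 122) ms; accuracies 94.58% vs 99.12%), and the event-related potential
#' (ERP) defaults place a P300-like positive peak of 3.5397 uV at 356 ms
#' (target) and 0.74667 uV at 372 ms (standard) on Cz, with corresponding Pz
#' values (2.7219 uV at 296 ms; 0.949 uV at 268 ms).
#'
#' @param rt_mean_target,rt_mean_standard Mean reaction time per class, ms.
#' @param rt_sd_target,rt_sd_standard Trial-to-trial RT standard deviation
#'   per class, ms (lognormal RTs are moment-matched to mean/SD).
#' @param acc_target,acc_standard Probability of a correct button per class.
#' @param p300_amp_target,p300_amp_standard P300 peak amplitude at the peak
#'   channel (Cz), uV.
#' @param p300_latency P300 peak latency at Cz for targets, ms.
#' @param erp_width_ms Gaussian ERP kernel standard deviation, ms (total
#'   kernel width about four times this).
#' @param hbo_amp_target,hbo_amp_standard Event-locked oxygenated-hemoglobin
#'   response amplitude in right-frontal long channels, uM.
#' @param hrf_peak_time Hemodynamic response function peak time, s.
#' @param erp_table Optional data.frame (`channel`, `class`, `amplitude`,
#'   `latency_ms`) overriding the per-channel ERP layout; defaults to
#'   [default_erp_table()] built from the amplitude/latency arguments.
#' @param hbo_weights Optional named vector of per-long-channel weights for
#'   the neural HbO response; defaults to 1 on right-frontal channels, 0
#'   elsewhere.
#' @param seed Integer seed stored with the profile.
#' @return A `participant_profile` list.
#' @export
participant_profile <- function(rt_mean_target = 718, rt_mean_standard = 542,
                                rt_sd_target = 148, rt_sd_standard = 122,
                                acc_target = 0.9458, acc_standard = 0.9912,
                                p300_amp_target = 3.5397,
                                p300_amp_standard = 0.74667,
                                p300_latency = 356, erp_width_ms = 50,
                                hbo_amp_target = 0.2, hbo_amp_standard = 0,
                                hrf_peak_time = 9.0,
                                erp_table = NULL, hbo_weights = NULL,
                                seed = 1L) {
  for (f in c("rt_sd_target", "rt_sd_standard"))
    check_scalar_num(get(f), f, positive = TRUE)
  for (f in c("acc_target", "acc_standard"))
    check_scalar_num(get(f), f, min = 0, max = 1)
  for (f in c("p300_amp_target", "p300_amp_standard", "hbo_amp_target",
              "hbo_amp_standard", "p300_latency", "hrf_peak_time"))
    check_scalar_num(get(f), f)
  p <- structure(list(rt_mean_target = rt_mean_target,
                      rt_mean_standard = rt_mean_standard,
                      rt_sd_target = rt_sd_target,
                      rt_sd_standard = rt_sd_standard,
                      acc_target = acc_target, acc_standard = acc_standard,
                      p300_amp_target = p300_amp_target,
                      p300_amp_standard = p300_amp_standard,
                      p300_latency = p300_latency,
                      erp_width_ms = erp_width_ms,
                      hbo_amp_target = hbo_amp_target,
                      hbo_amp_standard = hbo_amp_standard,
                      hrf_peak_time = hrf_peak_time,
                      erp_table = erp_table, hbo_weights = hbo_weights,
                      seed = as.integer(seed)),
                 class = "participant_profile")
  if (is.null(p$erp_table)) p$erp_table <- default_erp_table(p)
  if (is.null(p$hbo_weights)) {
    geom <- fnirs_geometry()
    w <- stats::setNames(rep(0, sum(!geom$is_short)),
                         geom$channel[!geom$is_short])
    w[geom$channel[!geom$is_short & geom$region == "frontal_right"]] <- 1
    p$hbo_weights <- w
  }
  p
}

#' Default per-channel ERP amplitude/latency table
#'
#' Cz is the peak channel; Pz carries the reported parietal-midline values;
#' remaining channels scale the Cz amplitude by an ROI-dependent spatial
#' weight (parietal 0.4, frontal 0.25, temporal 0.15, unassigned 0.1) at the
#' Cz latency, giving a midline-peaked topography.
#'
#' @param profile A `participant_profile` (amplitude/latency fields are
#'   read from it).
#' @return data.frame with columns `channel`, `class`, `amplitude` (uV),
#'   `latency_ms`.
#' @export
default_erp_table <- function(profile) {
  chans <- eeg_channels()
  roi_of <- stats::setNames(rep(names(EEG_ROI_CHANNELS),
                                lengths(EEG_ROI_CHANNELS)),
                            unlist(EEG_ROI_CHANNELS))
  weight <- function(ch) {
    roi <- roi_of[ch]
    if (is.na(roi)) return(0.10)
    switch(sub("_(left|right|midline)$", "", roi),
           parietal = 0.40, frontal = 0.25, temporal = 0.15, 0.10)
  }
  rows <- list()
  for (cls in c("target", "standard")) {
    amp_cz <- if (cls == "target") profile$p300_amp_target else
      profile$p300_amp_standard
    lat_cz <- if (cls == "target") profile$p300_latency else 372
    for (ch in chans) {
      if (ch == "Cz") { amp <- amp_cz; lat <- lat_cz }
      else if (ch == "Pz") {
        amp <- if (cls == "target") 2.7219 else 0.949
        lat <- if (cls == "target") 296 else 268
      } else { amp <- weight(ch) * amp_cz; lat <- lat_cz }
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, class = cls, amplitude = amp, latency_ms = lat,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Noise model for synthetic recordings
#'
#' Magnitudes are package defaults chosen as realistic for research-grade
#' wearable EEG/fNIRS hardware; none are reported values of the validation
#' study (which published no noise figures).
#'
#' @param eeg_background_sd 1/f-shaped EEG background, uV RMS.
#' @param eeg_line_freq,eeg_line_amp Power-line frequency (Hz) and sinusoid
#'   amplitude (uV).
#' @param eeg_outlier_rate,eeg_outlier_amp Rate (events/min) and amplitude
#'   (uV) of large-amplitude EEG outliers (blink/EMG stand-ins) that exercise
#'   epoch rejection.
#' @param cardiac_freq,resp_freq,mayer_freq Systemic oscillation frequencies,
#'   Hz (cardiac, respiratory, Mayer waves).
#' @param systemic_amps Named vector of HbO amplitudes (uM) for components
#'   `cardiac`, `resp`, `mayer`.
#' @param skin_amp Low-frequency scalp (skin) hemodynamic component, uM RMS.
#' @param skin_share Fraction of the paired short channel's skin signal
#'   present in each long channel.
#' @param od_noise_sd White measurement noise added in optical density.
#' @param motion_spike_rate,motion_spike_amp Motion spikes per minute and
#'   their optical-density amplitude.
#' @param motion_shift_rate,motion_shift_amp Baseline step shifts per minute
#'   and their optical-density amplitude.
#' @param bad_channel_fraction_eeg Fraction of EEG channels given >30 kOhm
#'   impedance.
#' @param bad_channel_fraction_fnirs Fraction of fNIRS channels simulated
#'   with broken optode coupling (independent noise per wavelength).
#' @return A `noise_model` list.
#' @export
noise_model <- function(eeg_background_sd = 5, eeg_line_freq = 60,
                        eeg_line_amp = 2, eeg_outlier_rate = 0.3,
                        eeg_outlier_amp = 150,
                        cardiac_freq = 1.2, resp_freq = 0.25,
                        mayer_freq = 0.1,
                        systemic_amps = c(cardiac = 0.8, resp = 0.3,
                                          mayer = 0.2),
                        skin_amp = 0.3, skin_share = 0.8,
                        od_noise_sd = 2e-4,
                        motion_spike_rate = 1, motion_spike_amp = 0.05,
                        motion_shift_rate = 0.3, motion_shift_amp = 0.02,
                        bad_channel_fraction_eeg = 0.05,
                        bad_channel_fraction_fnirs = 0.05) {
  nm <- as.list(environment())
  for (f in c("eeg_background_sd", "eeg_line_amp", "skin_amp", "od_noise_sd",
              "motion_spike_rate", "motion_shift_rate"))
    check_scalar_num(nm[[f]], f, min = 0)
  check_scalar_num(skin_share, "skin_share", min = 0, max = 1)
  structure(nm, class = "noise_model")
}

# Recording duration in seconds (baseline + task + baseline)
run_duration <- function(config) {
  2 * config$baseline_duration + config$task_duration
}

#' Simulate button responses for a schedule
#'
#' For each stimulus the button matches the stimulus class with the class
#' accuracy probability; the reaction time is lognormal, moment-matched to
#' the class mean/SD. Responses that would land at or after the next stimulus
#' onset are truncated to omissions (no marker emitted).
#'
#' @param schedule A `stimulus_schedule`.
#' @param profile A `participant_profile`.
#' @param seed Integer seed (default `profile$seed`).
#' @return data.frame of marker records (`stream`, `timestamp`, `payload`
#'   with `button=` and `rt=` fields), suitable as the `marker` element of an
#'   `event_stream_set`.
#' @export
simulate_responses <- function(schedule, profile, seed = profile$seed) {
  set.seed(as.integer(seed))
  ev <- schedule$events
  isi <- schedule$config$isi
  lp_t <- lognormal_params(profile$rt_mean_target, profile$rt_sd_target)
  lp_s <- lognormal_params(profile$rt_mean_standard, profile$rt_sd_standard)
  out <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    cls <- ev$class[i]
    lp <- if (cls == "target") lp_t else lp_s
    acc <- if (cls == "target") profile$acc_target else profile$acc_standard
    rt <- stats::rlnorm(1, lp$meanlog, lp$sdlog)  # ms
    correct <- stats::runif(1) < acc
    if (rt >= isi * 1000) next  # response after next onset -> omission
    button <- if (correct) cls else setdiff(c("target", "standard"), cls)
    out[[i]] <- data.frame(
      stream = "marker", timestamp = ev$onset[i] + rt / 1000,
      payload = sprintf("button=%s;rt=%.6f", button, rt),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(stream = character(0), timestamp = numeric(0),
                      payload = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$timestamp), , drop = FALSE]
}

#' Raw EEG container
#' @param samples Channels x time matrix, uV.
#' @param rate Sampling rate, Hz.
#' @param labels Channel labels (length `nrow(samples)`).
#' @param impedances Per-channel electrode impedance, kOhm.
#' @return A `raw_eeg` object.
#' @export
raw_eeg <- function(samples, rate, labels, impedances) {
  stopifnot(is.matrix(samples), nrow(samples) == length(labels),
            length(impedances) == length(labels), all(is.finite(samples)))
  structure(list(samples = samples, rate = rate, labels = labels,
                 impedances = impedances),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$rate))
  invisible(x)
}

#' Raw fNIRS container
#' @param intensities Array `[channel, wavelength, time]` of strictly
#'   positive light intensities (arbitrary units).
#' @param rate Sampling rate, Hz.
#' @param geometry Channel geometry data.frame as from [fnirs_geometry()].
#' @param wavelengths The two wavelengths, nm.
#' @return A `raw_fnirs` object.
#' @export
raw_fnirs <- function(intensities, rate, geometry, wavelengths = c(760, 850)) {
  stopifnot(length(dim(intensities)) == 3L, dim(intensities)[2] == 2L,
            dim(intensities)[1] == nrow(geometry), all(intensities > 0))
  structure(list(intensities = intensities, rate = rate, geometry = geometry,
                 wavelengths = wavelengths),
            class = "raw_fnirs")
}

#' @export
print.raw_fnirs <- function(x, ...) {
  cat(sprintf("<raw_fnirs> %d channels (%d short) x 2 wavelengths x %d samples @ %g Hz\n",
              dim(x$intensities)[1], sum(x$geometry$is_short),
              dim(x$intensities)[3], x$rate))
  invisible(x)
}

# 1/f-shaped Gaussian noise scaled to the requested SD. The spectrum is
# pink above `f_floor` Hz and flat below it, approximating AC-coupled EEG
# hardware whose power does not diverge toward DC.
pink_noise <- function(n, sd, rate = 250, f_floor = 1) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (n < 4) return(w * sd)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))  # avoid zero at DC
  k <- pmin(k, n - k + 1)
  f <- k * rate / n
  shape <- 1 / sqrt(pmax(f, f_floor))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Simulate a raw EEG recording for a schedule
#'
#' The recording is a linear superposition of 1/f-shaped Gaussian background,
#' a power-line sinusoid, occasional large-amplitude outliers, and one
#' Gaussian-bump ERP kernel per stimulus, projected on channels via the
#' profile's ERP table (midline-peaked by default).
#'
#' @param schedule A `stimulus_schedule`.
#' @param profile A `participant_profile`.
#' @param noise A `noise_model`.
#' @param rate Sampling rate, Hz (default 250).
#' @param seed Integer seed (default `profile$seed`).
#' @return A `raw_eeg` covering baseline + task + baseline.
#' @export
simulate_eeg <- function(schedule, profile, noise = noise_model(),
                         rate = 250, seed = profile$seed) {
  set.seed(as.integer(seed))
  cfg <- schedule$config
  if (noise$eeg_line_freq >= rate / 2)
    stop("line frequency must be below the EEG Nyquist", call. = FALSE)
  dur <- run_duration(cfg)
  n <- round(dur * rate)
  labels <- eeg_channels()
  nch <- length(labels)
  samples <- matrix(0, nch, n)
  t_idx <- (seq_len(n) - 1) / rate
  for (c in seq_len(nch)) {
    bg <- pink_noise(n, noise$eeg_background_sd, rate)
    line <- if (noise$eeg_line_amp > 0)
      noise$eeg_line_amp * sin(2 * pi * noise$eeg_line_freq * t_idx +
                                 stats::runif(1, 0, 2 * pi))
    else { stats::runif(1); numeric(n) }
    samples[c, ] <- bg + line
  }
  # amplitude outliers (blink/EMG stand-ins): short bursts on one channel
  n_out <- stats::rpois(1, noise$eeg_outlier_rate * dur / 60)
  if (n_out > 0) {
    for (k in seq_len(n_out)) {
      ch <- sample.int(nch, 1)
      at <- sample.int(n - 10L, 1)
      amp <- sample(c(-1, 1), 1) * noise$eeg_outlier_amp
      burst <- amp * exp(-((0:9) - 4)^2 / 8)
      samples[ch, at:(at + 9L)] <- samples[ch, at:(at + 9L)] + burst
    }
  }
  # ERP kernels (deterministic; added after all RNG so that amplitude
  # settings never change the noise draw)
  sigma <- profile$erp_width_ms / 1000
  et <- profile$erp_table
  ev <- schedule$events
  onset_idx <- round(ev$onset * rate)  # 0-based sample of onset
  for (r in seq_len(nrow(et))) {
    amp <- et$amplitude[r]
    if (amp == 0) next
    ch <- match(et$channel[r], labels)
    if (is.na(ch)) next
    lat <- et$latency_ms[r] / 1000
    k0 <- floor((lat - 4 * sigma) * rate)
    k1 <- ceiling((lat + 4 * sigma) * rate)
    kern <- amp * exp(-((k0:k1) / rate - lat)^2 / (2 * sigma^2))
    for (i in which(ev$class == et$class[r])) {
      idx <- onset_idx[i] + (k0:k1) + 1L
      ok <- idx >= 1L & idx <= n
      samples[ch, idx[ok]] <- samples[ch, idx[ok]] + kern[ok]
    }
  }
  imped <- exp(stats::rnorm(nch, log(10), 0.35))
  bad <- stats::runif(nch) < noise$bad_channel_fraction_eeg
  imped[bad] <- stats::runif(sum(bad), 35, 80)
  raw_eeg(samples, rate, labels, imped)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (shape 6 and 16, unit rate, undershoot
#' ratio 1/6) with the time axis scaled so the positive peak falls at
#' `peak_time`; normalized to a maximum of 1.
#'
#' @param t Time points, s (>= 0).
#' @param peak_time Peak time, s.
#' @return Numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak_time = 9.0) {
  s <- 5 / peak_time  # canonical peak sits at 5 s
  ts <- t * s
  h <- stats::dgamma(ts, shape = 6, rate = 1) -
    stats::dgamma(ts, shape = 16, rate = 1) / 6
  h / max(h)
}

# Extinction coefficients, 1/(mM*cm), from standard compiled optical tables
# (rows = wavelengths 760/850 nm, cols = HbO/HbR)
default_extinction <- function(wavelengths = c(760, 850)) {
  tab <- rbind(`760` = c(hbo = 0.5860, hbr = 1.5485),
               `850` = c(hbo = 1.0580, hbr = 0.6913))
  tab[as.character(wavelengths), , drop = FALSE]
}

#' Modified Beer-Lambert parameters
#'
#' @param geometry Channel geometry data.frame ([fnirs_geometry()]).
#' @param wavelengths Two wavelengths, nm.
#' @param extinction 2x2 matrix of extinction coefficients, 1/(mM*cm)
#'   (rows = wavelengths, cols = HbO, HbR).
#' @param dpf Differential pathlength factor per wavelength.
#' @return An `mbll_params` list.
#' @export
mbll_params <- function(geometry, wavelengths = c(760, 850),
                        extinction = default_extinction(wavelengths),
                        dpf = c(6.0, 6.0)) {
  stopifnot(nrow(extinction) == 2L, ncol(extinction) == 2L)
  if (kappa(extinction) >= 100)
    stop("extinction matrix is ill-conditioned (condition number >= 100)",
         call. = FALSE)
  structure(list(geometry = geometry, wavelengths = wavelengths,
                 extinction = unname(as.matrix(extinction)), dpf = dpf),
            class = "mbll_params")
}

# Forward modified Beer-Lambert: concentrations (uM) -> Delta OD
# hbo/hbr: channels x time matrices covering every geometry row
forward_mbll <- function(hbo, hbr, params) {
  eps <- params$extinction
  d_cm <- params$geometry$separation_mm / 10
  od <- array(0, dim = c(nrow(hbo), 2L, ncol(hbo)))
  for (w in 1:2) {
    od[, w, ] <- (eps[w, 1] * hbo + eps[w, 2] * hbr) / 1000 *
      (d_cm * params$dpf[w])
  }
  od
}

#' Simulate a raw fNIRS recording for a schedule
#'
#' Per long channel the neural signal is the profile's HRF convolved with the
#' class-weighted stimulus train (right-frontal weight 1 for targets by
#' default); deoxygenated hemoglobin follows at -1/3 of HbO. Systemic
#' cardiac/respiratory/Mayer oscillations and a low-frequency skin component
#' (shared with the region's short channel at `skin_share`) are added to all
#' channels with volume-type HbR (+0.3 x HbO). Concentrations are converted
#' to two-wavelength intensities through the forward modified Beer-Lambert
#' model, after which optical-density measurement noise, motion spikes, and
#' baseline step shifts are injected.
#'
#' @param schedule A `stimulus_schedule`.
#' @param profile A `participant_profile`.
#' @param noise A `noise_model`.
#' @param rate Sampling rate, Hz (default 10).
#' @param geometry Channel geometry (default [fnirs_geometry()]).
#' @param seed Integer seed (default `profile$seed`).
#' @return A `raw_fnirs` object.
#' @export
simulate_fnirs <- function(schedule, profile, noise = noise_model(),
                           rate = 10, geometry = fnirs_geometry(),
                           seed = profile$seed) {
  set.seed(as.integer(seed))
  cfg <- schedule$config
  for (f in c("cardiac_freq", "resp_freq", "mayer_freq"))
    if (noise[[f]] >= rate / 2)
      stop(sprintf("%s must be below the fNIRS Nyquist", f), call. = FALSE)
  dur <- run_duration(cfg)
  n <- round(dur * rate)
  t_idx <- (seq_len(n) - 1) / rate
  nch <- nrow(geometry)
  ev <- schedule$events

  # neural HbO: HRF convolved with class-weighted impulse train
  kern_len <- ceiling(32 * profile$hrf_peak_time / 5 * rate)
  kern <- hrf_double_gamma((seq_len(kern_len) - 1) / rate,
                           profile$hrf_peak_time)
  neural_resp <- numeric(n)
  train <- numeric(n)
  amp_by_class <- c(target = profile$hbo_amp_target,
                    standard = profile$hbo_amp_standard)
  idx <- round(ev$onset * rate) + 1L
  train[idx] <- amp_by_class[ev$class]
  conv_full <- stats::convolve(train, rev(kern), type = "open")
  neural_resp <- conv_full[seq_len(n)]

  hbo <- matrix(0, nch, n)
  hbr <- matrix(0, nch, n)
  w <- profile$hbo_weights
  long_idx <- which(!geometry$is_short)

  # skin component per short channel (low-frequency smoothed noise)
  skin <- matrix(0, sum(geometry$is_short), n)
  rownames(skin) <- geometry$channel[geometry$is_short]
  if (noise$skin_amp > 0) {
    bf <- signal::butter(2, min(0.05 / (rate / 2), 0.9), type = "low")
    for (s in seq_len(nrow(skin))) {
      x <- signal::filtfilt(bf, stats::rnorm(n))
      skin[s, ] <- x / stats::sd(x) * noise$skin_amp
    }
  } else {
    for (s in seq_len(nrow(skin))) stats::rnorm(n)
  }

  mayer_phase <- stats::runif(1, 0, 2 * pi)
  amps <- noise$systemic_amps
  for (c in seq_len(nch)) {
    sys <- amps[["cardiac"]] *
      sin(2 * pi * noise$cardiac_freq * t_idx + stats::runif(1, 0, 2 * pi)) +
      amps[["resp"]] *
      sin(2 * pi * noise$resp_freq * t_idx + stats::runif(1, 0, 2 * pi)) +
      amps[["mayer"]] * stats::runif(1, 0.5, 1.5) *
      sin(2 * pi * noise$mayer_freq * t_idx + mayer_phase)
    if (geometry$is_short[c]) {
      sk <- skin[geometry$channel[c], ]
    } else {
      pair <- geometry$short_pair[c]
      sk <- if (!is.na(pair) && pair %in% rownames(skin))
        noise$skin_share * skin[pair, ] else numeric(n)
    }
    systemic <- sys + sk
    neural <- if (!geometry$is_short[c]) {
      wc <- if (geometry$channel[c] %in% names(w)) w[[geometry$channel[c]]] else 0
      wc * neural_resp
    } else numeric(n)
    hbo[c, ] <- neural + systemic
    hbr[c, ] <- -neural / 3 + 0.3 * systemic  # volume-type systemic HbR
  }

  params <- mbll_params(geometry)
  od <- forward_mbll(hbo, hbr, params)

  # optical-density measurement noise
  if (noise$od_noise_sd > 0)
    od <- od + array(stats::rnorm(length(od), 0, noise$od_noise_sd), dim(od))

  # motion artifacts: spikes and baseline step shifts (both wavelengths)
  n_spk <- stats::rpois(1, noise$motion_spike_rate * dur / 60)
  for (k in seq_len(n_spk)) {
    ch <- sample.int(nch, 1)
    at <- sample.int(n, 1)
    a <- sample(c(-1, 1), 1) * noise$motion_spike_amp * stats::runif(1, 1, 3)
    od[ch, , at] <- od[ch, , at] + a
  }
  n_shf <- stats::rpois(1, noise$motion_shift_rate * dur / 60)
  for (k in seq_len(n_shf)) {
    ch <- sample.int(nch, 1)
    at <- sample.int(n - 1L, 1)
    a <- sample(c(-1, 1), 1) * noise$motion_shift_amp * stats::runif(1, 1, 3)
    od[ch, , at:n] <- od[ch, , at:n] + a
  }

  # broken-coupling channels: wavelengths carry independent noise only
  bad <- stats::runif(nch) < noise$bad_channel_fraction_fnirs
  for (c in which(bad))
    od[c, , ] <- matrix(stats::rnorm(2 * n, 0, 0.01), 2, n)

  gains <- stats::runif(nch, 0.5, 2)  # per-channel source power / coupling
  intens <- array(0, dim = dim(od))
  for (w2 in 1:2) intens[, w2, ] <- gains * exp(-od[, w2, ])
  raw_fnirs(intens, rate, geometry, params$wavelengths)
}

#' Cohort profile distribution
#'
#' Between-participant variation around the default profile. The
#' standard-class mean RT and the (strictly positive) target-standard RT
#' difference are drawn separately so every participant's true effect has the
#' expected sign; the difference is lognormal, moment-matched to
#' `rt_diff_mean`/`rt_diff_between_sd`. Accuracy SDs default to the
#' cohort-level values reported for the protocol.
#'
#' @param rt_standard_between_sd SD of the standard-class mean RT, ms.
#' @param rt_diff_mean,rt_diff_between_sd Mean/SD of the target-standard RT
#'   difference, ms.
#' @param acc_target_between_sd,acc_standard_between_sd Accuracy SDs
#'   (probability scale).
#' @param erp_amp_between_sd Named vector of amplitude SDs (uV) for the Cz/Pz
#'   rows (`cz_target`, `cz_standard`, `pz_target`, `pz_standard`).
#' @param erp_latency_between_sd Latency jitter SD, ms.
#' @param hbo_amp_between_sd HbO amplitude SD, uM.
#' @param hrf_peak_between_sd HRF peak-time SD, s.
#' @return A `profile_distribution` list.
#' @export
profile_distribution <- function(rt_standard_between_sd = 30,
                                 rt_diff_mean = 176,
                                 rt_diff_between_sd = 20,
                                 acc_target_between_sd = 0.07412,
                                 acc_standard_between_sd = 0.01447,
                                 erp_amp_between_sd = c(cz_target = 0.6258,
                                                        cz_standard = 0.4929,
                                                        pz_target = 0.4756,
                                                        pz_standard = 0.3637),
                                 erp_latency_between_sd = 8,
                                 hbo_amp_between_sd = 0.05,
                                 hrf_peak_between_sd = 0.5) {
  structure(as.list(environment()), class = "profile_distribution")
}

#' Draw per-participant profiles around the defaults
#'
#' @param n Number of participants.
#' @param dist A [profile_distribution()].
#' @param base Base profile whose values are the population means.
#' @param seed Integer seed.
#' @return List of `participant_profile` objects (element `i` carries seed
#'   `child_seed(seed, i)`).
#' @export
sample_cohort_profiles <- function(n, dist = profile_distribution(),
                                   base = participant_profile(),
                                   seed = 1L) {
  set.seed(as.integer(seed))
  lpd <- lognormal_params(dist$rt_diff_mean, max(dist$rt_diff_between_sd,
                                                 1e-6))
  lapply(seq_len(n), function(i) {
    rt_s <- stats::rnorm(1, base$rt_mean_standard, dist$rt_standard_between_sd)
    rt_d <- stats::rlnorm(1, lpd$meanlog, lpd$sdlog)
    acc_t <- min(1, max(0.5, stats::rnorm(1, base$acc_target,
                                          dist$acc_target_between_sd)))
    acc_s <- min(1, max(0.5, stats::rnorm(1, base$acc_standard,
                                          dist$acc_standard_between_sd)))
    amp <- dist$erp_amp_between_sd
    cz_t <- max(0.3, stats::rnorm(1, base$p300_amp_target, amp[["cz_target"]]))
    cz_s <- max(0.05, stats::rnorm(1, base$p300_amp_standard,
                                   amp[["cz_standard"]]))
    pz_t <- max(0.3, stats::rnorm(1, 2.7219, amp[["pz_target"]]))
    pz_s <- max(0.05, stats::rnorm(1, 0.949, amp[["pz_standard"]]))
    lat_jit <- stats::rnorm(4, 0, dist$erp_latency_between_sd)
    hbo_t <- max(0.02, stats::rnorm(1, base$hbo_amp_target,
                                    dist$hbo_amp_between_sd))
    hrf_pk <- max(5, stats::rnorm(1, base$hrf_peak_time,
                                  dist$hrf_peak_between_sd))
    p <- participant_profile(
      rt_mean_target = rt_s + rt_d, rt_mean_standard = rt_s,
      rt_sd_target = base$rt_sd_target, rt_sd_standard = base$rt_sd_standard,
      acc_target = acc_t, acc_standard = acc_s,
      p300_amp_target = cz_t, p300_amp_standard = cz_s,
      p300_latency = base$p300_latency + lat_jit[1],
      erp_width_ms = base$erp_width_ms,
      hbo_amp_target = hbo_t, hbo_amp_standard = base$hbo_amp_standard,
      hrf_peak_time = hrf_pk, seed = child_seed(seed, i))
    et <- p$erp_table
    et$amplitude[et$channel == "Pz" & et$class == "target"] <- pz_t
    et$amplitude[et$channel == "Pz" & et$class == "standard"] <- pz_s
    et$latency_ms[et$channel == "Pz" & et$class == "target"] <- 296 + lat_jit[2]
    et$latency_ms[et$channel == "Pz" & et$class == "standard"] <-
      268 + lat_jit[3]
    et$latency_ms[et$class == "standard" & et$channel != "Pz"] <-
      372 + lat_jit[4]
    p$erp_table <- et
    p
  })
}

#' Simulate a full cohort
#'
#' Draws per-participant profiles, generates each participant's schedule,
#' marker stream, and (optionally) raw EEG/fNIRS recordings. With an output
#' directory, one subdirectory per participant is written holding
#' `events.jsonl`, `eeg.bin`/`eeg.json`, and `fnirs.bin`/`fnirs.json`.
#'
#' @param n_participants Cohort size (>= 1).
#' @param config A [task_config()].
#' @param dist A [profile_distribution()].
#' @param noise A [noise_model()].
#' @param seed Master integer seed; participant `i` uses
#'   `child_seed(seed, i)` throughout, so any participant can be regenerated
#'   alone.
#' @param modalities Subset of `c("events", "eeg", "fnirs")` to simulate.
#' @param out_dir Optional output directory.
#' @return List with `profiles` and `participants` (each a list with
#'   `schedule`, `streams`, and the simulated recordings), invisibly when
#'   `out_dir` is set.
#' @export
simulate_cohort <- function(n_participants, config = task_config(),
                            dist = profile_distribution(),
                            noise = noise_model(), seed = 1L,
                            modalities = c("events", "eeg", "fnirs"),
                            out_dir = NULL) {
  stopifnot(n_participants >= 1)
  profiles <- sample_cohort_profiles(n_participants, dist, seed = seed)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    p <- profiles[[i]]
    sched <- generate_oddball_schedule(config, seed = child_seed(p$seed, 1))
    streams <- schedule_to_event_streams(sched)
    part <- list(schedule = sched)
    if ("events" %in% modalities) {
      streams$marker <- simulate_responses(sched, p,
                                           seed = child_seed(p$seed, 2))
      part$streams <- streams
    }
    if ("eeg" %in% modalities)
      part$eeg <- simulate_eeg(sched, p, noise, seed = child_seed(p$seed, 3))
    if ("fnirs" %in% modalities)
      part$fnirs <- simulate_fnirs(sched, p, noise,
                                   seed = child_seed(p$seed, 4))
    if (!is.null(out_dir)) {
      pdir <- file.path(out_dir, sprintf("participant_%02d", i))
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(part$streams))
        write_event_streams(part$streams, file.path(pdir, "events.jsonl"))
      if (!is.null(part$eeg)) write_raw_eeg(part$eeg, file.path(pdir, "eeg"))
      if (!is.null(part$fnirs))
        write_raw_fnirs(part$fnirs, file.path(pdir, "fnirs"))
      part$dir <- pdir
      part$eeg <- NULL; part$fnirs <- NULL  # keep the on-disk copy only
    }
    participants[[i]] <- part
  }
  res <- list(profiles = profiles, participants = participants)
  if (is.null(out_dir)) res else invisible(res)
}
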