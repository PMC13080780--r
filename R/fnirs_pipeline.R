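# fNIRS pipeline: optical density, scalp-coupling-index pruning, motion
# correction, modified Beer-Lambert conversion, physiological low-pass,
# short-channel regression, and event-locked HbO epoching.

#' Convert raw intensities to optical-density changes
#'
#' Delta OD = -log(I / I0) per channel and wavelength. The reference I0 is
#' the per-channel temporal mean of the full recording by default, or the
#' mean over the first `baseline` seconds.
#'
#' @param raw A `raw_fnirs`.
#' @param baseline `NULL` (full-recording mean) or seconds of initial
#'   baseline to use as I0 reference.
#' @return An `optical_density`: `od` array `[channel, wavelength, time]`,
#'   `rate`, `geometry`, `wavelengths`.
#' @export
optical_density <- function(raw, baseline = NULL) {
  stopifnot(inherits(raw, "raw_fnirs"))
  n <- dim(raw$intensities)[3]
  ref_idx <- if (is.null(baseline)) seq_len(n)
  else seq_len(max(2L, round(baseline * raw$rate)))
  od <- raw$intensities
  nch <- dim(od)[1]
  for (w in 1:2) {
    for (c in seq_len(nch)) {
      i0 <- mean(raw$intensities[c, w, ref_idx])
      od[c, w, ] <- -log(raw$intensities[c, w, ] / i0)
    }
  }
  structure(list(od = od, rate = raw$rate, geometry = raw$geometry,
                 wavelengths = raw$wavelengths),
            class = "optical_density")
}

#' Scalp coupling index and channel mask
#'
#' SCI is the zero-lag Pearson correlation between the two wavelengths'
#' cardiac-band (0.5--2.5 Hz) filtered, normalized intensity signals; a
#' channel is invalid iff SCI < 0.4 (strictly; exactly 0.4 is valid).
#' Zero-variance channels get an undefined SCI and are invalid.
#'
#' @param raw A `raw_fnirs` (at least 10 s long).
#' @param cardiac_band Band-pass edges, Hz.
#' @param threshold Validity threshold (default 0.4).
#' @return List: `sci` (per-channel value, `NA` when undefined) and `mask`
#'   (a `channel_mask` data.frame).
#' @export
scalp_coupling_index <- function(raw, cardiac_band = c(0.5, 2.5),
                                 threshold = 0.4) {
  n <- dim(raw$intensities)[3]
  if (n / raw$rate < 10) stop("recording shorter than 10 s", call. = FALSE)
  nyq <- raw$rate / 2
  bf <- signal::butter(3, pmin(cardiac_band / nyq, 0.98), type = "pass")
  nch <- dim(raw$intensities)[1]
  sci <- rep(NA_real_, nch)
  trim <- seq_len(n)
  edge <- min(round(5 * raw$rate), floor((n - 2) / 3))
  trim <- (edge + 1):(n - edge)  # discard filter edge transients
  for (c in seq_len(nch)) {
    x1 <- raw$intensities[c, 1, ]
    x2 <- raw$intensities[c, 2, ]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) next
    f1 <- signal::filtfilt(bf, x1 / mean(x1) - 1)
    f2 <- signal::filtfilt(bf, x2 / mean(x2) - 1)
    if (stats::sd(f1[trim]) == 0 || stats::sd(f2[trim]) == 0) next
    sci[c] <- stats::cor(f1[trim], f2[trim])
  }
  valid <- !is.na(sci) & sci >= threshold
  reason <- ifelse(is.na(sci), "SCI undefined (zero variance)",
                   ifelse(valid, "",
                          sprintf("SCI %.2f < %g", sci, threshold)))
  mask <- structure(data.frame(channel = raw$geometry$channel, valid = valid,
                               reason = reason, stringsAsFactors = FALSE),
                    class = c("channel_mask", "data.frame"))
  list(sci = stats::setNames(sci, raw$geometry$channel), mask = mask)
}

# Detect baseline step shifts via a robust moving criterion on the first
# difference and re-level the data after each shift using spline-smoothed
# estimates of the local baseline on both sides of the shift. Detection can
# run on a different (e.g. pre-despiking) copy of the signal.
spline_shift_correct <- function(x, rate, k_detect = 8, side_s = 3,
                                 detect_from = x) {
  dx <- diff(detect_from)
  s <- stats::mad(dx)
  if (s == 0) return(x)
  jumps <- which(abs(dx) > k_detect * s)
  if (!length(jumps)) return(x)
  # merge detections closer than 3 samples (a spike shows as two opposite
  # jumps in adjacent samples; treated as one candidate)
  jumps <- jumps[c(TRUE, diff(jumps) > 3)]
  w <- max(8L, round(side_s * rate))
  out <- x
  n <- length(x)
  level_est <- function(idx, at) {
    v <- out[idx]
    # winsorize so a residual spike cannot bias the level estimate
    med <- stats::median(v)
    lim <- 5 * stats::mad(v) + 1e-12
    v <- pmin(pmax(v, med - lim), med + lim)
    if (length(idx) >= 8) {
      fit <- stats::smooth.spline(idx, v, df = min(4, length(idx) - 1))
      stats::predict(fit, at)$y
    } else stats::median(v)
  }
  for (j in jumps) {
    g <- 2L  # guard samples around the detected transition
    pre_idx <- max(1L, j - w):max(1L, j - g)
    post_idx <- min(n, j + 1L + g):min(n, j + 1L + w)
    jump <- level_est(post_idx, j + 1L) - level_est(pre_idx, j)
    if (abs(jump) < 4 * s) next  # not a sustained level shift (e.g. a spike)
    out[(j + 1L):n] <- out[(j + 1L):n] - jump
  }
  out
}

#' Correct motion artifacts in optical density
#'
#' Two stages, per channel and wavelength: spline-based re-leveling of
#' baseline step shifts detected by a robust moving criterion on the first
#' difference (run first -- a sharp step would otherwise be smeared across a
#' coarse wavelet block), followed by wavelet despiking: a discrete Haar
#' decomposition whose detail coefficients beyond `k_iqr` times the
#' interquartile range of their level are zeroed before reconstruction.
#'
#' @param od An `optical_density`.
#' @param levels Wavelet decomposition depth (default 4).
#' @param k_iqr Despiking fence width in IQR units (default 1.5).
#' @param k_detect Step-detection threshold in robust-SD units (default 8).
#' @return A corrected `optical_density`.
#' @export
motion_correct <- function(od, levels = 4, k_iqr = 1.5, k_detect = 8) {
  stopifnot(inherits(od, "optical_density"))
  out <- od
  for (c in seq_len(dim(od$od)[1])) {
    for (w in 1:2) {
      raw_x <- od$od[c, w, ]
      # steps are re-leveled before despiking: the wavelet stage would smear
      # a sharp step across a coarse block, hiding it from the detector; the
      # level estimator is spike-robust, so the order is safe
      x <- spline_shift_correct(raw_x, od$rate, k_detect = k_detect)
      out$od[c, w, ] <- wavelet_despike(x, levels = levels, k = k_iqr)
    }
  }
  out
}

# Zero-phase FIR low-pass kernel for physiological filtering
phys_fir <- function(rate, cutoff, order = NULL) {
  if (is.null(order)) {
    # Hamming-window design, transition width ~3.3/N of fs. A transition of
    # 1.25 x cutoff keeps a flat passband well below the cutoff while the
    # stopband edge lands near 2 x cutoff (>= 20 dB by 0.25 Hz at fs = 10).
    order <- 2 * round(1.65 * rate / (1.25 * cutoff))
    order <- max(order, 64L)
  }
  h <- as.numeric(unclass(signal::fir1(order, cutoff / (rate / 2),
                                       type = "low")))
  h / sum(h)  # exact unity DC gain
}

#' Low-pass filter physiological oscillations
#'
#' Linear-phase FIR applied forward and backward (zero phase), cutoff 0.08 Hz
#' by default, removing cardiac, respiratory, and Mayer-wave oscillations
#' from hemoglobin (or optical-density) time series.
#'
#' @param x A `hemo_timeseries` or `optical_density`.
#' @param cutoff Cutoff frequency, Hz.
#' @param order FIR order; the default targets >= 20 dB attenuation by
#'   0.25 Hz.
#' @return Filtered object of the same class.
#' @export
lowpass_physiological <- function(x, cutoff = 0.08, order = NULL) {
  if (x$rate <= 2 * cutoff)
    stop("sampling rate too low for the requested cutoff", call. = FALSE)
  h <- phys_fir(x$rate, cutoff, order)
  flen <- length(unclass(h))
  apply_ff <- function(v) fir_zerophase(h, v)
  if (inherits(x, "hemo_timeseries")) {
    if (ncol(x$hbo) < 3 * flen)
      stop("recording shorter than 3 filter lengths", call. = FALSE)
    x$hbo <- t(apply(x$hbo, 1, apply_ff))
    x$hbr <- t(apply(x$hbr, 1, apply_ff))
  } else if (inherits(x, "optical_density")) {
    if (dim(x$od)[3] < 3 * flen)
      stop("recording shorter than 3 filter lengths", call. = FALSE)
    for (w in 1:2) x$od[, w, ] <- t(apply(x$od[, w, ], 1, apply_ff))
  } else stop("unsupported input type", call. = FALSE)
  x
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Per channel and sample, solves the 2x2 system
#' \deqn{\Delta OD(\lambda) = [\varepsilon_{HbO}(\lambda)\,\Delta HbO +
#'   \varepsilon_{HbR}(\lambda)\,\Delta HbR] \cdot d \cdot DPF(\lambda)}
#' for (Delta HbO, Delta HbR) in uM, using the shipped extinction
#' coefficients and the channel's source-detector separation.
#'
#' @param od An `optical_density`.
#' @param params An [mbll_params()] (defaults to the od's geometry with
#'   shipped coefficients).
#' @return A `hemo_timeseries`: `hbo`, `hbr` (channels x time, uM), `rate`,
#'   `geometry`.
#' @export
mbll <- function(od, params = mbll_params(od$geometry, od$wavelengths)) {
  eps <- params$extinction
  if (abs(det(eps)) < 1e-12) stop("singular extinction matrix", call. = FALSE)
  inv <- solve(eps)
  d_cm <- od$geometry$separation_mm / 10
  nch <- dim(od$od)[1]
  n <- dim(od$od)[3]
  hbo <- matrix(0, nch, n)
  hbr <- matrix(0, nch, n)
  for (c in seq_len(nch)) {
    rhs <- rbind(od$od[c, 1, ] / (d_cm[c] * params$dpf[1]),
                 od$od[c, 2, ] / (d_cm[c] * params$dpf[2]))
    conc <- inv %*% rhs * 1000  # mM -> uM
    hbo[c, ] <- conc[1, ]
    hbr[c, ] <- conc[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, rate = od$rate,
                 geometry = od$geometry),
            class = "hemo_timeseries")
}

#' Regress short-channel (scalp) signals out of long channels
#'
#' Per long channel, an ordinary least-squares fit of the paired short
#' channel (plus intercept) is removed; the residual is the corrected
#' cortical signal. Pairing follows `geometry$short_pair`; when a paired
#' short channel is invalid, the first valid short channel substitutes. If no
#' valid short channel exists the input passes through with a
#' `scr_skipped` attribute set.
#'
#' @param hemo A `hemo_timeseries` containing both long and short channels.
#' @param short_mask Optional `channel_mask` restricting which short channels
#'   may serve as regressors.
#' @return A `hemo_timeseries` holding the corrected long channels only
#'   (geometry subset accordingly).
#' @export
short_channel_regression <- function(hemo, short_mask = NULL) {
  g <- hemo$geometry
  short_idx <- which(g$is_short)
  ok <- rep(TRUE, length(short_idx))
  if (!is.null(short_mask)) {
    v <- stats::setNames(short_mask$valid, short_mask$channel)
    ok <- v[g$channel[short_idx]]
    ok[is.na(ok)] <- FALSE
  }
  valid_short <- short_idx[ok]
  long_idx <- which(!g$is_short)
  out_hbo <- hemo$hbo[long_idx, , drop = FALSE]
  out_hbr <- hemo$hbr[long_idx, , drop = FALSE]
  skipped <- FALSE
  if (!length(valid_short)) {
    warning("no valid short channels: skin regression skipped")
    skipped <- TRUE
  } else {
    for (j in seq_along(long_idx)) {
      li <- long_idx[j]
      pair <- g$short_pair[li]
      si <- short_idx[match(pair, g$channel[short_idx])]
      if (is.na(si) || !(si %in% valid_short)) si <- valid_short[1]
      for (comp in c("hbo", "hbr")) {
        ycur <- hemo[[comp]][li, ]
        xcur <- hemo[[comp]][si, ]
        X <- cbind(1, xcur)
        fit <- stats::lm.fit(X, ycur)
        if (comp == "hbo") out_hbo[j, ] <- fit$residuals
        else out_hbr[j, ] <- fit$residuals
      }
    }
  }
  structure(list(hbo = out_hbo, hbr = out_hbr, rate = hemo$rate,
                 geometry = g[long_idx, , drop = FALSE],
                 scr_skipped = skipped),
            class = "hemo_timeseries")
}

#' Event-locked HbO epoch averages
#'
#' Extracts `window` (default [-1, 20] s, inclusive endpoints) epochs around
#' each stimulus onset, subtracts the [-1, 0) s prestimulus mean per epoch
#' and channel, and averages within class. Consecutive epochs overlap by
#' design (the ISI is shorter than the window); the class mean is an
#' event-locked average, not a deconvolved response. Events whose window
#' leaves the recording are dropped with a warning.
#'
#' @param hemo A `hemo_timeseries` (long channels).
#' @param events Stimulus events data.frame (`onset`, `class`).
#' @param window Epoch window, s.
#' @return A `hemo_epoch_result`: per class, `mean`/`sem` (channels x
#'   samples, uM), plus `times`, `channels`, `n_events`, and per-class
#'   peak value/time of the channel-mean waveform.
#' @export
epoch_hbo <- function(hemo, events, window = c(-1, 20)) {
  rate <- hemo$rate
  k0 <- round(window[1] * rate)
  k1 <- round(window[2] * rate)
  n <- ncol(hemo$hbo)
  onset_idx <- round(events$onset * rate) + 1L
  keep <- onset_idx + k0 >= 1L & onset_idx + k1 <= n
  if (any(!keep))
    warning(sprintf("%d event(s) too close to the recording edge dropped",
                    sum(!keep)))
  times <- (k0:k1) / rate
  pre <- which(times < 0)
  classes <- c("target", "standard")
  res <- list()
  for (cls in classes) {
    idx <- which(keep & events$class == cls)
    if (!length(idx)) next
    nch <- nrow(hemo$hbo)
    acc <- array(0, dim = c(length(idx), nch, length(times)))
    for (j in seq_along(idx)) {
      sl <- (onset_idx[idx[j]] + k0):(onset_idx[idx[j]] + k1)
      ep <- hemo$hbo[, sl, drop = FALSE]
      ep <- ep - rowMeans(ep[, pre, drop = FALSE])
      acc[j, , ] <- ep
    }
    st <- trialwise_stats(acc)
    m <- st$mean
    s <- st$sd / sqrt(length(idx))
    cm <- colMeans(m)  # channel-mean waveform
    pk <- which.max(cm)
    res[[cls]] <- list(mean = m, sem = s, n_events = length(idx),
                       peak_value = cm[pk], peak_time = times[pk])
  }
  structure(c(res, list(times = times, channels = hemo$geometry$channel,
                        rate = rate)),
            class = "hemo_epoch_result")
}

#' Run the complete single-participant fNIRS analysis
#'
#' Processing order: intensities -> optical density -> SCI mask -> wavelet +
#' spline motion correction -> modified Beer-Lambert -> 0.08 Hz low-pass ->
#' short-channel regression -> event-locked epoching.
#'
#' @param raw A `raw_fnirs`.
#' @param events Stimulus events data.frame (`onset`, `class`).
#' @param window Epoch window, s.
#' @param lowpass_cutoff Physiological low-pass cutoff, Hz.
#' @param sci_threshold Scalp-coupling-index validity threshold.
#' @return List: `mask` (SCI channel mask), `sci`, `epochs` (a
#'   `hemo_epoch_result` over long channels), `hemo` (corrected long-channel
#'   `hemo_timeseries`).
#' @export
analyze_fnirs <- function(raw, events, window = c(-1, 20),
                          lowpass_cutoff = 0.08, sci_threshold = 0.4) {
  sci <- scalp_coupling_index(raw, threshold = sci_threshold)
  od <- optical_density(raw)
  od <- motion_correct(od)
  hemo <- mbll(od)
  hemo <- lowpass_physiological(hemo, cutoff = lowpass_cutoff)
  short_mask <- sci$mask[raw$geometry$is_short, , drop = FALSE]
  hemo <- short_channel_regression(hemo, short_mask)
  ep <- epoch_hbo(hemo, events, window)
  list(mask = sci$mask, sci = sci$sci, epochs = ep, hemo = hemo)
}
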