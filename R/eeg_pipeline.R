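# EEG pipeline: channel validity, zero-phase filtering, epoching, baseline
# correction, trial averaging, and P300 extraction.

#' Mark EEG channels invalid by impedance
#'
#' A channel is invalid iff its electrode impedance strictly exceeds 30 kOhm
#' (exactly 30 is valid).
#'
#' @param impedances Per-channel impedance, kOhm (finite, non-negative).
#' @param labels Optional channel labels.
#' @param threshold Impedance threshold, kOhm (default 30).
#' @return A `channel_mask` data.frame: `channel`, `valid`, `reason`.
#' @export
validate_channels_eeg <- function(impedances, labels = NULL, threshold = 30) {
  stopifnot(all(is.finite(impedances)), all(impedances >= 0))
  if (is.null(labels)) labels <- paste0("ch", seq_along(impedances))
  valid <- impedances <= threshold
  structure(data.frame(
    channel = labels, valid = valid,
    reason = ifelse(valid, "",
                    sprintf("impedance %.1f kOhm > %g kOhm", impedances,
                            threshold)),
    stringsAsFactors = FALSE), class = c("channel_mask", "data.frame"))
}

#' Filter a raw EEG recording (zero-phase low-pass + line notch)
#'
#' Applies a zero-phase FIR low-pass at `lowpass` Hz (DC retained -- the
#' passband starts at 0 Hz) and a zero-phase Butterworth band-stop notch
#' around the power-line frequency. Samples whose filtered absolute amplitude
#' exceeds `artifact_uv` are recorded in the `artifacts` element (per-channel
#' sample indices) for later epoch rejection.
#'
#' @param raw A `raw_eeg`.
#' @param lowpass Low-pass cutoff, Hz (default 45).
#' @param line_freq Notch center, Hz (default 60); `NA` disables the notch.
#' @param artifact_uv Amplitude-artifact threshold, uV (default 100).
#' @param fir_order Low-pass FIR order (default 100).
#' @return A filtered `raw_eeg` with an `artifacts` element.
#' @export
preprocess_eeg <- function(raw, lowpass = 45, line_freq = 60,
                           artifact_uv = 100, fir_order = 100) {
  stopifnot(inherits(raw, "raw_eeg"))
  if (raw$rate <= 2 * lowpass)
    stop("sampling rate too low for the requested passband", call. = FALSE)
  h <- as.numeric(unclass(signal::fir1(fir_order, lowpass / (raw$rate / 2),
                                       type = "low")))
  h <- h / sum(h)  # exact unity DC gain (the passband starts at 0 Hz)
  notch <- if (!is.na(line_freq))
    signal::butter(2, c(line_freq - 2, line_freq + 2) / (raw$rate / 2),
                   type = "stop")
  else NULL
  out <- raw
  for (c in seq_len(nrow(raw$samples))) {
    x <- fir_zerophase(h, raw$samples[c, ])
    if (!is.null(notch)) x <- signal::filtfilt(notch, x)
    out$samples[c, ] <- x
  }
  out$artifacts <- lapply(seq_len(nrow(out$samples)),
                          function(c) which(abs(out$samples[c, ]) > artifact_uv))
  out
}

#' Extract stimulus-locked EEG epochs
#'
#' One epoch per stimulus event over `window` (default [-0.2, 1.0] s around
#' onset, inclusive endpoints: `round(1.2 * rate) + 1` samples). Epochs
#' containing any marked artifact sample on any channel are rejected; events
#' whose window leaves the recording are dropped with a warning.
#'
#' @param raw A (preprocessed) `raw_eeg`.
#' @param events Stimulus events data.frame (`onset`, `class`), e.g.
#'   `schedule$events`.
#' @param window Epoch window relative to onset, s.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples),
#'   `times` (s), `classes`, `rate`, `labels`, `baseline_corrected`,
#'   `n_rejected`.
#' @export
epoch_eeg <- function(raw, events, window = c(-0.2, 1.0)) {
  rate <- raw$rate
  k0 <- round(window[1] * rate)
  k1 <- round(window[2] * rate)
  n_samp <- k1 - k0 + 1L
  n <- ncol(raw$samples)
  onset_idx <- round(events$onset * rate) + 1L
  keep <- onset_idx + k0 >= 1L & onset_idx + k1 <= n
  if (any(!keep))
    warning(sprintf("%d event(s) too close to the recording edge dropped",
                    sum(!keep)))
  onset_idx <- onset_idx[keep]
  classes <- events$class[keep]
  art <- raw$artifacts
  rejected <- logical(length(onset_idx))
  if (!is.null(art)) {
    allart <- sort(unique(unlist(art)))
    if (length(allart)) {
      for (i in seq_along(onset_idx)) {
        lo <- onset_idx[i] + k0; hi <- onset_idx[i] + k1
        rejected[i] <- any(allart >= lo & allart <= hi)
      }
    }
  }
  use <- which(!rejected)
  data <- array(0, dim = c(length(use), nrow(raw$samples), n_samp))
  for (j in seq_along(use)) {
    i <- use[j]
    data[j, , ] <- raw$samples[, (onset_idx[i] + k0):(onset_idx[i] + k1)]
  }
  structure(list(data = data, times = (k0:k1) / rate, classes = classes[use],
                 rate = rate, labels = raw$labels,
                 baseline_corrected = FALSE,
                 n_rejected = sum(rejected)),
            class = "eeg_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the prestimulus interval
#' ([-0.2, 0) s by default -- all samples strictly before onset) from the
#' whole epoch.
#'
#' @param epochs An `eeg_epochs` (or `hemo_epochs`-like) object with `data`
#'   and `times`.
#' @return The corrected object, `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(epochs) {
  pre <- which(epochs$times < 0)
  if (!length(pre)) stop("window has no prestimulus samples", call. = FALSE)
  d <- epochs$data
  bl <- apply(d[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- d - array(rep(bl, dim(d)[3]), dim = dim(d))
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Average epochs of one class into an ERP
#'
#' @param epochs A baseline-corrected `eeg_epochs`.
#' @param class Stimulus class (`"target"` or `"standard"`).
#' @return An `erp_result`: `mean` and `sem` (channels x samples matrices),
#'   `times`, `labels`, `rate`, `n_trials`, `class`.
#' @export
average_erp <- function(epochs, class) {
  idx <- which(epochs$classes == class)
  if (!length(idx))
    stop(sprintf("no epochs for class '%s'", class), call. = FALSE)
  d <- epochs$data[idx, , , drop = FALSE]
  st <- trialwise_stats(d)
  m <- st$mean
  s <- st$sd / sqrt(length(idx))
  structure(list(mean = m, sem = s, times = epochs$times,
                 labels = epochs$labels, rate = epochs$rate,
                 n_trials = length(idx), class = class),
            class = "erp_result")
}

#' Extract the P300 peak from an averaged ERP waveform
#'
#' The peak is the maximum of the class-mean waveform inside the search
#' window (default 250--400 ms post-stimulus); its time is the latency. Ties
#' break toward the earliest sample.
#'
#' @param erp An `erp_result`, or a numeric waveform (then `times` must be
#'   supplied via attributes of the call: use the `erp` interface instead).
#' @param channel Channel label.
#' @param window Search window, ms (default `c(250, 400)`).
#' @param require_positive Flag the result when no strictly positive value
#'   exists in the window (default `TRUE`).
#' @return List: `latency_ms`, `amplitude`, `positive_peak` (FALSE when the
#'   windowed maximum is not positive).
#' @export
extract_p300 <- function(erp, channel, window = c(250, 400),
                         require_positive = TRUE) {
  ch <- match(channel, erp$labels)
  if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  tm <- erp$times * 1000
  sel <- which(tm >= window[1] & tm <= window[2])
  if (!length(sel)) stop("search window outside epoch", call. = FALSE)
  wv <- erp$mean[ch, sel]
  i <- which.max(wv)  # which.max returns the earliest maximum
  list(latency_ms = tm[sel][i], amplitude = wv[i],
       positive_peak = !require_positive || wv[i] > 0)
}

#' Run the complete single-participant EEG analysis
#'
#' Impedance masking, zero-phase filtering, epoching, baseline correction,
#' and class-wise ERP averaging.
#'
#' @param raw A `raw_eeg`.
#' @param events Stimulus events data.frame (`onset`, `class`).
#' @param window Epoch window, s.
#' @return List: `mask`, `erp` (named list with `target`, `standard`),
#'   `n_rejected`.
#' @export
analyze_eeg <- function(raw, events, window = c(-0.2, 1.0)) {
  mask <- validate_channels_eeg(raw$impedances, raw$labels)
  filt <- preprocess_eeg(raw)
  ep <- baseline_correct(epoch_eeg(filt, events, window))
  list(mask = mask,
       erp = list(target = average_erp(ep, "target"),
                  standard = average_erp(ep, "standard")),
       n_rejected = ep$n_rejected)
}
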