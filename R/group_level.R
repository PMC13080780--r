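# Group-level aggregation: ROI averaging, grand averages with SEM, cohort
# behavioral statistics, and the cohort report.

#' Average per-channel waveforms into ROIs
#'
#' The ROI waveform is the mean over the ROI's valid member channels; ROIs
#' whose members are all invalid (or absent from the result) are omitted
#' with a reason entry.
#'
#' @param waveforms Channels x samples matrix with rownames set to channel
#'   labels (e.g. `erp_result$mean` after `rownames<-`), or an `erp_result`.
#' @param mask A `channel_mask` covering the waveform channels.
#' @param roi_map A [default_roi_map()]-style map.
#' @param modality `"eeg"` or `"fnirs"`.
#' @return List: `roi` (named list of ROI-mean waveforms) and `omitted`
#'   (named character vector of reasons).
#' @export
roi_average <- function(waveforms, mask, roi_map = default_roi_map(),
                        modality = "eeg") {
  if (inherits(waveforms, "erp_result")) {
    m <- waveforms$mean
    rownames(m) <- waveforms$labels
    waveforms <- m
  }
  labels <- rownames(waveforms)
  if (is.null(labels)) stop("waveforms must carry channel rownames",
                            call. = FALSE)
  vmap <- stats::setNames(mask$valid, mask$channel)
  rois <- roi_map[[modality]]
  out <- list()
  omitted <- character(0)
  for (roi in names(rois)) {
    members <- rois[[roi]]
    unknown <- setdiff(members, c(labels, mask$channel))
    if (length(unknown))
      stop(sprintf("unknown channel label(s) in ROI '%s': %s", roi,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    present <- intersect(members, labels)
    if (!length(present)) {
      omitted[roi] <- "no member channels in result"
      next
    }
    valid <- present[!is.na(vmap[present]) & vmap[present]]
    if (!length(valid)) {
      omitted[roi] <- "all member channels invalid"
      next
    }
    out[[roi]] <- colMeans(waveforms[valid, , drop = FALSE])
  }
  list(roi = out, omitted = omitted)
}

#' Grand average across participants
#'
#' Pointwise mean and SEM (across-participant SD / sqrt(n)) over a list of
#' equal-length participant waveforms. With a single participant the mean is
#' returned and the SEM flagged undefined (NA).
#'
#' @param waveforms List (one element per participant) of numeric vectors.
#' @return List: `mean`, `sem`, `n`.
#' @export
grand_average <- function(waveforms) {
  waveforms <- waveforms[!vapply(waveforms, is.null, TRUE)]
  n <- length(waveforms)
  if (n == 0L) stop("no participant waveforms", call. = FALSE)
  m <- do.call(rbind, waveforms)
  list(mean = colMeans(m),
       sem = if (n >= 2) col_sem(m) else rep(NA_real_, ncol(m)),
       n = n)
}

#' Assemble the cohort report
#'
#' Collects (1) the RT/accuracy table, (2) the cohort Wilcoxon result on
#' per-participant mean RTs, (3) the P300 peak table at Cz and Pz per class
#' from the grand-average ERPs, (4) the right-frontal HbO class means with
#' peak time, and (5) the exclusion log. Missing modalities yield explicit
#' gaps rather than errors.
#'
#' @param behavior List of per-participant behavior summaries
#'   ([summarize_behavior()] outputs); required.
#' @param eeg List of per-participant EEG results ([analyze_eeg()] outputs),
#'   or `NULL`.
#' @param fnirs List of per-participant fNIRS results ([analyze_fnirs()]
#'   outputs), or `NULL`.
#' @param roi_map ROI map used for aggregation.
#' @param exclusion_threshold Drop a participant from a modality when more
#'   than this fraction of its channels is invalid (default 0.5).
#' @param p300_window P300 search window, ms.
#' @param hbo_roi fNIRS ROI examined for the hemodynamic contrast.
#' @return A `cohort_report` list; see Details in the vignette.
#' @export
cohort_report <- function(behavior, eeg = NULL, fnirs = NULL,
                          roi_map = default_roi_map(),
                          exclusion_threshold = 0.5,
                          p300_window = c(250, 400),
                          hbo_roi = "frontal_right") {
  n <- length(behavior)
  rt_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- behavior[[i]]
    data.frame(participant = i,
               rt_target = b$mean_rt[b$class == "target"],
               rt_standard = b$mean_rt[b$class == "standard"],
               acc_target = b$accuracy_pct[b$class == "target"],
               acc_standard = b$accuracy_pct[b$class == "standard"])
  }))
  behavior_summary <- data.frame(
    class = c("target", "standard"),
    mean_rt = c(mean(rt_tab$rt_target), mean(rt_tab$rt_standard)),
    sd_rt = c(stats::sd(rt_tab$rt_target), stats::sd(rt_tab$rt_standard)),
    mean_accuracy_pct = c(mean(rt_tab$acc_target), mean(rt_tab$acc_standard)),
    sd_accuracy_pct = c(stats::sd(rt_tab$acc_target),
                        stats::sd(rt_tab$acc_standard)))
  wil <- wilcoxon_signed_rank(rt_tab$rt_target, rt_tab$rt_standard)

  exclusions <- data.frame(participant = integer(0), modality = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  note_exclusion <- function(i, modality, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(participant = i, modality = modality,
                                    reason = reason, stringsAsFactors = FALSE))
  }

  report <- list(n_participants = n, behavior = behavior_summary,
                 behavior_per_participant = rt_tab, wilcoxon = wil)

  if (!is.null(eeg)) {
    keep <- logical(n)
    for (i in seq_len(n)) {
      frac_bad <- mean(!eeg[[i]]$mask$valid)
      if (frac_bad > exclusion_threshold)
        note_exclusion(i, "eeg", sprintf("%.0f%% channels invalid",
                                         100 * frac_bad))
      else keep[i] <- TRUE
    }
    ga_chan <- list()
    for (ch in c("Cz", "Pz")) {
      for (cls in c("target", "standard")) {
        wfs <- lapply(which(keep), function(i) {
          r <- eeg[[i]]
          ok <- r$mask$valid[match(ch, r$mask$channel)]
          if (is.na(ok) || !ok) return(NULL)
          r$erp[[cls]]$mean[match(ch, r$erp[[cls]]$labels), ]
        })
        ga_chan[[paste(ch, cls, sep = ".")]] <- grand_average(wfs)
      }
    }
    times <- eeg[[which(keep)[1]]]$erp$target$times
    p300 <- do.call(rbind, lapply(c("Cz", "Pz"), function(ch) {
      do.call(rbind, lapply(c("target", "standard"), function(cls) {
        ga <- ga_chan[[paste(ch, cls, sep = ".")]]
        fake_erp <- structure(list(mean = matrix(ga$mean, 1), times = times,
                                   labels = ch), class = "erp_result")
        pk <- extract_p300(fake_erp, ch, window = p300_window)
        data.frame(channel = ch, class = cls, n = ga$n,
                   amplitude = pk$amplitude, latency_ms = pk$latency_ms,
                   stringsAsFactors = FALSE)
      }))
    }))
    # ROI grand averages over participant ROI means
    roi_ga <- list()
    for (cls in c("target", "standard")) {
      per_roi <- list()
      for (i in which(keep)) {
        ra <- roi_average(eeg[[i]]$erp[[cls]], eeg[[i]]$mask, roi_map, "eeg")
        for (roi in names(ra$roi)) per_roi[[roi]][[as.character(i)]] <- ra$roi[[roi]]
      }
      roi_ga[[cls]] <- lapply(per_roi, grand_average)
    }
    report$eeg <- list(times = times, channel_grand_averages = ga_chan,
                       p300 = p300, roi_grand_averages = roi_ga,
                       n_included = sum(keep))
  } else report$eeg <- NULL

  if (!is.null(fnirs)) {
    keep <- logical(n)
    for (i in seq_len(n)) {
      frac_bad <- mean(!fnirs[[i]]$mask$valid)
      if (frac_bad > exclusion_threshold)
        note_exclusion(i, "fnirs", sprintf("%.0f%% channels invalid",
                                           100 * frac_bad))
      else keep[i] <- TRUE
    }
    times <- fnirs[[which(keep)[1]]]$epochs$times
    hbo_ga <- list()
    for (cls in c("target", "standard")) {
      wfs <- lapply(which(keep), function(i) {
        r <- fnirs[[i]]
        ep <- r$epochs[[cls]]
        if (is.null(ep)) return(NULL)
        m <- ep$mean
        rownames(m) <- r$epochs$channels
        lmask <- r$mask[match(rownames(m), r$mask$channel), , drop = FALSE]
        ra <- roi_average(m, lmask, roi_map, "fnirs")
        ra$roi[[hbo_roi]]
      })
      hbo_ga[[cls]] <- grand_average(wfs)
    }
    pk_idx <- which.max(hbo_ga$target$mean)
    report$fnirs <- list(times = times, hbo_roi = hbo_roi,
                         grand_averages = hbo_ga,
                         target_peak_time = times[pk_idx],
                         target_peak_value = hbo_ga$target$mean[pk_idx],
                         n_included = sum(keep))
  } else report$fnirs <- NULL

  report$exclusions <- exclusions
  report$missing_modalities <- c("eeg", "fnirs")[c(is.null(eeg),
                                                   is.null(fnirs))]
  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d participants\n", x$n_participants))
  cat(sprintf("  RT: target %.0f (SD %.0f) ms vs standard %.0f (SD %.0f) ms\n",
              x$behavior$mean_rt[1], x$behavior$sd_rt[1],
              x$behavior$mean_rt[2], x$behavior$sd_rt[2]))
  cat(sprintf("  Accuracy: target %.2f%%, standard %.2f%%\n",
              x$behavior$mean_accuracy_pct[1], x$behavior$mean_accuracy_pct[2]))
  cat(sprintf("  Wilcoxon: Z = %.2f, p = %.3g, r = %.2f (n = %d)\n",
              x$wilcoxon$z, x$wilcoxon$p, x$wilcoxon$r, x$wilcoxon$n_pairs))
  if (!is.null(x$eeg)) {
    cat("  P300 peaks (grand average):\n")
    p <- x$eeg$p300
    for (i in seq_len(nrow(p)))
      cat(sprintf("    %s %-8s %6.3f uV at %.0f ms\n", p$channel[i],
                  p$class[i], p$amplitude[i], p$latency_ms[i]))
  }
  if (!is.null(x$fnirs))
    cat(sprintf("  HbO (%s ROI): target peak %.3f uM at %.1f s\n",
                x$fnirs$hbo_roi, x$fnirs$target_peak_value,
                x$fnirs$target_peak_time))
  if (length(x$missing_modalities))
    cat("  missing modalities:", paste(x$missing_modalities, collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a cohort report to disk as CSV/JSON
#'
#' @param report A `cohort_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$behavior, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$behavior_per_participant,
                   file.path(out_dir, "behavior_per_participant.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report$wilcoxon),
                       file.path(out_dir, "wilcoxon.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$eeg)) {
    utils::write.csv(report$eeg$p300, file.path(out_dir, "p300_peaks.csv"),
                     row.names = FALSE)
    ga <- report$eeg$channel_grand_averages
    wide <- data.frame(time_s = report$eeg$times)
    for (nm in names(ga)) wide[[nm]] <- ga[[nm]]$mean
    utils::write.csv(wide, file.path(out_dir, "erp_grand_averages.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$fnirs)) {
    wide <- data.frame(time_s = report$fnirs$times,
                       target = report$fnirs$grand_averages$target$mean,
                       standard = report$fnirs$grand_averages$standard$mean)
    utils::write.csv(wide, file.path(out_dir, "hbo_grand_averages.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(roi = report$fnirs$hbo_roi,
                              peak_time = report$fnirs$target_peak_time,
                              peak_value = report$fnirs$target_peak_value),
                         file.path(out_dir, "hbo_peak.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
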