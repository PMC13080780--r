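# One-command replication of the oddball validation experiment on synthetic
# data: simulate a cohort, run all three analyses, assemble the report.

#' Run the full synthetic replication experiment
#'
#' For each of `config$n_participants` participants (profiles drawn from the
#' cohort distribution, deterministic in the master seed): generate a
#' schedule, simulate responses and EEG/fNIRS recordings, run the behavioral,
#' ERP, and hemodynamic pipelines, then aggregate everything with
#' [cohort_report()]. Raw recordings are processed one participant at a time
#' and discarded, so memory stays flat in the cohort size.
#'
#' @param config A [run_config()].
#' @param modalities Subset of `c("eeg", "fnirs")` to simulate and analyze
#'   in addition to behavior.
#' @param verbose Print per-participant progress.
#' @return A `cohort_report`. When `config$output` is set the report is also
#'   written there via [write_cohort_report()].
#' @examples
#' \donttest{
#' cfg <- run_config(n_participants = 2, seed = 7)
#' rep <- run_replication(cfg, modalities = character(0))
#' rep$wilcoxon$w_plus  # 3 = 2*3/2 when both RT differences are positive
#' }
#' @export
run_replication <- function(config = run_config(),
                            modalities = c("eeg", "fnirs"),
                            verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  pl <- config$pipeline
  n <- config$n_participants
  profiles <- sample_cohort_profiles(n, config$dist, seed = config$seed)
  behavior <- vector("list", n)
  eeg_res <- if ("eeg" %in% modalities) vector("list", n) else NULL
  fnirs_res <- if ("fnirs" %in% modalities) vector("list", n) else NULL
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    sched <- generate_oddball_schedule(config$task,
                                       seed = child_seed(p$seed, 1))
    streams <- schedule_to_event_streams(sched)
    streams$marker <- simulate_responses(sched, p,
                                         seed = child_seed(p$seed, 2))
    trials <- match_responses(streams$stimulus, streams$marker,
                              isi = config$task$isi,
                              response_floor = pl$response_floor)
    behavior[[i]] <- summarize_behavior(trials)
    if ("eeg" %in% modalities) {
      raw <- simulate_eeg(sched, p, config$noise,
                          seed = child_seed(p$seed, 3))
      mask <- validate_channels_eeg(raw$impedances, raw$labels,
                                    threshold = pl$impedance_threshold)
      filt <- preprocess_eeg(raw, lowpass = pl$eeg_lowpass,
                             line_freq = config$noise$eeg_line_freq,
                             artifact_uv = pl$artifact_uv)
      ep <- baseline_correct(epoch_eeg(filt, sched$events, pl$erp_window))
      eeg_res[[i]] <- list(mask = mask,
                           erp = list(target = average_erp(ep, "target"),
                                      standard = average_erp(ep, "standard")),
                           n_rejected = ep$n_rejected)
      rm(raw, filt, ep)
    }
    if ("fnirs" %in% modalities) {
      raw <- simulate_fnirs(sched, p, config$noise,
                            seed = child_seed(p$seed, 4))
      # epochs near the recording tail are dropped by design (20 s windows)
      fnirs_res[[i]] <- suppressWarnings(
        analyze_fnirs(raw, sched$events, window = pl$hbo_window,
                      lowpass_cutoff = pl$fnirs_lowpass,
                      sci_threshold = pl$sci_threshold))
      fnirs_res[[i]]$hemo <- NULL  # keep epoch averages only
      rm(raw)
    }
    if (verbose) message(sprintf("participant %d/%d done", i, n))
  }
  report <- cohort_report(behavior, eeg_res, fnirs_res,
                          exclusion_threshold = pl$exclusion_threshold,
                          p300_window = pl$p300_window)
  if (!is.null(config$output)) write_cohort_report(report, config$output)
  report
}
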