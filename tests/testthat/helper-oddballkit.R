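# Shared fixtures and independent oracles, built in code at test time.

# Exact two-sided p of the signed-rank statistic by full 2^n enumeration of
# sign assignments (independent oracle for the normal approximation).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Minimal hand-built schedule with the given classes at exact ISI spacing
toy_schedule <- function(classes, isi = 2, baseline = 10,
                         gap_min = 1L, gap_max = 100L) {
  cfg <- task_config(isi = isi, task_duration = length(classes) * isi,
                     baseline_duration = baseline,
                     gap_min = gap_min, gap_max = gap_max)
  structure(list(config = cfg,
                 events = data.frame(index = seq_along(classes),
                                     onset = baseline +
                                       (seq_along(classes) - 1) * isi,
                                     class = classes,
                                     stringsAsFactors = FALSE)),
            class = "stimulus_schedule")
}

# Tiny fNIRS geometry: n_long long channels paired to one short channel
toy_geometry <- function(n_long = 2) {
  data.frame(
    channel = c(paste0("L", seq_len(n_long)), "S1"),
    source = "src", detector = "det",
    separation_mm = c(rep(30, n_long), 8),
    is_short = c(rep(FALSE, n_long), TRUE),
    short_pair = c(rep("S1", n_long), NA),
    region = "toy", stringsAsFactors = FALSE)
}

# raw_fnirs carrying the given HbO/HbR (uM, channels x time) noise-free
# through the forward Beer-Lambert model
toy_raw_fnirs <- function(hbo, hbr = -hbo / 3, rate = 10,
                          geometry = toy_geometry(nrow(hbo) - 1)) {
  params <- mbll_params(geometry)
  od <- oddballkit:::forward_mbll(hbo, hbr, params)
  intens <- array(0, dim = dim(od))
  for (w in 1:2) intens[, w, ] <- exp(-od[, w, ])
  raw_fnirs(intens, rate, geometry)
}

# Marker record data.frame from explicit (timestamp, button) pairs
toy_markers <- function(timestamps, buttons) {
  data.frame(stream = "marker", timestamp = timestamps,
             payload = sprintf("button=%s", buttons), stringsAsFactors = FALSE)
}

# The heavy default-cohort replication is computed once per test run and
# shared between acceptance blocks.
cohort_cache <- new.env(parent = emptyenv())
default_cohort_report <- function() {
  if (is.null(cohort_cache$report)) {
    cfg <- run_config(n_participants = 53, seed = 42)
    cohort_cache$report <- suppressWarnings(run_replication(cfg))
  }
  cohort_cache$report
}
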