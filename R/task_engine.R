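# Oddball task-event engine: stimulus schedules and event streams.

#' Oddball task configuration
#'
#' Timing parameters of a single visual-oddball run. Defaults follow the
#' validated mobile protocol: 2 s interstimulus interval (ISI), 0.5 s stimulus
#' presentations, a 4-minute task flanked by two 10-second resting baselines,
#' and 7--21 standard stimuli between consecutive targets.
#'
#' @param isi Onset-to-onset interstimulus interval, seconds.
#' @param stim_duration Stimulus presentation time, seconds; must be < `isi`.
#' @param task_duration Total task time (excluding baselines), seconds.
#' @param baseline_duration Resting baseline applied before and after the
#'   task, seconds.
#' @param gap_min,gap_max Minimum/maximum count of standard stimuli between
#'   consecutive targets (inclusive bounds).
#' @param seed Integer seed recorded with the config (used by
#'   [generate_oddball_schedule()] when no seed is passed explicitly).
#' @return A `task_config` list.
#' @examples
#' cfg <- task_config()
#' cfg$isi
#' @export
task_config <- function(isi = 2.0, stim_duration = 0.5, task_duration = 240,
                        baseline_duration = 10, gap_min = 7L, gap_max = 21L,
                        seed = 1L) {
  check_scalar_num(isi, "isi", positive = TRUE)
  check_scalar_num(stim_duration, "stim_duration", positive = TRUE)
  check_scalar_num(task_duration, "task_duration", positive = TRUE)
  check_scalar_num(baseline_duration, "baseline_duration", positive = TRUE)
  check_scalar_num(gap_min, "gap_min", min = 1)
  check_scalar_num(gap_max, "gap_max", min = 1)
  if (stim_duration >= isi) stop_field("stim_duration", "must be < isi")
  if (gap_min > gap_max) stop_field("gap_min", "must be <= gap_max")
  structure(list(isi = isi, stim_duration = stim_duration,
                 task_duration = task_duration,
                 baseline_duration = baseline_duration,
                 gap_min = as.integer(gap_min), gap_max = as.integer(gap_max),
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Generate an oddball stimulus schedule
#'
#' Lays out `floor(task_duration / isi)` stimulus onsets spaced exactly `isi`
#' seconds apart, the first at `baseline_duration`, and assigns classes so
#' that the number of standards between consecutive targets is drawn uniformly
#' over the integers `[gap_min, gap_max]`. The first target is preceded by a
#' uniformly drawn gap as well, so target positions carry no edge bias.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed; defaults to `config$seed`. The schedule
#'   is a deterministic function of `(config, seed)`.
#' @return A `stimulus_schedule`: list with `config` and `events`, a
#'   data.frame with columns `index`, `onset` (s), `class`
#'   (`"target"`/`"standard"`).
#' @examples
#' sched <- generate_oddball_schedule(task_config(), seed = 7)
#' nrow(sched$events)      # 120 events for the default 240 s / 2 s
#' table(sched$events$class)
#' @export
generate_oddball_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  n_events <- floor(config$task_duration / config$isi)
  if (config$gap_min + 1 > n_events)
    stop("task too short for one target: gap_min + 1 exceeds event count",
         call. = FALSE)
  rng <- local({ set.seed(as.integer(seed)); NULL })
  classes <- rep("standard", n_events)
  pos <- 0L
  repeat {
    gap <- sample.int(config$gap_max - config$gap_min + 1L, 1L) +
      config$gap_min - 1L
    pos <- pos + gap + 1L
    if (pos > n_events) break
    classes[pos] <- "target"
  }
  onsets <- config$baseline_duration + (seq_len(n_events) - 1L) * config$isi
  structure(list(config = config,
                 events = data.frame(index = seq_len(n_events),
                                     onset = onsets, class = classes,
                                     stringsAsFactors = FALSE)),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<stimulus_schedule> %d events (%d targets), ISI %g s, onsets %g..%g s\n",
              nrow(ev), sum(ev$class == "target"), x$config$isi,
              min(ev$onset), max(ev$onset)))
  invisible(x)
}

# Gaps (counts of standards) between consecutive targets of a schedule
target_gaps <- function(schedule) {
  ti <- which(schedule$events$class == "target")
  if (length(ti) < 2L) return(integer(0))
  diff(ti) - 1L
}

#' Serialize a schedule as the three task event streams
#'
#' Task events fall into three categories mirrored as three record streams:
#' `metadata` (task information/configuration, task start/stop, baseline
#' start/stop), `stimulus` (one record per presentation carrying class and
#' onset), and `marker` (user responses; empty until a participant --
#' simulated or real -- responds). Timestamps are seconds on a run-local
#' monotonic clock starting at 0 when the run begins.
#'
#' @param schedule A `stimulus_schedule`.
#' @return An `event_stream_set`: list of three data.frames (`metadata`,
#'   `stimulus`, `marker`), each with columns `stream`, `timestamp`,
#'   `payload` (semicolon-separated `key=value` text).
#' @export
schedule_to_event_streams <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  cfg <- schedule$config
  ev <- schedule$events
  run_end <- cfg$baseline_duration + nrow(ev) * cfg$isi + cfg$baseline_duration

  meta_payloads <- c(
    paste0("type=config;", paste(sprintf("%s=%s", names(unclass(cfg)),
                                         unlist(unclass(cfg))),
                                 collapse = ";")),
    "type=baseline_start;phase=pre",
    "type=task_start",
    "type=task_stop",
    "type=baseline_start;phase=post",
    "type=baseline_stop;phase=post")
  meta_times <- c(0, 0, cfg$baseline_duration,
                  cfg$baseline_duration + nrow(ev) * cfg$isi,
                  cfg$baseline_duration + nrow(ev) * cfg$isi, run_end)
  metadata <- data.frame(stream = "metadata", timestamp = meta_times,
                         payload = meta_payloads, stringsAsFactors = FALSE)

  stimulus <- data.frame(
    stream = "stimulus", timestamp = ev$onset,
    payload = sprintf("index=%d;class=%s;onset=%.6f", ev$index, ev$class,
                      ev$onset),
    stringsAsFactors = FALSE)

  marker <- data.frame(stream = character(0), timestamp = numeric(0),
                       payload = character(0), stringsAsFactors = FALSE)
  structure(list(metadata = metadata, stimulus = stimulus, marker = marker),
            class = "event_stream_set")
}

# Parse "k1=v1;k2=v2" payload text into a named character vector
parse_payload <- function(payload) {
  parts <- strsplit(payload, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

# Stimulus stream -> events data.frame (index, onset, class)
stimulus_stream_events <- function(streams) {
  pl <- lapply(streams$stimulus$payload, parse_payload)
  data.frame(index = as.integer(vapply(pl, `[[`, "", "index")),
             onset = as.numeric(vapply(pl, `[[`, "", "onset")),
             class = vapply(pl, `[[`, "", "class"),
             stringsAsFactors = FALSE)
}

#' Validate a stimulus schedule against its invariants
#'
#' Checks every structural invariant of a schedule and reports each violation
#' with the offending event indices: first onset at `baseline_duration`,
#' onsets spaced exactly by the ISI and strictly increasing, event count equal
#' to `floor(task_duration / isi)`, and every inter-target gap within
#' `[gap_min, gap_max]`.
#'
#' @param schedule A `stimulus_schedule` (possibly hand-built).
#' @return A data.frame with columns `invariant`, `message`, `indices`
#'   (comma-separated offending event indices or `""`). Zero rows iff the
#'   schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  cfg <- schedule$config
  ev <- schedule$events
  bad <- list()
  add <- function(invariant, message, indices = integer(0)) {
    bad[[length(bad) + 1L]] <<- data.frame(
      invariant = invariant, message = message,
      indices = paste(indices, collapse = ","), stringsAsFactors = FALSE)
  }
  if (nrow(ev) == 0L) {
    add("event_count", "schedule has no events")
  } else {
    if (abs(ev$onset[1] - cfg$baseline_duration) > 1e-9)
      add("first_onset", sprintf("first onset %.6f != baseline_duration %.6f",
                                 ev$onset[1], cfg$baseline_duration), 1L)
    steps <- diff(ev$onset)
    off <- which(abs(steps - cfg$isi) > 1e-9)
    if (length(off))
      add("onset_spacing", sprintf("onset steps differ from isi %.6f", cfg$isi),
          off + 1L)
    n_expect <- floor(cfg$task_duration / cfg$isi)
    if (nrow(ev) != n_expect)
      add("event_count", sprintf("%d events, expected %d", nrow(ev), n_expect))
    gaps <- target_gaps(schedule)
    ti <- which(ev$class == "target")
    if (length(gaps)) {
      viol <- which(gaps < cfg$gap_min | gaps > cfg$gap_max)
      if (length(viol))
        add("target_gap",
            sprintf("inter-target gaps outside [%d, %d]",
                    cfg$gap_min, cfg$gap_max),
            ti[viol + 1L])
    }
  }
  if (!length(bad))
    return(data.frame(invariant = character(0), message = character(0),
                      indices = character(0), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}
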