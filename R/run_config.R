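# Run configuration: defaults, validation, YAML/JSON round-trip.

#' Full replication run configuration
#'
#' Bundles the task timing, cohort size and profile distribution, noise
#' model, and every pipeline threshold/window with their protocol defaults
#' (30 kOhm impedance, SCI 0.4, 45 Hz EEG band, 0.08 Hz fNIRS cutoff,
#' [-0.2, 1] s ERP epochs, [250, 400] ms P300 window, [-1, 20] s HbO epochs,
#' 7--21 gaps, 2 s ISI, 0.5 s stimuli, 240 s task, 10 s baselines).
#'
#' @param task A [task_config()].
#' @param n_participants Cohort size.
#' @param dist A [profile_distribution()].
#' @param noise A [noise_model()].
#' @param pipeline Named list of pipeline parameters; see defaults in the
#'   function body. Partial lists are merged over the defaults.
#' @param seed Master seed.
#' @param output Output directory or `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(task = task_config(), n_participants = 53,
                       dist = profile_distribution(), noise = noise_model(),
                       pipeline = list(), seed = 1L, output = NULL) {
  defaults <- list(impedance_threshold = 30, sci_threshold = 0.4,
                   eeg_lowpass = 45, fnirs_lowpass = 0.08,
                   erp_window = c(-0.2, 1.0), p300_window = c(250, 400),
                   hbo_window = c(-1, 20), response_floor = 100,
                   artifact_uv = 100, exclusion_threshold = 0.5)
  unknown <- setdiff(names(pipeline), names(defaults))
  if (length(unknown))
    stop_field(paste0("pipeline.", unknown[1]), "unknown parameter")
  pipeline <- utils::modifyList(defaults, pipeline)
  check_scalar_num(n_participants, "n_participants", min = 1)
  for (f in c("impedance_threshold", "sci_threshold", "eeg_lowpass",
              "fnirs_lowpass", "response_floor", "artifact_uv",
              "exclusion_threshold"))
    check_scalar_num(pipeline[[f]], paste0("pipeline.", f))
  structure(list(task = task, n_participants = as.integer(n_participants),
                 dist = dist, noise = noise, pipeline = pipeline,
                 seed = as.integer(seed), output = output),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Fields absent from the file keep their defaults. The mapping round-trips
#' through [save_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_num <- function(x) if (is.list(x)) unlist(x) else x
  task <- do.call(task_config, lapply(raw$task %||% list(), as_num))
  dist_args <- lapply(raw$dist %||% list(), as_num)
  noise_args <- lapply(raw$noise %||% list(), as_num)
  run_config(task = task,
             n_participants = raw$n_participants %||% 53,
             dist = do.call(profile_distribution, dist_args),
             noise = do.call(noise_model, noise_args),
             pipeline = lapply(raw$pipeline %||% list(), as_num),
             seed = raw$seed %||% 1L,
             output = raw$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration as YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  named_to_map <- function(l) lapply(l, function(v)
    if (is.null(names(v))) v else as.list(v))
  x <- list(task = unclass(config$task),
            n_participants = config$n_participants,
            dist = named_to_map(unclass(config$dist)),
            noise = named_to_map(unclass(config$noise)),
            pipeline = config$pipeline,
            seed = config$seed, output = config$output)
  yaml::write_yaml(x, path)
  invisible(path)
}
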