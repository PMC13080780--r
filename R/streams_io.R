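# Serialization: JSON-lines event streams and flat-binary raw recordings.

#' Write an event stream set as JSON lines
#'
#' One record per line with fields `stream`, `timestamp`, `payload`, in
#' within-stream timestamp order (metadata, then stimulus, then marker
#' blocks). The representation round-trips losslessly through
#' [read_event_streams()].
#'
#' @param streams An `event_stream_set`.
#' @param path Output file path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_event_streams <- function(streams, path) {
  recs <- rbind(streams$metadata, streams$stimulus, streams$marker)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(recs))) {
    writeLines(jsonlite::toJSON(list(stream = recs$stream[i],
                                     timestamp = recs$timestamp[i],
                                     payload = recs$payload[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read an event stream set from JSON lines
#'
#' @param path File written by [write_event_streams()].
#' @return An `event_stream_set`.
#' @export
read_event_streams <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(stream = vapply(recs, `[[`, "", "stream"),
                   timestamp = vapply(recs, `[[`, 0, "timestamp"),
                   payload = vapply(recs, `[[`, "", "payload"),
                   stringsAsFactors = FALSE)
  out <- lapply(c(metadata = "metadata", stimulus = "stimulus",
                  marker = "marker"),
                function(s) {
                  d <- df[df$stream == s, , drop = FALSE]
                  rownames(d) <- NULL
                  d
                })
  structure(out, class = "event_stream_set")
}

#' Write a raw EEG recording (flat binary + JSON sidecar)
#'
#' Samples are stored channel-major as little-endian float64 in
#' `<prefix>.bin`; labels, rate, and impedances in `<prefix>.json`.
#'
#' @param raw A `raw_eeg` object.
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_raw_eeg <- function(raw, prefix) {
  con <- file(paste0(prefix, ".bin"), open = "wb")
  writeBin(as.vector(t(raw$samples)), con, size = 8, endian = "little")
  close(con)
  side <- list(modality = "eeg", rate = raw$rate, labels = raw$labels,
               impedances = raw$impedances,
               n_channels = nrow(raw$samples), n_samples = ncol(raw$samples))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a raw EEG recording written by [write_raw_eeg()]
#' @param prefix Path prefix used at write time.
#' @return A `raw_eeg` object.
#' @export
read_raw_eeg <- function(prefix) {
  side <- jsonlite::fromJSON(paste0(prefix, ".json"))
  n <- side$n_channels * side$n_samples
  con <- file(paste0(prefix, ".bin"), open = "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  raw_eeg(samples = t(matrix(x, nrow = side$n_samples)), rate = side$rate,
          labels = side$labels, impedances = side$impedances)
}

#' Write a raw fNIRS recording (flat binary + JSON sidecar)
#'
#' Intensities are stored as little-endian float64 ordered channel, then
#' wavelength, then time; geometry and wavelengths go to the sidecar.
#'
#' @param raw A `raw_fnirs` object.
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_raw_fnirs <- function(raw, prefix) {
  con <- file(paste0(prefix, ".bin"), open = "wb")
  writeBin(as.vector(raw$intensities), con, size = 8, endian = "little")
  close(con)
  side <- list(modality = "fnirs", rate = raw$rate,
               wavelengths = raw$wavelengths, geometry = raw$geometry,
               dim = dim(raw$intensities))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a raw fNIRS recording written by [write_raw_fnirs()]
#' @param prefix Path prefix used at write time.
#' @return A `raw_fnirs` object.
#' @export
read_raw_fnirs <- function(prefix) {
  side <- jsonlite::fromJSON(paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), open = "rb")
  x <- readBin(con, "double", n = prod(side$dim), size = 8, endian = "little")
  close(con)
  raw_fnirs(intensities = array(x, dim = side$dim), rate = side$rate,
            geometry = side$geometry, wavelengths = side$wavelengths)
}
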