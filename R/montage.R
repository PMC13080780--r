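# Montage fixtures: EEG channel set, fNIRS channel geometry, and the ROI map.
#
# The published sensor-to-ROI table contains several run-together channel
# strings (e.g. "AFP1AFF5F3F1") and an apparent left/right swap in the
# temporal fNIRS rows; the map below is a best-effort tokenization, flagged
# for review. "temporal midline" and "central midline" are aliases for the
# Cz ROI because the source uses both names.

EEG_ROI_CHANNELS <- list(
  frontal_left     = c("AFp1", "AFF5", "F3", "F1"),
  frontal_right    = c("AFp2", "AFF6h", "F4", "F2"),
  temporal_left    = c("FTT7h", "TTP7h"),
  temporal_right   = c("FTT8h", "TTP8h"),
  parietal_left    = c("P1", "P7", "CPP5h", "TPP7h"),
  parietal_right   = c("P2", "P8", "CPP6h", "TPP8h"),
  frontal_midline  = "Fz",
  parietal_midline = "Pz",
  temporal_midline = "Cz")

# Channels recorded but not assigned to an analysis ROI (explicitly unassigned)
EEG_UNASSIGNED <- c("Fp1", "Fp2", "F7", "F8", "C3", "C4", "CP1", "CP2", "Oz")

FNIRS_ROI_CHANNELS <- list(
  frontal_left   = c("FPz-Fp1", "FPz-AF3", "AFF7-AF3", "F5-AF3", "F5-F7",
                     "AF3-AFz"),
  frontal_right  = c("FPz-Fp2", "FPz-AF4", "AF8-Fp2", "AF8-AF4", "F6-AF4",
                     "F6-F8", "AF4-AFz"),
  temporal_left  = c("FT7-T7", "TP7-T7", "C5-T7"),
  temporal_right = c("FT8-T8", "TP8-T8", "C6-T8"),
  parietal_left  = c("P5-P3", "P5-CP5", "P3-CP3"),
  parietal_right = c("P6-P4", "P6-CP6", "P4-CP4"))

FNIRS_UNASSIGNED <- c("F7-FT7", "F8-FT8", "FC3-C3", "FC4-C4", "FC1-Cz",
                      "FC2-Cz", "C1-CP1", "C2-CP2", "CP1-P1", "CP2-P2",
                      "PO3-O1", "PO4-O2", "POz-Oz", "TP9-P7", "TP10-P8",
                      "FT9-FT7", "FT10-FT8", "PO7-PO3")

# Region label per short channel (used for long->short pairing)
FNIRS_SHORT_REGION <- c(S1 = "frontal_left", S2 = "frontal_right",
                        S3 = "temporal_left", S4 = "temporal_right",
                        S5 = "parietal_left", S6 = "parietal_right",
                        S7 = "frontal_midline", S8 = "central")

#' EEG channel labels of the default 32-channel montage
#' @return Character vector of 32 labels (10-20 extended system).
#' @export
eeg_channels <- function() {
  unname(c(unlist(EEG_ROI_CHANNELS), EEG_UNASSIGNED))
}

#' Default fNIRS channel geometry (43 long + 8 short channels)
#'
#' Long channels use a 30 mm source-detector separation, short channels 8 mm.
#' Each long channel is paired with the short channel of its scalp region for
#' short-channel regression; the pairing is shipped explicitly and can be
#' overridden.
#'
#' @return A data.frame with columns `channel`, `source`, `detector`,
#'   `separation_mm`, `is_short`, `short_pair`, `region`.
#' @export
fnirs_geometry <- function() {
  long_roi <- rep(names(FNIRS_ROI_CHANNELS), lengths(FNIRS_ROI_CHANNELS))
  long <- c(unname(unlist(FNIRS_ROI_CHANNELS)), FNIRS_UNASSIGNED)
  region <- c(long_roi, rep("unassigned", length(FNIRS_UNASSIGNED)))
  # region -> nearest short channel
  short_of <- c(frontal_left = "S1", frontal_right = "S2",
                temporal_left = "S3", temporal_right = "S4",
                parietal_left = "S5", parietal_right = "S6",
                unassigned = "S8")
  sd_split <- strsplit(long, "-", fixed = TRUE)
  long_df <- data.frame(
    channel = long,
    source = vapply(sd_split, `[`, "", 1L),
    detector = vapply(sd_split, `[`, "", 2L),
    separation_mm = 30, is_short = FALSE,
    short_pair = unname(short_of[region]),
    region = region, stringsAsFactors = FALSE)
  short_df <- data.frame(
    channel = names(FNIRS_SHORT_REGION),
    source = names(FNIRS_SHORT_REGION), detector = "short",
    separation_mm = 8, is_short = TRUE, short_pair = NA_character_,
    region = unname(FNIRS_SHORT_REGION), stringsAsFactors = FALSE)
  rbind(long_df, short_df)
}

#' Default region-of-interest map
#'
#' Nine EEG ROIs (six lateral, three midline) and six fNIRS ROIs. Midline
#' ROIs exist for EEG only. `aliases` maps alternative ROI names onto
#' canonical ones (the Cz midline is referred to both as "temporal midline"
#' and "central midline" in the source protocol).
#'
#' @return A `roi_map`: list with elements `eeg` (named list of channel
#'   vectors), `fnirs` (named list of channel vectors), and `aliases`.
#' @examples
#' m <- default_roi_map()
#' m$eeg$parietal_midline
#' m$fnirs$frontal_right
#' @export
default_roi_map <- function() {
  structure(list(eeg = EEG_ROI_CHANNELS, fnirs = FNIRS_ROI_CHANNELS,
                 aliases = c(central_midline = "temporal_midline")),
            class = "roi_map")
}

# Resolve an ROI label through aliases; error on unknown label
resolve_roi <- function(roi_map, modality, label) {
  if (label %in% names(roi_map$aliases)) label <- roi_map$aliases[[label]]
  if (!label %in% names(roi_map[[modality]]))
    stop(sprintf("unknown %s ROI '%s'", modality, label), call. = FALSE)
  label
}
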