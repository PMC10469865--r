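# Montage and channel-pair definitions for the 62-channel extended 10-20
# layout used by the SEED recording system: 54 lateral channels arranged as
# 27 left/right mirror pairs plus 8 midline channels.

.pair_left <- c(
  "FP1", "AF3", "F1", "F3", "F5", "F7", "FT7", "T7", "TP7",
  "FC1", "FC3", "FC5", "C1", "C3", "C5", "CP1", "CP3", "CP5",
  "P1", "P3", "P5", "P7", "PO3", "PO5", "PO7", "O1", "CB1"
)
.pair_right <- c(
  "FP2", "AF4", "F2", "F4", "F6", "F8", "FT8", "T8", "TP8",
  "FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6",
  "P2", "P4", "P6", "P8", "PO4", "PO6", "PO8", "O2", "CB2"
)
.midline <- c("FPZ", "FZ", "FCZ", "CZ", "CPZ", "PZ", "POZ", "OZ")

#' Standard 62-channel montage
#'
#' Channel labels of the extended 10-20 montage used throughout: the 54
#' lateral channels (27 symmetric left/right pairs) plus 8 midline channels,
#' in anterior-to-posterior scan order.
#'
#' @return Character vector of 62 channel labels.
#' @export
seed_montage <- function() {
  c(
    "FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2"
  )
}

#' Midline channel labels
#'
#' The 8 channels on the centre line. They carry no left/right counterpart
#' and are discarded before asymmetry features are formed.
#'
#' @return Character vector of 8 labels.
#' @export
midline_channels <- function() .midline

#' Build the left/right channel-pair map
#'
#' Pairs the 54 lateral channels of the montage into 27 symmetric
#' (left, right) pairs, mirroring channels equidistant from the centre line.
#' Midline channels are excluded.
#'
#' @param channel_labels Character vector of available channel labels. Must
#'   contain all 54 lateral channels; extra labels (e.g. midline) are ignored.
#' @return A data.frame of class `"channel_pair_map"` with columns
#'   `pair_index` (1..27), `left` and `right`.
#' @export
build_pair_map <- function(channel_labels = seed_montage()) {
  need <- c(.pair_left, .pair_right)
  missing <- setdiff(need, channel_labels)
  if (length(missing) > 0) {
    stop_hw(
      "montage is missing required lateral channel(s): %s",
      paste(missing, collapse = ", ")
    )
  }
  if (anyDuplicated(channel_labels)) {
    stop_hw(
      "duplicated channel label(s): %s",
      paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", ")
    )
  }
  map <- data.frame(
    pair_index = seq_len(27L),
    left = .pair_left,
    right = .pair_right,
    stringsAsFactors = FALSE
  )
  class(map) <- c("channel_pair_map", "data.frame")
  map
}

#' Frequency band names
#'
#' Canonical band order used for feature indexing (pair-major, band-minor).
#'
#' @return `c("delta", "theta", "alpha", "beta", "gamma")`
#' @export
band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Canonical asymmetry feature names
#'
#' The 135 feature identifiers in canonical order: pair-major (pairs 1..27),
#' band-minor (delta, theta, alpha, beta, gamma), named `<LEFT>_<RIGHT>_<band>`.
#'
#' @param pairs A channel pair map from [build_pair_map()].
#' @return Character vector of length 135.
#' @export
feature_names <- function(pairs = build_pair_map()) {
  as.vector(t(outer(
    paste0(pairs$left, "_", pairs$right),
    band_names(),
    paste,
    sep = "_"
  )))
}

# (pair_index, band) lookup for each canonical feature position
feature_index_table <- function(pairs = build_pair_map()) {
  data.frame(
    feature = feature_names(pairs),
    pair_index = rep(pairs$pair_index, each = 5L),
    left = rep(pairs$left, each = 5L),
    right = rep(pairs$right, each = 5L),
    band = rep(band_names(), times = nrow(pairs)),
    stringsAsFactors = FALSE
  )
}
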