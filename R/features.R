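# Asymmetry features: natural-log ratios of relative wavelet band energy
# between symmetric left/right channel pairs. 27 pairs x 5 bands = 135
# features per 4-second segment, in canonical pair-major, band-minor order.

.energy_eps <- 1e-12

#' Log-ratio asymmetry of two relative energies
#'
#' `ln(E_left / E_right)` with an epsilon floor (1e-12) inside the logarithm
#' to absorb numerically zero band energies. The log of the ratio is
#' identically the difference of the logs, so the same value serves as both
#' the ratio-form feature and the difference-form statistic.
#'
#' @param e_left,e_right Relative energies (non-negative fractions);
#'   vectorized.
#' @return Numeric log-ratio(s), always finite.
#' @export
asymmetry_ratio <- function(e_left, e_right) {
  if (any(e_left < 0) || any(e_right < 0)) {
    stop_hw("relative energies must be non-negative")
  }
  log(pmax(e_left, .energy_eps)) - log(pmax(e_right, .energy_eps))
}

#' Asymmetry feature vector for one segment's band-energy table
#'
#' @param energies Channels x 5 matrix of relative band energies with channel
#'   labels as rownames and bands (`delta`..`gamma`) as colnames, covering at
#'   least the 54 paired channels.
#' @param pairs Channel pair map from [build_pair_map()].
#' @return Named numeric vector of length 135 in canonical order
#'   (pair-major, band-minor), names per [feature_names()].
#' @export
feature_vector <- function(energies, pairs = build_pair_map()) {
  missing <- setdiff(c(pairs$left, pairs$right), rownames(energies))
  if (length(missing) > 0) {
    stop_hw(
      "energy table lacks channel(s): %s",
      paste(missing, collapse = ", ")
    )
  }
  if (!identical(colnames(energies), band_names())) {
    stop_hw("energy table columns must be the five bands in canonical order")
  }
  el <- energies[pairs$left, , drop = FALSE]
  er <- energies[pairs$right, , drop = FALSE]
  vals <- asymmetry_ratio(as.vector(t(el)), as.vector(t(er)))
  names(vals) <- feature_names(pairs)
  vals
}

#' Compute the asymmetry feature table for a collection of recordings
#'
#' Runs preprocessing (optional) and feature extraction end to end: each
#' recording is resampled/filtered/segmented, each segment's 54 lateral
#' channels are decomposed with the six-level db2 transform, relative band
#' energies are formed, and the 135 pairwise log-ratios are assembled into
#' one row per segment.
#'
#' @param recordings List of `"eeg_recording"` objects, or an
#'   `"eeg_dataset"`.
#' @param preprocess If `TRUE` (default) apply [preprocess_recording()]
#'   first; if `FALSE` the recordings must already be at 200 Hz and are
#'   segmented without filtering.
#' @param target_fs,low,high,window_seconds Preprocessing parameters.
#' @return data.frame of class `"asymmetry_features"`: columns `subject_id`,
#'   `session_id`, `trial_id`, `segment_index`, `emotion`, then the 135
#'   features in canonical order.
#' @export
compute_features <- function(recordings, preprocess = TRUE, target_fs = 200,
                             low = 0.5, high = 50, window_seconds = 4) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (length(recordings) == 0) stop_hw("empty recording collection")
  pairs <- build_pair_map(recordings[[1]]$channels)
  lateral <- c(pairs$left, pairs$right)
  rows <- lapply(recordings, function(rec) {
    segs <- if (preprocess) {
      preprocess_recording(rec, target_fs, low, high, window_seconds)
    } else {
      if (rec$fs != 200) {
        stop_hw(
          "feature band map is calibrated for fs = 200 Hz (got %g); resample first",
          rec$fs
        )
      }
      segment_recording(rec, window_seconds)
    }
    if (length(segs) == 0) {
      return(NULL)
    }
    feats <- t(vapply(segs, function(s) {
      x <- t(s$data[lateral, , drop = FALSE]) # samples x channels
      en <- segment_band_energies(x, channels = lateral)
      feature_vector(en, pairs)
    }, numeric(135L)))
    meta <- data.frame(
      subject_id = rec$subject_id,
      session_id = rec$session_id,
      trial_id = rec$trial_id,
      segment_index = vapply(segs, function(s) s$segment_index, 0),
      emotion = rec$emotion,
      stringsAsFactors = FALSE
    )
    cbind(meta, as.data.frame(feats))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop_hw("no recording yielded at least one segment")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("asymmetry_features", "data.frame")
  out
}

# split a feature table into metadata and the 135-column feature matrix
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features))
  cols <- feature_names()
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0) {
    stop_hw(
      "feature table lacks %d canonical feature column(s), e.g. %s",
      length(missing), missing[1]
    )
  }
  as.matrix(features[, cols])
}
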