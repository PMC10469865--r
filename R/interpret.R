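# Interpretation: average per-fold coefficients, rank extremes, and expand
# log-ratio coefficients into signed per-channel, per-band associations.
# A positive coefficient on pair (x, y) at band b means the left channel's
# relative energy is directly related to the emotion and the right
# channel's inversely; the expansion makes this explicit while reproducing
# the linear predictor identically.

#' Average coefficients across LOGO folds
#'
#' Element-wise arithmetic mean of the 135-length embedded coefficient
#' vectors; zeros from unselected features are included in the average.
#'
#' @param folds A `"logo_result"` (list of fold results, one emotion).
#' @return Object of class `"averaged_model"`: list with `emotion`,
#'   `omega_bar` (length 135, named), `n_folds`, and the frozen pooled
#'   `center`/`scale` carried over for external validation.
#' @export
average_coefficients <- function(folds) {
  if (length(folds) == 0) stop_hw("no folds to average")
  emotions <- unique(vapply(folds, function(f) f$emotion, ""))
  if (length(emotions) != 1L) {
    stop_hw("folds mix emotions: %s", paste(emotions, collapse = ", "))
  }
  omega <- rowMeans(vapply(folds, function(f) f$omega, numeric(135L)))
  structure(
    list(
      emotion = emotions,
      omega_bar = omega,
      n_folds = length(folds),
      center = attr(folds, "center"),
      scale = attr(folds, "scale")
    ),
    class = "averaged_model"
  )
}

#' Expand pairwise coefficients to per-channel associations
#'
#' Each coefficient omega at (pair (x, y), band b) contributes `+omega` to
#' the left channel x and `-omega` to the right channel y at band b, so that
#' `sum_i omega_i * f_i = sum_{ch,b} value[ch,b] * log E[ch,b]` exactly.
#'
#' @param model An `"averaged_model"` (or any named 135-vector via
#'   `omega_bar`).
#' @param pairs Channel pair map.
#' @return Object of class `"channel_association_map"`: 54 x 5 numeric
#'   matrix (channels x bands) with attributes `emotion` and `normalized`.
#' @export
expand_to_channels <- function(model, pairs = build_pair_map()) {
  omega <- if (inherits(model, "averaged_model")) model$omega_bar else model
  if (length(omega) != 135L) stop_hw("expected 135 coefficients, got %d", length(omega))
  idx <- feature_index_table(pairs)
  channels <- c(pairs$left, pairs$right)
  value <- matrix(
    0, length(channels), 5L,
    dimnames = list(channels, band_names())
  )
  for (i in seq_len(nrow(idx))) {
    value[idx$left[i], idx$band[i]] <- value[idx$left[i], idx$band[i]] + omega[i]
    value[idx$right[i], idx$band[i]] <- value[idx$right[i], idx$band[i]] - omega[i]
  }
  structure(
    value,
    class = c("channel_association_map", "matrix", "array"),
    emotion = if (inherits(model, "averaged_model")) model$emotion else NA_character_,
    normalized = FALSE
  )
}

#' Highest and lowest k averaged coefficients
#'
#' @param model An `"averaged_model"`.
#' @param k How many from each end (default 5).
#' @return List with data.frames `highest` and `lowest` (columns `feature`,
#'   `pair_index`, `left`, `right`, `band`, `value`), sorted by value
#'   descending/ascending with deterministic ties (pair index, then band
#'   order).
#' @export
top_k_coefficients <- function(model, k = 5L) {
  stopifnot(inherits(model, "averaged_model"))
  if (k > 135L) stop_hw("k must be <= 135")
  idx <- feature_index_table()
  idx$value <- as.numeric(model$omega_bar)
  band_rank <- match(idx$band, band_names())
  hi <- idx[order(-idx$value, idx$pair_index, band_rank), ][seq_len(k), ]
  lo <- idx[order(idx$value, idx$pair_index, band_rank), ][seq_len(k), ]
  rownames(hi) <- rownames(lo) <- NULL
  list(highest = hi, lowest = lo)
}

#' Normalize an association map by its maximum absolute value
#'
#' Divides by the maximum absolute value, preserving signs; idempotent.
#'
#' @param map A `"channel_association_map"`.
#' @return Normalized map with at least one entry at +/-1.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "channel_association_map"))
  m <- max(abs(map))
  if (m == 0) stop_hw("cannot normalize an all-zero association map")
  out <- map / m
  attr(out, "normalized") <- TRUE
  attr(out, "emotion") <- attr(map, "emotion")
  class(out) <- class(map)
  out
}

#' Export an association map as a long topography table
#'
#' @param map A `"channel_association_map"`.
#' @param path Output CSV path (optional; when NULL the table is only
#'   returned).
#' @return data.frame with columns `emotion`, `channel`, `band`, `value`,
#'   `normalized`, sorted by (band, channel); written to `path` when given.
#' @export
export_topography <- function(map, path = NULL) {
  stopifnot(inherits(map, "channel_association_map"))
  out <- expand.grid(
    channel = rownames(map), band = colnames(map),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out$value <- map[cbind(out$channel, out$band)]
  out <- data.frame(
    emotion = attr(map, "emotion"),
    out[order(out$band, out$channel), ],
    normalized = isTRUE(attr(map, "normalized")),
    stringsAsFactors = FALSE
  )[, c("emotion", "channel", "band", "value", "normalized")]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
  }
  out
}
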