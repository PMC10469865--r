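# Containers for EEG trials and 4-second analysis windows.

#' Construct an EEG recording
#'
#' One trial's multi-channel signal with its sampling rate, montage labels and
#' identifying metadata.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param subject_id,session_id,trial_id Identifiers (coerced to character).
#' @param emotion Emotion label for the trial.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, channels, subject_id, session_id,
                          trial_id, emotion) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_hw("'data' must be a numeric channels x samples matrix")
  }
  if (length(channels) != nrow(data)) {
    stop_hw(
      "channel label count (%d) does not match data rows (%d)",
      length(channels), nrow(data)
    )
  }
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop_hw("recording contains non-finite samples")
  }
  rownames(data) <- channels
  structure(
    list(
      data = data,
      fs = fs,
      channels = as.character(channels),
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      trial_id = as.character(trial_id),
      emotion = as.character(emotion)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s session %s trial %s (%s): %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$session_id, x$trial_id, x$emotion,
    nrow(x$data), ncol(x$data), x$fs
  ))
  invisible(x)
}

#' Metadata of a recording collection
#'
#' @param recordings List of `"eeg_recording"` objects.
#' @return data.frame with one row per recording: subject_id, session_id,
#'   trial_id, emotion, fs, n_channels, n_samples.
#' @export
recording_manifest <- function(recordings) {
  if (length(recordings) == 0) stop_hw("empty recording collection")
  do.call(rbind, lapply(recordings, function(r) {
    data.frame(
      subject_id = r$subject_id,
      session_id = r$session_id,
      trial_id = r$trial_id,
      emotion = r$emotion,
      fs = r$fs,
      n_channels = nrow(r$data),
      n_samples = ncol(r$data),
      stringsAsFactors = FALSE
    )
  }))
}
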