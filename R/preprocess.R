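# Preprocessing: resampling to 200 Hz, 0.5-50 Hz Butterworth band-pass
# (order 4, applied forward-backward for zero phase) and non-overlapping
# 4-second segmentation.

#' Resample a recording to a lower sampling rate
#'
#' Integer-factor decimation with a windowed-sinc anti-alias low-pass applied
#' beforehand (cutoff at 90% of the target Nyquist frequency). Upsampling and
#' non-integer rate ratios are outside the supported workflow.
#'
#' @param rec An `"eeg_recording"`.
#' @param target_fs Target sampling rate in Hz (default 200).
#' @return The resampled `"eeg_recording"`; returned unchanged if
#'   `rec$fs == target_fs`.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(target_fs, "target_fs", positive = TRUE)
  if (rec$fs == target_fs) {
    return(rec)
  }
  if (rec$fs < target_fs) {
    stop_hw(
      "upsampling (%g -> %g Hz) is not supported; recordings must be acquired at >= target rate",
      rec$fs, target_fs
    )
  }
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop_hw(
      "sampling-rate ratio %g/%g is not an integer; only integer decimation is supported",
      rec$fs, target_fs
    )
  }
  factor <- as.integer(round(factor))
  h <- fir_lowpass(n_taps = 10L * factor + 1L, cutoff_norm = 0.9 / (2 * factor))
  keep <- seq.int(1L, ncol(rec$data), by = factor)
  out <- t(apply(rec$data, 1L, function(x) fir_filter(h, x)[keep]))
  eeg_recording(
    out, target_fs, rec$channels,
    rec$subject_id, rec$session_id, rec$trial_id, rec$emotion
  )
}

#' Band-pass filter a recording
#'
#' Order-4 Butterworth band-pass applied forward-backward (zero phase) to
#' each channel independently.
#'
#' @param rec An `"eeg_recording"`.
#' @param low,high Pass-band edges in Hz (defaults 0.5 and 50).
#' @param order Butterworth prototype order (default 4).
#' @return Filtered `"eeg_recording"`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 50, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  ba <- butter_bandpass(order = order, low = low, high = high, fs = rec$fs)
  out <- t(apply(rec$data, 1L, function(x) filtfilt_iir(ba$b, ba$a, x)))
  eeg_recording(
    out, rec$fs, rec$channels,
    rec$subject_id, rec$session_id, rec$trial_id, rec$emotion
  )
}

#' Cut a recording into non-overlapping windows
#'
#' Splits the trial into consecutive `window_seconds` windows starting at
#' sample 1; a trailing remainder shorter than one window is discarded.
#'
#' @param rec An `"eeg_recording"` at 200 Hz.
#' @param window_seconds Window length in seconds (default 4).
#' @return List of `"eeg_segment"` objects (possibly empty), each holding a
#'   channels x (window_seconds * fs) matrix plus parent identifiers and a
#'   0-based `segment_index`.
#' @export
segment_recording <- function(rec, window_seconds = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(window_seconds, "window_seconds", positive = TRUE)
  wlen <- window_seconds * rec$fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop_hw("window_seconds * fs must be an integer sample count")
  }
  wlen <- as.integer(round(wlen))
  n_seg <- ncol(rec$data) %/% wlen
  if (n_seg == 0) {
    return(list())
  }
  lapply(seq_len(n_seg) - 1L, function(i) {
    structure(
      list(
        data = rec$data[, (i * wlen + 1L):((i + 1L) * wlen), drop = FALSE],
        fs = rec$fs,
        channels = rec$channels,
        subject_id = rec$subject_id,
        session_id = rec$session_id,
        trial_id = rec$trial_id,
        segment_index = i,
        emotion = rec$emotion
      ),
      class = "eeg_segment"
    )
  })
}

#' Standard preprocessing for one recording
#'
#' Resample to `target_fs`, band-pass filter, and segment; the composition of
#' [resample_recording()], [bandpass_filter()] and [segment_recording()].
#' Filtering precedes segmentation so filter edge effects are confined to
#' trial boundaries.
#'
#' @param rec An `"eeg_recording"`.
#' @param target_fs Target sampling rate (default 200 Hz).
#' @param low,high Band-pass edges in Hz.
#' @param window_seconds Segmentation window (default 4 s).
#' @return List of `"eeg_segment"` objects.
#' @export
preprocess_recording <- function(rec, target_fs = 200, low = 0.5, high = 50,
                                 window_seconds = 4) {
  rec <- resample_recording(rec, target_fs)
  rec <- bandpass_filter(rec, low = low, high = high)
  segment_recording(rec, window_seconds = window_seconds)
}
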