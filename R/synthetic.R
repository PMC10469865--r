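# Synthetic EEG with planted hemispheric asymmetries.
#
# Signal model per channel: five band-limited stochastic oscillations (one
# per named EEG band), a broadband 1/f^k background, and a "rest" component
# confined to the unnamed wavelet levels (d1: 50-100 Hz and a6: < 1.56 Hz).
# At the 200 Hz fast path the oscillations are realized in the analysis
# wavelet basis (random db2 coefficients confined to the band's level), so a
# planted multiplicative energy gain on a band's component translates
# directly into the relative wavelet energy the feature stage measures. An
# asymmetry effect with log-effect L multiplies the targeted band's energy
# by exp(+L/2) on the left channel and exp(-L/2) on the right channel of
# each targeted pair, and the "rest" component absorbs the difference so
# per-channel total energy stays hemisphere-symmetric; the pairwise
# log-energy-ratio therefore has expectation L while untargeted cells stay
# at 0. The expected in-band share of the 1/f background is subtracted from
# each band's component energy so the planted log-ratio is not diluted.

#' Declare a planted asymmetry effect
#'
#' @param emotion Targeted emotion label.
#' @param band One of `delta`, `theta`, `alpha`, `beta`, `gamma`.
#' @param pairs `"all"` or an integer vector of pair indices (1..27).
#' @param log_effect Target mean of `log(E_left / E_right)` for the targeted
#'   cells (dimensionless; positive means more relative energy on the left).
#' @return Object of class `"asymmetry_effect"`.
#' @export
asymmetry_effect <- function(emotion, band, pairs = "all", log_effect) {
  if (!band %in% band_names()) {
    stop_hw("unknown band '%s'; expected one of %s", band, paste(band_names(), collapse = ", "))
  }
  assert_scalar_number(log_effect, "log_effect")
  if (!identical(pairs, "all")) {
    pairs <- as.integer(pairs)
    if (any(pairs < 1L | pairs > 27L)) stop_hw("pair indices must be in 1..27")
  }
  structure(
    list(
      emotion = as.character(emotion), band = band,
      pairs = pairs, log_effect = log_effect
    ),
    class = "asymmetry_effect"
  )
}

#' Specify a synthetic EEG dataset
#'
#' The default geometry mirrors a 62-channel, 200 Hz recording protocol with
#' balanced emotion labels per session.
#'
#' @param n_subjects,n_sessions Counts (>= 1).
#' @param trials_per_session_per_emotion Trials per emotion per session.
#' @param trial_duration Trial length in seconds; `trial_duration * fs` must
#'   be an integer.
#' @param fs Sampling rate in Hz (200 is the calibrated fast path; higher
#'   integer multiples of 200 use Fourier-domain band synthesis and are meant
#'   to exercise the resampling stage).
#' @param montage Ordered channel labels; must contain all 54 lateral
#'   channels exactly once.
#' @param emotions Emotion label set.
#' @param band_profiles Positive baseline weights for the five named bands
#'   (normalized internally).
#' @param asymmetry_effects List of [asymmetry_effect()] objects.
#' @param subject_sd SD of the per-subject, per-band log-normal gain.
#' @param noise_exponent Spectral slope k of the 1/f^k background.
#' @param noise_weight,rest_weight Energy shares of the broadband background
#'   and of the unnamed-level rest component (the remainder goes to the five
#'   named bands).
#' @param rms_total Overall signal scale, microvolts RMS.
#' @param seed Integer seed; all randomness derives deterministically from it.
#' @return Object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_subjects = 15L,
                           n_sessions = 3L,
                           trials_per_session_per_emotion = 6L,
                           trial_duration = 120,
                           fs = 200,
                           montage = seed_montage(),
                           emotions = c("neutral", "sad", "fear", "happy"),
                           band_profiles = c(
                             delta = 0.28, theta = 0.21,
                             alpha = 0.21, beta = 0.16, gamma = 0.14
                           ),
                           asymmetry_effects = list(),
                           subject_sd = 0.2,
                           noise_exponent = 1,
                           noise_weight = 0.10,
                           rest_weight = 0.12,
                           rms_total = 30,
                           seed = 1L) {
  for (nm in c("n_subjects", "n_sessions", "trials_per_session_per_emotion")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop_hw("'%s' must be an integer >= 1", nm)
    }
  }
  assert_scalar_number(trial_duration, "trial_duration", positive = TRUE)
  assert_scalar_number(fs, "fs", positive = TRUE)
  n_samples <- trial_duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop_hw("trial_duration * fs must yield an integer sample count")
  }
  if (!setequal(names(band_profiles), band_names()) ||
    any(band_profiles <= 0)) {
    stop_hw("band_profiles must be positive weights named after the five bands")
  }
  build_pair_map(montage) # validates lateral coverage and duplicates
  if (length(emotions) < 1) stop_hw("at least one emotion label required")
  stopifnot(noise_weight >= 0, rest_weight >= 0, noise_weight + rest_weight < 1)
  if (inherits(asymmetry_effects, "asymmetry_effect")) {
    asymmetry_effects <- list(asymmetry_effects)
  }
  for (eff in asymmetry_effects) {
    stopifnot(inherits(eff, "asymmetry_effect"))
    if (!eff$emotion %in% emotions) {
      stop_hw("effect targets emotion '%s' not in the label set", eff$emotion)
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sessions = as.integer(n_sessions),
      trials_per_session_per_emotion = as.integer(trials_per_session_per_emotion),
      trial_duration = trial_duration,
      fs = fs,
      montage = montage,
      emotions = emotions,
      band_profiles = band_profiles[band_names()],
      asymmetry_effects = asymmetry_effects,
      subject_sd = subject_sd,
      noise_exponent = noise_exponent,
      noise_weight = noise_weight,
      rest_weight = rest_weight,
      rms_total = rms_total,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' SEED-IV-style generator layout
#'
#' 15 subjects x 3 sessions x 24 trials (6 per emotion), 62 channels; trial
#' duration defaults to 120 s (the source protocol's roughly 2-minute clips)
#' but may be shortened for desk-scale runs.
#'
#' @param ... Overrides passed to [generator_spec()].
#' @return `"generator_spec"`.
#' @export
seed_iv_spec <- function(...) {
  args <- list(
    n_subjects = 15L, n_sessions = 3L,
    trials_per_session_per_emotion = 6L, trial_duration = 120
  )
  args[names(list(...))] <- list(...)
  do.call(generator_spec, args)
}

#' SEED-V-style generator layout (disgust excluded)
#'
#' 16 subjects x 3 sessions x 3 trials per retained emotion.
#'
#' @param ... Overrides passed to [generator_spec()].
#' @return `"generator_spec"`.
#' @export
seed_v_spec <- function(...) {
  args <- list(
    n_subjects = 16L, n_sessions = 3L,
    trials_per_session_per_emotion = 3L, trial_duration = 120
  )
  args[names(list(...))] <- list(...)
  do.call(generator_spec, args)
}

# frequency interval of a named band (200 Hz dyadic convention)
band_freq_range <- function(band) {
  map <- band_level_map()
  row <- map[!is.na(map$band) & map$band == band, ]
  if (nrow(row) == 0) stop_hw("unknown band label '%s'", band)
  c(row$low_hz, row$high_hz)
}

#' Generate a band-limited stochastic oscillation
#'
#' `method = "fourier"` draws white noise and confines it to the band's
#' frequency interval with a brick-wall spectral mask (all spectral power in
#' band, sample RMS normalized exactly). `method = "wavelet"` draws random
#' db2 coefficients confined to the band's decomposition level (requires
#' `fs = 200`); its wavelet energy sits entirely at the band's level at the
#' cost of some spectral leakage outside the nominal interval.
#'
#' @param band Band label (`delta`..`gamma`).
#' @param rms Target sample RMS (microvolts); 0 yields an all-zero waveform.
#' @param duration Length in seconds; `duration * fs` must be an integer.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param method `"fourier"` (default) or `"wavelet"`.
#' @return Numeric waveform of `duration * fs` samples.
#' @export
generate_band_limited_component <- function(band, rms, duration, fs = 200,
                                            seed = 1L,
                                            method = c("fourier", "wavelet")) {
  method <- match.arg(method)
  fr <- band_freq_range(band)
  assert_scalar_number(rms, "rms")
  if (rms < 0) stop_hw("'rms' must be >= 0")
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop_hw("duration * fs must be an integer")
  n <- as.integer(round(n))
  if (rms == 0) {
    return(numeric(n))
  }
  with_seed(seed, {
    if (method == "fourier") {
      x <- band_noise_block(n, fs, fr[1], fr[2], channels = 1L)[, 1L]
    } else {
      if (fs != 200) stop_hw("wavelet-domain synthesis requires fs = 200")
      x <- wavelet_band_block(n, band, energy = 1, channels = 1L)[, 1L]
    }
    x * (rms / rms(x))
  })
}

# Fourier brick-wall band noise, samples x channels, unit RMS per channel
band_noise_block <- function(n, fs, lo, hi, channels) {
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  mask <- f >= lo & f <= hi
  if (!any(mask)) stop_hw("band [%g, %g] Hz empty at this resolution", lo, hi)
  z <- stats::mvfft(matrix(stats::rnorm(n * channels), n, channels))
  z[!mask, ] <- 0
  x <- Re(stats::mvfft(z, inverse = TRUE)) / n
  scale <- sqrt(colMeans(x^2))
  sweep(x, 2L, pmax(scale, .Machine$double.eps), "/")
}

# number of coefficients per component for the padded plan of length n
dwt_plan_sizes <- function(n, levels = 6L) {
  np <- n + (2^levels - n %% 2^levels) %% 2^levels
  sizes <- np / 2^seq_len(levels)
  c(d = sizes, a = sizes[levels])
}

# wavelet-domain band component: random db2 coefficients at the band's
# level, inverse transform, truncated to n samples; expected total energy
# `energy` per channel (sum of squares over the padded plan)
wavelet_band_block <- function(n, band, energy, channels) {
  level <- c(gamma = 2L, beta = 3L, alpha = 4L, theta = 5L, delta = 6L)[[band]]
  sizes <- dwt_plan_sizes(n)
  d <- lapply(seq_len(6L), function(j) {
    if (j == level) {
      matrix(stats::rnorm(sizes[j] * channels, sd = sqrt(energy / sizes[j])),
        sizes[j], channels
      )
    } else {
      matrix(0, sizes[j], channels)
    }
  })
  dec <- list(d = d, a = matrix(0, sizes[7L], channels), n = n, levels = 6L)
  idwt_mat(dec)
}

# rest component confined to the unnamed a6 level (< 1.56 Hz); per-channel
# energies given by the vector `energy`. Kept out of d1 (50-100 Hz) so the
# hemisphere-balancing energy largely survives the 0.5-50 Hz band-pass.
rest_block <- function(n, energy, channels) {
  sizes <- dwt_plan_sizes(n)
  zero <- function(j) matrix(0, sizes[j], channels)
  a6 <- matrix(stats::rnorm(sizes[7L] * channels), sizes[7L], channels)
  a6 <- sweep(a6, 2L, sqrt(energy / sizes[7L]), "*")
  dec <- list(
    d = lapply(1:6, zero), a = a6, n = n, levels = 6L
  )
  idwt_mat(dec)
}

# 1/f^k background: FFT-shaped white noise over [0.5, fs/2] Hz,
# samples x channels, expected energy 1 per channel; attribute "band_share"
# gives the exact spectral share of each named band under the envelope
pink_block <- function(n, fs, exponent, channels) {
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  env <- numeric(n)
  sel <- f >= 0.5 & f <= fs / 2
  env[sel] <- f[sel]^(-exponent / 2)
  env <- env / sqrt(sum(env^2))
  shares <- vapply(band_names(), function(b) {
    fr <- band_freq_range(b)
    sum(env[f >= fr[1] & f < fr[2]]^2)
  }, 0)
  z <- stats::mvfft(matrix(stats::rnorm(n * channels), n, channels))
  x <- Re(stats::mvfft(z * env, inverse = TRUE)) / n # expected energy 1/channel
  attr(x, "band_share") <- shares
  x
}

# per-channel energy gain factors implied by the planted effects for one
# (emotion, band): named vector over montage channels, default 1
effect_gains <- function(spec, emotion, band, pairs) {
  gains <- rep(1, length(spec$montage))
  names(gains) <- spec$montage
  for (eff in spec$asymmetry_effects) {
    if (eff$emotion != emotion || eff$band != band) next
    idx <- if (identical(eff$pairs, "all")) pairs$pair_index else eff$pairs
    gains[pairs$left[idx]] <- gains[pairs$left[idx]] * exp(eff$log_effect / 2)
    gains[pairs$right[idx]] <- gains[pairs$right[idx]] * exp(-eff$log_effect / 2)
  }
  gains
}

# energy shares (fractions of rms_total^2) per component for every channel
# of one subject/emotion: list(named = 5 x channels, rest = channels, noise
# = scalar share)
channel_energy_plan <- function(spec, subject_gain, emotion, pairs, noise_share) {
  nch <- length(spec$montage)
  named_total <- 1 - spec$noise_weight - spec$rest_weight
  w <- spec$band_profiles / sum(spec$band_profiles) * named_total
  named <- matrix(0, 5L, nch, dimnames = list(band_names(), spec$montage))
  for (b in band_names()) {
    gains <- effect_gains(spec, emotion, b, pairs)
    named[b, ] <- w[[b]] * subject_gain[[b]] * gains
  }
  # subtract the background's expected in-band energy so the measured band
  # energy matches the planted target; floor at a small positive value
  comp <- spec$noise_weight * noise_share[band_names()]
  named_c <- pmax(named - comp, 1e-4)
  total_target <- sum(w * subject_gain) + spec$rest_weight + spec$noise_weight
  rest <- total_target - spec$noise_weight - colSums(named_c)
  if (any(rest <= 0)) {
    stop_hw(
      "rest_weight %.3f too small to absorb the planted asymmetries; increase it",
      spec$rest_weight
    )
  }
  list(named = named_c, rest = rest)
}

# generate one trial deterministically from the spec and its indices
generate_trial <- function(spec, subject, session, trial, emotion, pairs,
                           subject_gain) {
  fs <- spec$fs
  n <- as.integer(round(spec$trial_duration * fs))
  nch <- length(spec$montage)
  trial_seed <- derive_seed(spec$seed, "trial", subject, session, trial)
  scale2 <- spec$rms_total^2
  with_seed(trial_seed, {
    block_len <- as.integer(4 * fs)
    n_blocks <- ceiling(n / block_len)
    noise <- pink_block(block_len, fs, spec$noise_exponent, 1L)
    plan <- channel_energy_plan(
      spec, subject_gain, emotion, pairs,
      noise_share = attr(noise, "band_share")
    )
    blocks <- vector("list", n_blocks)
    for (k in seq_len(n_blocks)) {
      x <- matrix(0, block_len, nch)
      for (b in band_names()) {
        energy <- plan$named[b, ] * scale2 * block_len
        if (fs == 200) {
          comp <- wavelet_band_block(block_len, b, energy = 1, channels = nch)
          comp <- sweep(comp, 2L, sqrt(energy), "*")
        } else {
          fr <- band_freq_range(b)
          comp <- band_noise_block(block_len, fs, fr[1], fr[2], channels = nch)
          comp <- sweep(comp, 2L, sqrt(energy / block_len), "*")
        }
        x <- x + comp
      }
      x <- x + rest_block(block_len, plan$rest * scale2 * block_len, nch)
      pb <- pink_block(block_len, fs, spec$noise_exponent, nch)
      x <- x + pb * sqrt(spec$noise_weight * scale2 * block_len)
      blocks[[k]] <- x
    }
    data <- t(do.call(rbind, blocks)[seq_len(n), , drop = FALSE])
    eeg_recording(
      data, fs, spec$montage,
      subject_id = sprintf("S%02d", subject),
      session_id = as.character(session),
      trial_id = as.character(trial),
      emotion = emotion
    )
  })
}

subject_band_gain <- function(spec, subject) {
  g <- with_seed(
    derive_seed(spec$seed, "subject", subject),
    exp(stats::rnorm(5L, 0, spec$subject_sd))
  )
  names(g) <- band_names()
  g
}

#' Generate a labeled synthetic EEG dataset
#'
#' Produces `n_subjects * n_sessions * (n_emotions *
#' trials_per_session_per_emotion)` recordings with balanced emotion labels
#' per session. Identical spec and seed reproduce the dataset bit for bit.
#'
#' @param spec A `"generator_spec"`.
#' @param subjects Optional subset of subject indices to generate (used for
#'   streaming large datasets subject by subject).
#' @return List of `"eeg_recording"` objects, class `"eeg_dataset"`.
#' @export
generate_dataset <- function(spec, subjects = seq_len(spec$n_subjects)) {
  stopifnot(inherits(spec, "generator_spec"))
  pairs <- build_pair_map(spec$montage)
  n_trials <- length(spec$emotions) * spec$trials_per_session_per_emotion
  emo_seq <- rep(spec$emotions, times = spec$trials_per_session_per_emotion)
  out <- list()
  for (s in subjects) {
    gain <- subject_band_gain(spec, s)
    for (sess in seq_len(spec$n_sessions)) {
      for (t in seq_len(n_trials)) {
        out[[length(out) + 1L]] <- generate_trial(
          spec, s, sess, t, emo_seq[t], pairs, gain
        )
      }
    }
  }
  class(out) <- c("eeg_dataset", "list")
  out
}

#' Generate features directly, one subject at a time
#'
#' Streaming composition of [generate_dataset()] and [compute_features()]
#' that never holds more than one subject's raw signal in memory. Output is
#' identical to computing features on the full generated dataset.
#'
#' @param spec A `"generator_spec"`.
#' @param preprocess Apply the band-pass/resampling stage (default `TRUE`).
#' @param ... Passed to [compute_features()].
#' @return An `"asymmetry_features"` data.frame.
#' @export
simulate_features <- function(spec, preprocess = TRUE, ...) {
  parts <- lapply(seq_len(spec$n_subjects), function(s) {
    compute_features(
      generate_dataset(spec, subjects = s),
      preprocess = preprocess, ...
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("asymmetry_features", "data.frame")
  out
}
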