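# In-code fixture builders shared across test files. Feature tables are
# built directly (Gaussian log-ratios) wherever the full signal pipeline is
# not itself under test; EEG-level fixtures use small generator specs.

# feature table with n_seg segments per (subject, emotion); optional mean
# shifts are a named list feature -> list(emotion, delta)
make_feature_table <- function(n_subjects = 4, n_seg = 10, sd = 0.3,
                               shifts = list(), seed = 1,
                               emotions = c("neutral", "sad", "fear", "happy")) {
  set.seed(seed)
  fn <- hemiwave::feature_names()
  rows <- expand.grid(
    segment_index = seq_len(n_seg) - 1L,
    emotion = emotions,
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    stringsAsFactors = FALSE
  )
  n <- nrow(rows)
  X <- matrix(stats::rnorm(n * length(fn), 0, sd), n, length(fn))
  colnames(X) <- fn
  for (f in names(shifts)) {
    sel <- rows$emotion == shifts[[f]]$emotion
    X[sel, f] <- X[sel, f] + shifts[[f]]$delta
  }
  out <- cbind(
    data.frame(
      subject_id = rows$subject_id,
      session_id = "1",
      trial_id = "1",
      segment_index = rows$segment_index,
      emotion = rows$emotion,
      stringsAsFactors = FALSE
    ),
    as.data.frame(X)
  )
  class(out) <- c("asymmetry_features", "data.frame")
  out
}

# small EEG generator spec for fast structural tests
tiny_spec <- function(...) {
  args <- list(
    n_subjects = 2L, n_sessions = 1L, trials_per_session_per_emotion = 1L,
    trial_duration = 8, fs = 200, seed = 11L
  )
  args[names(list(...))] <- list(...)
  do.call(hemiwave::generator_spec, args)
}

# brute-force two-sided exact signed-rank p-value by enumerating all 2^n
# sign assignments of the observed absolute ranks
enumerate_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  total <- 2^n
  v_all <- vapply(seq_len(total) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, 0)
  p_le <- sum(v_all <= v_obs) / total
  p_ge <- sum(v_all >= v_obs) / total
  min(1, 2 * min(p_le, p_ge))
}

# random positive relative-energy table over the 54 lateral channels
random_energy_table <- function(seed = 1) {
  set.seed(seed)
  pairs <- hemiwave::build_pair_map()
  ch <- c(pairs$left, pairs$right)
  en <- matrix(stats::runif(length(ch) * 5, 0.05, 0.3),
    length(ch), 5,
    dimnames = list(ch, hemiwave::band_names())
  )
  en
}
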