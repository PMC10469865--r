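# Experiment 1: per (pair, band, emotion) cell, the median log-energy
# difference eta, a two-sided Wilcoxon signed-rank test of symmetry about
# zero, and Bonferroni control over the full 27 x 5 x 4 = 540-cell family.

#' Pool the log-difference sample for one cell
#'
#' Collects the segment-level log-energy differences for one
#' (pair, band, emotion) cell, pooled across subjects, sessions and trials.
#'
#' @param features An `"asymmetry_features"` table.
#' @param pair_index Pair index 1..27.
#' @param band Band name.
#' @param emotion Emotion label.
#' @return Numeric vector of per-segment log differences.
#' @export
collect_deltas <- function(features, pair_index, band, emotion) {
  idx <- feature_index_table()
  col <- idx$feature[idx$pair_index == pair_index & idx$band == band]
  if (length(col) != 1L) stop_hw("unknown (pair %s, band %s) cell", pair_index, band)
  rows <- features$emotion == emotion
  if (!any(rows)) {
    stop_hw(
      "no segments with emotion '%s' for cell (pair %d, %s)",
      emotion, pair_index, band
    )
  }
  features[rows, col]
}

#' Wilcoxon signed-rank test of symmetry about zero
#'
#' Two-sided test. Zero differences are discarded (Wilcoxon's rule). The
#' exact signed-rank distribution is used for n <= 25 when the absolute
#' values are tie-free; otherwise a normal approximation with tie correction
#' and continuity correction is applied.
#'
#' @param x Numeric sample of differences.
#' @param exact_max Largest zero-trimmed n for which the exact distribution
#'   is used (default 25).
#' @return List with `W` (the smaller of the positive- and negative-rank
#'   sums), `V` (positive-rank sum), `n` (zero-trimmed sample size),
#'   `p_value`, and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 25L) {
  if (anyNA(x)) stop_hw("sample contains NA")
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) stop_hw("all differences are zero; test undefined")
  if (n < 5) stop_hw("need at least 5 non-zero differences (got %d)", n)
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  w_neg <- n * (n + 1) / 2 - v
  w <- min(v, w_neg)
  ties <- anyDuplicated(abs(x)) > 0
  if (n <= exact_max && !ties) {
    p <- min(1, 2 * stats::psignrank(w, n))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(W = w, V = v, n = n, p_value = p, exact = exact)
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector (the full test family).
#' @param alpha_family Family-wise error target (default 0.05).
#' @return List with logical `significant` flags, `corrected_alpha`
#'   (`alpha_family / m`) and `n_tests`.
#' @export
bonferroni <- function(p_values, alpha_family = 0.05) {
  m <- length(p_values)
  if (m == 0) stop_hw("empty p-value family")
  list(
    significant = p_values < alpha_family / m,
    corrected_alpha = alpha_family / m,
    n_tests = m
  )
}

#' Build the full asymmetry test matrix
#'
#' One Wilcoxon signed-rank test per (pair, band, emotion) cell over the
#' segment-pooled log differences, with Bonferroni correction over all cells
#' jointly.
#'
#' @param features An `"asymmetry_features"` table containing all four
#'   emotions.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param emotions Emotion labels to include (default: those present, in
#'   first-appearance order).
#' @return data.frame of class `"asymmetry_matrix"`, one row per cell:
#'   `pair_index`, `pair_left`, `pair_right`, `band`, `emotion`, `n`, `eta`
#'   (median log difference), `W`, `p_value`, `significant`; attributes
#'   `n_tests` and `corrected_alpha`.
#' @export
build_asymmetry_matrix <- function(features, alpha_family = 0.05,
                                   emotions = unique(features$emotion)) {
  idx <- feature_index_table()
  cells <- expand.grid(
    feature_row = seq_len(nrow(idx)),
    emotion = emotions,
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(cells)), function(i) {
    fr <- idx[cells$feature_row[i], ]
    sample <- features[features$emotion == cells$emotion[i], fr$feature]
    if (length(sample) == 0) {
      stop_hw("empty cell (pair %d, %s, %s)", fr$pair_index, fr$band, cells$emotion[i])
    }
    test <- wilcoxon_signed_rank(sample)
    data.frame(
      pair_index = fr$pair_index,
      pair_left = fr$left,
      pair_right = fr$right,
      band = fr$band,
      emotion = cells$emotion[i],
      n = test$n,
      eta = stats::median(sample),
      W = test$W,
      p_value = test$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  corr <- bonferroni(out$p_value, alpha_family)
  out$significant <- corr$significant
  attr(out, "n_tests") <- corr$n_tests
  attr(out, "corrected_alpha") <- corr$corrected_alpha
  class(out) <- c("asymmetry_matrix", "data.frame")
  out
}
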