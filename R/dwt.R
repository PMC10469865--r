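# Six-level Daubechies-2 discrete wavelet transform and relative band energy.
#
# The transform is orthonormal: coefficients are computed by periodized
# convolution after zero-padding the input to the next multiple of 2^levels,
# so Parseval's identity (sum of squared coefficients equals signal energy)
# holds exactly for any input length, and perfect reconstruction is available.
#
# At fs = 200 Hz the dyadic levels map onto the classical EEG bands:
#   d1 50-100 Hz (unnamed), d2 gamma 25-50, d3 beta 12.5-25,
#   d4 alpha 6.25-12.5, d5 theta 3.125-6.25, d6 delta 1.5625-3.125,
#   a6 < 1.5625 Hz (unnamed).

# db2 analysis filters; g is the quadrature mirror of h
.db2_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db2_g <- rev(.db2_h) * c(1, -1, 1, -1)

#' Band-to-level frequency map at 200 Hz
#'
#' @return data.frame with columns `level`, `low_hz`, `high_hz`, `band`
#'   (NA for the unnamed d1 and a6 components).
#' @export
band_level_map <- function() {
  data.frame(
    component = c("d1", "d2", "d3", "d4", "d5", "d6", "a6"),
    level = c(1, 2, 3, 4, 5, 6, 6),
    low_hz = c(50, 25, 12.5, 6.25, 3.125, 1.5625, 0),
    high_hz = c(100, 50, 25, 12.5, 6.25, 3.125, 1.5625),
    band = c(NA, "gamma", "beta", "alpha", "theta", "delta", NA),
    stringsAsFactors = FALSE
  )
}

# one analysis step on a matrix (samples x channels); n must be even
dwt_step_mat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  base_idx <- seq.int(0L, n - 2L, by = 2L)
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  for (m in 0:3) {
    idx <- ((base_idx + m) %% n) + 1L
    a <- a + .db2_h[m + 1] * x[idx, , drop = FALSE]
    d <- d + .db2_g[m + 1] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# one synthesis step: (a, d) matrices (half x channels) -> (n x channels)
idwt_step_mat <- function(a, d) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0, n, ncol(a))
  base_idx <- seq.int(0L, n - 2L, by = 2L)
  for (m in 0:3) {
    idx <- ((base_idx + m) %% n) + 1L
    x[idx, ] <- x[idx, ] + .db2_h[m + 1] * a + .db2_g[m + 1] * d
  }
  x
}

# full decomposition of a samples x channels matrix (internal work-horse)
dwt_mat <- function(x, levels = 6L) {
  n0 <- nrow(x)
  if (n0 < 2^levels) {
    stop_hw(
      "input length %d too short for a %d-level transform (need >= %d samples)",
      n0, levels, 2^levels
    )
  }
  pad <- (2^levels - n0 %% 2^levels) %% 2^levels
  if (pad > 0) x <- rbind(x, matrix(0, pad, ncol(x)))
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step_mat(a)
    d[[j]] <- s$d
    a <- s$a
  }
  list(d = d, a = a, n = n0, pad = pad, levels = levels)
}

idwt_mat <- function(dec) {
  a <- dec$a
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step_mat(a, dec$d[[j]])
  }
  a[seq_len(dec$n), , drop = FALSE]
}

#' Six-level db2 wavelet decomposition of one channel
#'
#' Decomposes a single-channel segment with the Daubechies-2 wavelet into
#' detail coefficients `d1`..`d6` and the level-6 approximation `a6`. The
#' input is zero-padded to the next multiple of `2^levels` and transformed
#' with periodized orthonormal convolution, so the total coefficient energy
#' equals the signal energy exactly.
#'
#' @param x Numeric vector (one channel of a segment), length >= `2^levels`.
#' @param levels Number of decomposition levels (default 6).
#' @return Object of class `"wavelet_decomposition"`: list with elements
#'   `d` (list of detail coefficient vectors, finest first), `a`
#'   (approximation coefficients), `n` (original length), `levels`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, length.out = 801)[1:800])
#' dec <- dwt_decompose(x)
#' sum(vapply(dec$d, function(z) sum(z^2), 0)) + sum(dec$a^2) - sum(x^2)
#' @export
dwt_decompose <- function(x, levels = 6L) {
  if (!is.numeric(x)) stop_hw("input must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop_hw("input contains non-finite values")
  dec <- dwt_mat(matrix(x, ncol = 1L), levels = levels)
  out <- list(
    d = lapply(dec$d, function(m) m[, 1L]),
    a = dec$a[, 1L],
    n = dec$n,
    pad = dec$pad,
    levels = dec$levels
  )
  class(out) <- "wavelet_decomposition"
  out
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverse of [dwt_decompose()]; reproduces the input to machine precision.
#'
#' @param dec A `"wavelet_decomposition"` object.
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  m <- list(
    d = lapply(dec$d, function(v) matrix(v, ncol = 1L)),
    a = matrix(dec$a, ncol = 1L),
    n = dec$n,
    levels = dec$levels
  )
  idwt_mat(m)[, 1L]
}

# level energies for a samples x channels matrix: 7 x channels matrix with
# rows d1..d6, a6
level_energies_mat <- function(x, levels = 6L) {
  dec <- dwt_mat(x, levels = levels)
  en <- t(vapply(
    dec$d,
    function(m) colSums(m^2),
    numeric(ncol(x))
  ))
  rbind(en, colSums(dec$a^2))
}

#' Relative band energy of one decomposed channel
#'
#' Shares of total wavelet energy per named EEG band. The energy of detail
#' level `k` is the sum of its squared coefficients; the total is taken over
#' all components (`d1`..`d6` and `a6`), so the five named band shares sum to
#' at most 1 and the seven component shares sum to exactly 1.
#'
#' @param dec A `"wavelet_decomposition"` object with 6 levels (from
#'   [dwt_decompose()]).
#' @return Named numeric vector over `c("delta","theta","alpha","beta","gamma")`
#'   with attributes `E_total` (total energy) and `components` (all seven
#'   relative component energies).
#' @export
relative_band_energy <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  if (dec$levels != 6L) {
    stop_hw("band map requires a 6-level decomposition (got %d)", dec$levels)
  }
  en <- c(
    vapply(dec$d, function(z) sum(z^2), 0),
    sum(dec$a^2)
  )
  names(en) <- c(paste0("d", 1:6), "a6")
  total <- sum(en)
  if (total == 0) stop_hw("degenerate all-zero segment: total energy is 0")
  rel <- en / total
  out <- rel[c("d6", "d5", "d4", "d3", "d2")]
  names(out) <- band_names()
  attr(out, "E_total") <- total
  attr(out, "components") <- rel
  out
}

# relative band energies for a segment matrix (samples x channels):
# returns channels x 5 matrix (delta..gamma), plus per-channel totals
segment_band_energies <- function(x, channels = colnames(x)) {
  en <- level_energies_mat(x) # 7 x channels, rows d1..d6, a6
  totals <- colSums(en)
  if (any(totals == 0)) {
    stop_hw(
      "degenerate all-zero segment in channel(s): %s",
      paste(channels[totals == 0], collapse = ", ")
    )
  }
  rel <- t(en[c(6, 5, 4, 3, 2), , drop = FALSE]) / totals
  dimnames(rel) <- list(channels, band_names())
  attr(rel, "E_total") <- totals
  rel
}
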