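# IIR/FIR filtering primitives: Butterworth band-pass design via bilinear
# transform, zero-phase forward-backward application, and FIR anti-alias
# decimation. Implemented here because no signal-processing package is
# available in the target environment; the design was validated coefficient-
# for-coefficient against scipy.signal.butter.

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, ri * p)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog prototype poles, low-pass to band-pass transform with frequency
#' pre-warping, then bilinear transform.
#'
#' @param order Filter order of the low-pass prototype (the band-pass filter
#'   has `2 * order` poles). Default 4.
#' @param low,high Pass-band edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order = 4L, low, high, fs) {
  assert_scalar_number(low, "low", positive = TRUE)
  assert_scalar_number(high, "high", positive = TRUE)
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (low >= high) stop_hw("'low' (%g) must be < 'high' (%g)", low, high)
  if (high >= fs / 2) {
    stop_hw("'high' (%g Hz) must be below the Nyquist frequency (%g Hz)", high, fs / 2)
  }
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  pb <- complex(0)
  for (pp in p) {
    disc <- sqrt((pp * bw / 2)^2 - w0^2)
    pb <- c(pb, pp * bw / 2 + disc, pp * bw / 2 - disc)
  }
  zb <- rep(0 + 0i, order)
  fs2 <- 2 * fs
  pz <- (fs2 + pb) / (fs2 - pb)
  zz <- c((fs2 + zb) / (fs2 - zb), rep(-1 + 0i, length(pb) - length(zb)))
  kz <- Re(bw^order * prod(fs2 - zb) / prod(fs2 - pb))
  list(
    b = Re(kz * poly_from_roots(zz)),
    a = Re(poly_from_roots(pz))
  )
}

# causal IIR filter (direct form I) with step-response initial conditions so
# that a constant input produces its steady-state output immediately
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a) - 1L
  xp <- c(rep(x[1], nb - 1L), x)
  u <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  u <- u[nb:length(xp)]
  if (na > 0) {
    y0 <- x[1] * sum(b) / sum(a)
    as.numeric(stats::filter(u, -a[-1], method = "recursive", init = rep(y0, na)))
  } else {
    u
  }
}

# zero-phase forward-backward filtering with odd reflection padding
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * max(length(a), length(b))
  if (n <= pad) {
    stop_hw("signal too short for zero-phase filtering (need > %d samples)", pad)
  }
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# windowed-sinc (Hamming) low-pass FIR; cutoff in normalized (0, 0.5) of fs
fir_lowpass <- function(n_taps, cutoff_norm) {
  stopifnot(n_taps %% 2L == 1L)
  m <- (n_taps - 1L) / 2L
  k <- -m:m
  h <- 2 * cutoff_norm * sinc(2 * cutoff_norm * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# symmetric FIR filtering with reflection padding (zero phase by symmetry)
fir_filter <- function(h, x) {
  m <- (length(h) - 1L) / 2L
  n <- length(x)
  if (n <= m) stop_hw("signal too short for FIR filtering")
  xp <- c(2 * x[1] - x[(m + 1):2], x, 2 * x[n] - x[(n - 1):(n - m)])
  y <- as.numeric(stats::filter(xp, h, method = "convolution", sides = 2))
  y[(m + 1):(m + n)]
}
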