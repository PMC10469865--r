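# Resampling, band-pass filtering, segmentation.

make_rec <- function(data, fs, emotion = "neutral") {
  eeg_recording(
    data, fs, paste0("CH", seq_len(nrow(data))),
    subject_id = "S01", session_id = "1", trial_id = "1", emotion = emotion
  )
}

test_that("1000 Hz downsamples to 200 Hz preserving duration and tones", {
  t <- (0:(1000 * 20 - 1)) / 1000
  rec <- make_rec(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 3 * t)), 1000)
  out <- resample_recording(rec, 200)
  expect_equal(out$fs, 200)
  expect_equal(ncol(out$data), 20 * 200)
  # dominant periodogram peak still at 10 Hz within one bin
  sp <- Mod(fft(out$data[1, ]))^2
  freqs <- (seq_along(sp) - 1) * 200 / length(sp)
  half <- freqs < 100
  expect_lt(abs(freqs[half][which.max(sp[half])] - 10), 200 / length(sp) + 1e-9)
})

test_that("matching rate is identity and upsampling is refused", {
  rec <- make_rec(matrix(rnorm(400), 2), 200)
  expect_identical(resample_recording(rec, 200), rec)
  expect_error(resample_recording(rec, 400), "upsampl")
  expect_error(resample_recording(make_rec(matrix(rnorm(900), 2), 300), 200), "integer")
})

test_that("band-pass kills DC, keeps 10 Hz, crushes 70 Hz", {
  t <- (0:(200 * 10 - 1)) / 200
  trim <- 201:1800
  dc <- bandpass_filter(make_rec(matrix(5, 1, length(t)), 200))
  expect_lt(max(abs(dc$data[1, trim])), 0.1)
  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(make_rec(matrix(s10, 1), 200))$data[1, ]
  expect_lt(abs(sqrt(mean(y10[trim]^2)) / sqrt(mean(s10[trim]^2)) - 1), 0.05)
  s70 <- sin(2 * pi * 70 * t)
  y70 <- bandpass_filter(make_rec(matrix(s70, 1), 200))$data[1, ]
  expect_lt(sqrt(mean(y70[trim]^2)) / sqrt(mean(s70[trim]^2)), 0.1)
})

test_that("band edge above Nyquist is rejected", {
  rec <- make_rec(matrix(rnorm(2000), 1), 200)
  expect_error(bandpass_filter(rec, high = 100), "Nyquist")
})

test_that("filtering acts per channel and preserves channel order", {
  set.seed(1)
  x <- matrix(rnorm(2 * 2000), 2)
  rec <- make_rec(x, 200)
  out <- bandpass_filter(rec)
  solo <- bandpass_filter(make_rec(x[2, , drop = FALSE], 200))
  expect_equal(out$data[2, ], solo$data[1, ], tolerance = 1e-12)
  expect_identical(out$channels, rec$channels)
})

test_that("segmentation counts, indices and partition are exact", {
  rec <- make_rec(matrix(seq_len(148 * 200 * 2), 2, byrow = TRUE), 200)
  segs <- segment_recording(rec)
  expect_length(segs, 37L)
  expect_identical(vapply(segs, function(s) s$segment_index, 0), as.numeric(0:36))
  # no overlap, no gap: concatenation reproduces the leading floor multiple
  recon <- do.call(cbind, lapply(segs, function(s) s$data))
  expect_identical(recon, rec$data[, 1:(37 * 800)])
  expect_length(segment_recording(make_rec(matrix(0, 1, 780), 200)), 0L)
  two <- segment_recording(make_rec(matrix(seq_len(1700), 1), 200))
  expect_length(two, 2L)
  expect_equal(two[[1]]$data[1, ], 1:800, ignore_attr = TRUE)
  expect_equal(two[[2]]$data[1, ], 801:1600, ignore_attr = TRUE)
})

test_that("segments inherit parent identifiers", {
  rec <- make_rec(matrix(rnorm(1600), 1), 200, emotion = "fear")
  s <- segment_recording(rec)[[2]]
  expect_identical(s$emotion, "fear")
  expect_identical(s$subject_id, "S01")
  expect_identical(s$segment_index, 1L)
})
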