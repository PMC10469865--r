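# Generator: band components, dataset structure, determinism, calibration.

test_that("Fourier band components honor spectral confinement and RMS", {
  for (b in band_names()) {
    x <- generate_band_limited_component(b, rms = 2.5, duration = 4, seed = 3)
    expect_equal(sqrt(mean(x^2)), 2.5, tolerance = 0.05 * 2.5)
    sp <- Mod(fft(x))^2
    f <- pmin((seq_along(x) - 1) * 200 / length(x), 200 - (seq_along(x) - 1) * 200 / length(x))
    fr <- hemiwave:::band_freq_range(b)
    in_band <- sum(sp[f >= fr[1] & f <= fr[2]]) / sum(sp)
    expect_gte(in_band, 0.9)
  }
})

test_that("alpha component maximizes alpha relative energy downstream", {
  for (method in c("fourier", "wavelet")) {
    x <- generate_band_limited_component(
      "alpha",
      rms = 1, duration = 4, seed = 1, method = method
    )
    rel <- relative_band_energy(dwt_decompose(x))
    expect_identical(names(which.max(rel)), "alpha")
  }
})

test_that("zero amplitude and seed contracts hold", {
  expect_identical(
    generate_band_limited_component("delta", 0, 4),
    numeric(800)
  )
  a <- generate_band_limited_component("delta", 1, 4, seed = 1)
  b <- generate_band_limited_component("delta", 1, 4, seed = 2)
  expect_false(isTRUE(all.equal(a, b)))
  expect_equal(sqrt(mean(a^2)), sqrt(mean(b^2)), tolerance = 0.1)
  expect_identical(a, generate_band_limited_component("delta", 1, 4, seed = 1))
  expect_error(generate_band_limited_component("mu", 1, 4), "mu")
})

test_that("dataset geometry and label balance match the spec", {
  spec <- tiny_spec(n_subjects = 2, trials_per_session_per_emotion = 2)
  ds <- generate_dataset(spec)
  expect_length(ds, 2 * 1 * 4 * 2)
  meta <- recording_manifest(ds)
  counts <- table(meta$subject_id, meta$emotion)
  expect_true(all(counts == 2))
  expect_true(all(vapply(ds, function(r) nrow(r$data) == 62, TRUE)))
  expect_true(all(vapply(ds, function(r) ncol(r$data) == 8 * 200, TRUE)))
})

test_that("identical spec and seed reproduce the dataset bit for bit", {
  s1 <- generate_dataset(tiny_spec())
  s2 <- generate_dataset(tiny_spec())
  expect_identical(s1, s2)
  s3 <- generate_dataset(tiny_spec(seed = 12L))
  expect_false(identical(s1[[1]]$data, s3[[1]]$data))
})

test_that("streaming per-subject generation equals the monolithic dataset", {
  spec <- tiny_spec()
  full <- compute_features(generate_dataset(spec), preprocess = FALSE)
  streamed <- simulate_features(spec, preprocess = FALSE)
  expect_equal(full, streamed, tolerance = 1e-12)
})

test_that("SEED-IV-style layout yields 72 recordings per subject", {
  spec <- seed_iv_spec(n_subjects = 1, trial_duration = 4, seed = 5)
  ds <- generate_dataset(spec, subjects = 1)
  expect_length(ds, 72L)
  per_session <- table(recording_manifest(ds)$session_id)
  expect_true(all(per_session == 24))
})

test_that("invalid specs are rejected", {
  expect_error(generator_spec(trial_duration = 1.001, fs = 200), "integer")
  expect_error(generator_spec(montage = seed_montage()[-1]), "FP1")
  expect_error(generator_spec(n_subjects = 0), "n_subjects")
  expect_error(
    generator_spec(asymmetry_effects = list(
      asymmetry_effect("disgust", "alpha", "all", 0.5)
    )),
    "disgust"
  )
  expect_error(asymmetry_effect("sad", "sigma", "all", 0.5), "sigma")
})

test_that("planted effect is calibrated and untargeted cells stay null", {
  # single effect, >= 500 target-emotion segments, features straight off the
  # generator (the band-pass stage is exercised separately)
  spec <- generator_spec(
    n_subjects = 5, n_sessions = 1, trials_per_session_per_emotion = 5,
    trial_duration = 80, fs = 200,
    asymmetry_effects = list(asymmetry_effect("sad", "alpha", "all", 0.6)),
    seed = 21
  )
  feats <- simulate_features(spec, preprocess = FALSE)
  sad <- feats[feats$emotion == "sad", ]
  expect_gte(nrow(sad), 500L)
  alpha_cols <- grep("_alpha$", feature_names(), value = TRUE)
  expect_lt(abs(mean(as.matrix(sad[, alpha_cols])) - 0.6), 0.1)
  # untargeted bands for the target emotion
  for (b in c("delta", "theta", "beta", "gamma")) {
    cols <- grep(paste0("_", b, "$"), feature_names(), value = TRUE)
    expect_lt(abs(mean(as.matrix(sad[, cols]))), 0.05)
  }
  # untargeted emotions in the targeted band
  other <- feats[feats$emotion != "sad", ]
  expect_lt(abs(mean(as.matrix(other[, alpha_cols]))), 0.05)
})

test_that("fixture round-trips recordings exactly", {
  ds <- generate_dataset(tiny_spec(trial_duration = 4))
  dir <- tempfile("fixture")
  mpath <- write_fixture(ds, dir)
  expect_length(list.files(dir, pattern = "^rec_.*csv$"), length(ds))
  back <- read_recordings(mpath)
  expect_length(back, length(ds))
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$data, ds[[i]]$data)
    expect_identical(back[[i]]$emotion, ds[[i]]$emotion)
    expect_identical(back[[i]]$subject_id, ds[[i]]$subject_id)
  }
  expect_error(write_fixture(list(), tempfile()), "empty")
})
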