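# Coefficient averaging, channel expansion, ranking, normalization.

fake_fold <- function(omega, emotion = "sad", subject = "S01") {
  names(omega) <- feature_names()
  list(
    emotion = emotion, held_out_subject = subject, omega = omega,
    selected_mask = omega != 0, phi_star = 0.5, C_star = 1,
    metrics_train = NULL, metrics_test = NULL
  )
}

test_that("averaging includes embedded zeros and records fold count", {
  o1 <- numeric(135)
  o1[1] <- 1
  o2 <- numeric(135)
  o2[1] <- -1
  m <- average_coefficients(list(fake_fold(o1), fake_fold(o2)))
  expect_equal(m$omega_bar[[1]], 0)
  expect_equal(m$n_folds, 2L)
  same <- average_coefficients(list(fake_fold(o1), fake_fold(o1), fake_fold(o1)))
  expect_equal(unname(same$omega_bar), o1)
  expect_error(
    average_coefficients(list(fake_fold(o1), fake_fold(o2, emotion = "happy"))),
    "mix"
  )
})

test_that("a single coefficient expands with pairwise antisymmetry", {
  omega <- numeric(135)
  names(omega) <- feature_names()
  omega["FT7_FT8_gamma"] <- 0.5
  map <- expand_to_channels(omega)
  expect_equal(map["FT7", "gamma"], 0.5)
  expect_equal(map["FT8", "gamma"], -0.5)
  expect_equal(sum(map != 0), 2L)
})

test_that("expanded map reproduces the linear predictor exactly", {
  set.seed(31)
  pairs <- build_pair_map()
  omega <- rnorm(135)
  names(omega) <- feature_names()
  map <- expand_to_channels(omega)
  for (rep in 1:100) {
    en <- random_energy_table(seed = rep)
    f <- feature_vector(en, pairs)
    lin_ratio <- sum(omega * f)
    lin_channel <- sum(map * log(en[rownames(map), colnames(map)]))
    expect_lt(abs(lin_ratio - lin_channel), 1e-10)
  }
  # pairwise antisymmetry of the whole map
  expect_equal(map[pairs$left, ], -map[pairs$right, ],
    ignore_attr = TRUE, tolerance = 1e-12
  )
})

test_that("top-k ranking is value-sorted with deterministic ties", {
  omega <- numeric(135)
  omega[42] <- 0.7
  omega[10] <- -0.3
  m <- structure(
    list(
      emotion = "happy", omega_bar = stats::setNames(omega, feature_names()),
      n_folds = 1L
    ),
    class = "averaged_model"
  )
  tk <- top_k_coefficients(m, k = 5)
  expect_identical(tk$highest$feature[1], feature_names()[42])
  expect_identical(tk$lowest$feature[1], feature_names()[10])
  expect_equal(nrow(tk$highest), 5L)
  # zero ties fall back to pair index then band order
  expect_identical(tk$lowest$feature[2], feature_names()[1])
})

test_that("normalization scales to unit max, preserves signs, idempotent", {
  omega <- numeric(135)
  omega[5] <- 2
  omega[20] <- -1
  map <- expand_to_channels(stats::setNames(omega, feature_names()))
  nm <- normalize_map(map)
  expect_equal(max(abs(nm)), 1)
  expect_identical(sign(as.numeric(nm)), sign(as.numeric(map)))
  expect_equal(as.numeric(normalize_map(nm)), as.numeric(nm), tolerance = 1e-12)
  zero <- expand_to_channels(stats::setNames(numeric(135), feature_names()))
  expect_error(normalize_map(zero), "all-zero")
})

test_that("topography export is long, sorted, and round-trips", {
  omega <- stats::setNames(rnorm(135), feature_names())
  map <- normalize_map(expand_to_channels(omega))
  attr(map, "emotion") <- "fear"
  path <- tempfile(fileext = ".csv")
  tab <- export_topography(map, path)
  expect_equal(nrow(tab), 270L)
  expect_identical(tab$band, sort(tab$band))
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_true(all(back$normalized))
})
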