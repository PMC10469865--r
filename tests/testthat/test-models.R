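# Binarization, ANOVA-F selection, penalized fits, LOGO CV, metrics.

test_that("one-vs-all binarization", {
  expect_identical(
    binarize_labels(c("happy", "sad", "happy"), "happy"),
    c(1L, 0L, 1L)
  )
  expect_error(binarize_labels(c("happy", "sad"), "disgust"), "disgust")
  expect_identical(binarize_labels(rep("sad", 3), "sad"), rep(1L, 3))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 20), n)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 0.8
  mask <- anova_f_select(X, y)
  f_vals <- attr(mask, "F_values")
  for (j in seq_len(ncol(X))) {
    t_stat <- t.test(X[y == 1, j], X[y == 0, j], var.equal = TRUE)$statistic
    expect_equal(f_vals[j], unname(t_stat)^2, tolerance = 1e-9)
  }
  expect_true(all(mask[1:3]))
})

test_that("constant and uninformative features are excluded", {
  set.seed(4)
  y <- rep(c(0L, 1L), each = 100)
  X <- cbind(const = 1, noise = rnorm(200), signal = y + rnorm(200, 0, 0.01))
  mask <- anova_f_select(X, y)
  expect_false(mask[1])
  expect_true(mask[3])
  expect_equal(attr(mask, "p_values")[[1]], 1)
})

test_that("extreme regularization shrinks all coefficients to near zero", {
  set.seed(8)
  X <- matrix(rnorm(200 * 5), 200)
  y <- rep(c(0L, 1L), each = 100)
  beta <- fit_elasticnet_logistic(X, y, phi = 0.5, C = 1e-6)
  expect_true(all(abs(beta) < 1e-3))
})

test_that("an informative feature gets a positive coefficient", {
  set.seed(9)
  y <- rep(c(0L, 1L), each = 250)
  X <- cbind(
    sig = ifelse(y == 1, 1, -1) + rnorm(500, 0, 0.3),
    junk = rnorm(500)
  )
  beta <- fit_elasticnet_logistic(X, y, phi = 0.5, C = 1)
  expect_gt(beta[1], 0)
  expect_error(fit_elasticnet_logistic(X, rep(1L, 500), 0.5, 1), "single class")
})

test_that("C follows the inverse-strength convention", {
  set.seed(10)
  y <- rep(c(0L, 1L), each = 100)
  X <- cbind(ifelse(y == 1, 1, -1) + rnorm(200, 0, 0.5), rnorm(200))
  b_weak <- fit_elasticnet_logistic(X, y, 0.5, C = 100)
  b_strong <- fit_elasticnet_logistic(X, y, 0.5, C = 0.01)
  expect_gt(abs(b_weak[1]), abs(b_strong[1]))
})

test_that("default grids have the stated cardinality", {
  cfg <- model_config()
  expect_length(cfg$phi_grid, 11L)
  expect_length(cfg$C_grid, 6L)
  expect_equal(length(cfg$phi_grid) * length(cfg$C_grid), 66L)
  expect_false(cfg$fit_intercept)
})

test_that("degenerate one-point grid is returned without search", {
  cfg <- model_config(phi_grid = 0.3, C_grid = 10)
  res <- nested_grid_search(matrix(0, 4, 2), c(0, 1, 0, 1), letters[1:4], cfg)
  expect_equal(res$phi_star, 0.3)
  expect_equal(res$C_star, 10)
})

test_that("strong signal steers the search away from full shrinkage", {
  set.seed(30)
  n_sub <- 6
  rows_per <- 40
  groups <- rep(sprintf("S%d", 1:n_sub), each = rows_per)
  y <- rep(rep(c(0L, 1L), each = rows_per / 2), n_sub)
  X <- cbind(
    ifelse(y == 1, 1, -1) + rnorm(length(y), 0, 0.4),
    matrix(rnorm(length(y) * 4), ncol = 4)
  )
  res <- nested_grid_search(X, y, groups, model_config(seed = 2))
  expect_gt(res$C_star, 1e-3)
})

test_that("LOGO yields one fold per subject with disjoint splits and embedding", {
  feats <- make_feature_table(
    n_subjects = 5, n_seg = 8,
    shifts = list(FT7_FT8_alpha = list(emotion = "sad", delta = 1.5)),
    seed = 3
  )
  folds <- logo_cv(feats, "sad", model_config(
    phi_grid = c(0, 0.5, 1), C_grid = c(0.01, 1, 100), seed = 5
  ))
  expect_length(folds, 5L)
  held <- vapply(folds, function(f) f$held_out_subject, "")
  expect_identical(sort(held), sort(unique(feats$subject_id)))
  for (f in folds) {
    expect_length(f$omega, 135L)
    expect_true(all(f$omega[!f$selected_mask] == 0))
  }
  model <- average_coefficients(folds)
  expect_identical(names(which.max(abs(model$omega_bar))), "FT7_FT8_alpha")
  expect_gt(model$omega_bar[["FT7_FT8_alpha"]], 0)
})

test_that("test rows never influence the fitted coefficients", {
  feats <- make_feature_table(
    n_subjects = 4, n_seg = 6,
    shifts = list(T7_T8_gamma = list(emotion = "happy", delta = 1.2)),
    seed = 13
  )
  cfg <- model_config(phi_grid = 0.5, C_grid = 1, seed = 1)
  f1 <- logo_cv(feats, "happy", cfg)
  # scramble the held-out subject's rows: fold coefficients must not move
  tampered <- feats
  rows <- tampered$subject_id == "S01"
  set.seed(77)
  tampered[rows, feature_names()] <-
    tampered[rows, feature_names()][sample(sum(rows)), ] * 3
  f2 <- logo_cv(tampered, "happy", cfg)
  expect_equal(f1[[1]]$omega, f2[[1]]$omega, tolerance = 1e-12)
})

test_that("label-permuted data yields chance-level test AUC", {
  feats <- make_feature_table(
    n_subjects = 8, n_seg = 12,
    shifts = list(FT7_FT8_alpha = list(emotion = "sad", delta = 1.0)),
    seed = 17
  )
  cfg <- model_config(phi_grid = c(0, 1), C_grid = c(0.1, 10), seed = 9)
  aucs <- c()
  for (perm in 1:10) {
    permuted <- feats
    set.seed(100 + perm)
    permuted$emotion <- sample(permuted$emotion)
    folds <- suppressWarnings(logo_cv(permuted, "sad", cfg))
    aucs <- c(aucs, vapply(folds, function(f) f$metrics_test[["auc_roc"]], 0))
  }
  expect_gt(mean(aucs, na.rm = TRUE), 0.45)
  expect_lt(mean(aucs, na.rm = TRUE), 0.55)
})

test_that("metric set matches the hand-evaluated contingency table", {
  # TP=3, FP=1, FN=2, TN=4
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- compute_metrics(y, s)
  expect_equal(m[["sensitivity"]], 0.6)
  expect_equal(m[["specificity"]], 0.8)
  expect_equal(m[["ppv"]], 0.75)
  expect_equal(m[["npv"]], 2 / 3, tolerance = 1e-4)
  expect_equal(m[["f1"]], 2 / 3, tolerance = 1e-4)
  expect_equal(m[["g_mean"]], sqrt(0.48), tolerance = 1e-4)
  expect_equal(m[["g_mean"]]^2, m[["sensitivity"]] * m[["specificity"]],
    tolerance = 1e-12
  )
})

test_that("metric edge cases behave as documented", {
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_true(all(perfect == 1))
  flat <- compute_metrics(c(0, 1, 0, 1), rep(0.7, 4))
  expect_equal(flat[["auc_roc"]], 0.5)
  expect_warning(
    none <- compute_metrics(c(0, 1), c(0.1, 0.2)),
    "no predicted positives"
  )
  expect_equal(none[["ppv"]], 0)
  expect_equal(none[["f1"]], 0)
  single <- suppressWarnings(compute_metrics(c(1, 1), c(0.2, 0.4)))
  expect_true(is.na(single[["auc_roc"]]))
})

test_that("ranking metrics agree with small hand-computed cases", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  # ROC: pairs (1,2) pos score > neg in 3 of 4 comparisons + ties none
  expect_equal(auc_roc(y, s), 0.75)
  # AP: thresholds at 0.9 (P=1, R=.5), 0.8, 0.7 (P=2/3, R=1), 0.1
  expect_equal(auc_pr(y, s), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
})
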