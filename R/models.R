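# Experiment 2: one-vs-all elastic-net logistic regression per emotion with
# ANOVA-F feature pre-selection, leave-one-subject-out (LOGO) cross-
# validation and nested, group-aware hyperparameter search.
#
# Conventions: phi is the l1-ratio (glmnet's alpha); C is the INVERSE
# regularization strength, mapped to glmnet's penalty scale as
# lambda = 1 / (n * C); models carry no intercept; features are z-scored
# with statistics fitted on training rows only.

#' Model configuration
#'
#' @param phi_grid L1-ratio grid (default 0, 0.1, ..., 1).
#' @param C_grid Inverse-regularization-strength grid (default 1e-3..1e2 in
#'   decades).
#' @param select_alpha ANOVA-F selection threshold (default 0.05).
#' @param decision_threshold Probability cutoff for confusion metrics.
#' @param inner_folds Group-aware inner CV folds for the grid search.
#' @param seed Integer seed controlling inner-fold subject assignment.
#' @return Object of class `"model_config"`. The intercept is fixed at zero.
#' @export
model_config <- function(phi_grid = seq(0, 1, by = 0.1),
                         C_grid = 10^(-3:2),
                         select_alpha = 0.05,
                         decision_threshold = 0.5,
                         inner_folds = 3L,
                         seed = 1L) {
  stopifnot(
    all(phi_grid >= 0 & phi_grid <= 1), all(C_grid > 0),
    select_alpha > 0, select_alpha < 1, inner_folds >= 2
  )
  structure(
    list(
      phi_grid = phi_grid, C_grid = sort(C_grid),
      select_alpha = select_alpha, fit_intercept = FALSE,
      decision_threshold = decision_threshold,
      inner_folds = as.integer(inner_folds), seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' One-vs-all label binarization
#'
#' @param labels Character vector of emotion labels.
#' @param target_emotion The positive class.
#' @return Integer vector: 1 for the target emotion, 0 otherwise.
#' @export
binarize_labels <- function(labels, target_emotion) {
  if (!target_emotion %in% labels) {
    stop_hw("target emotion '%s' not present in the label set", target_emotion)
  }
  as.integer(labels == target_emotion)
}

#' ANOVA F-test univariate feature selection
#'
#' Two-group one-way ANOVA per feature column (identical to the squared
#' pooled-variance t test); features with p below `select_alpha` are kept.
#' Must be called on training rows only.
#'
#' @param X Numeric matrix (rows = segments, columns = features).
#' @param y Binary vector (both classes present).
#' @param select_alpha Significance threshold (default 0.05).
#' @return Logical mask over columns, with attributes `p_values` and
#'   `F_values`. Zero-variance features get p = 1 and are excluded.
#' @export
anova_f_select <- function(X, y, select_alpha = 0.05) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop_hw("both classes must be present")
  n <- nrow(X)
  n1 <- sum(y == 1)
  n0 <- n - n1
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((X - rep(m1, each = n) * (y == 1) -
    rep(m0, each = n) * (y == 0))^2)
  f <- ssb / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(f) & ssw == 0 & ssb == 0] <- 1
  p[is.na(p)] <- 1
  mask <- p < select_alpha
  attr(mask, "p_values") <- p
  attr(mask, "F_values") <- f
  mask
}

# lambda on glmnet's scale for inverse strength C and sample size n
lambda_for_C <- function(C, n) 1 / (n * C)

#' Fit an elastic-net penalized logistic regression
#'
#' No-intercept binomial fit at one (phi, C) point via coordinate descent
#' (glmnet), with `lambda = 1 / (n * C)` so that larger C means weaker
#' penalty. The design matrix is used as-is; standardize upstream.
#'
#' @param X Numeric matrix (already standardized).
#' @param y Binary response (both classes required).
#' @param phi L1-ratio in `[0, 1]`.
#' @param C Inverse regularization strength (> 0).
#' @return Numeric coefficient vector of length `ncol(X)`.
#' @export
fit_elasticnet_logistic <- function(X, y, phi, C) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_hw("response has a single class; cannot fit")
  n <- nrow(X)
  padded <- FALSE
  if (ncol(X) == 1L) { # glmnet requires >= 2 columns
    X <- cbind(X, 0)
    padded <- TRUE
  }
  lambda <- lambda_for_C(C, n)
  path <- lambda * c(64, 16, 4, 1) # short warm-start path ending at the target
  fit <- glmnet::glmnet(
    X, y,
    family = "binomial", alpha = phi, lambda = path,
    standardize = FALSE, intercept = FALSE, thresh = 1e-9, maxit = 1e6
  )
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  if (padded) beta <- beta[1L]
  beta
}

# per-(phi, C) mean validation AUC over group-aware inner folds;
# glmnet fits one path over all C values per (phi, fold)
inner_grid_scores <- function(X, y, groups, config) {
  subs <- sort(unique(groups))
  k <- config$inner_folds
  if (length(subs) < k) {
    stop_hw(
      "nested search needs >= %d distinct subjects in the training set (got %d)",
      k, length(subs)
    )
  }
  assign <- with_seed(
    derive_seed(config$seed, "inner", paste(subs, collapse = ",")),
    sample(rep_len(seq_len(k), length(subs)))
  )
  aucs <- array(NA_real_, c(length(config$phi_grid), length(config$C_grid), k))
  for (f in seq_len(k)) {
    val_subs <- subs[assign == f]
    val <- groups %in% val_subs
    if (length(unique(y[!val])) < 2L || length(unique(y[val])) < 2L) next
    n_tr <- sum(!val)
    lambdas <- sort(lambda_for_C(config$C_grid, n_tr), decreasing = TRUE)
    c_order <- order(config$C_grid) # lambda desc == C asc
    for (pi in seq_along(config$phi_grid)) {
      fit <- glmnet::glmnet(
        X[!val, , drop = FALSE], y[!val],
        family = "binomial", alpha = config$phi_grid[pi], lambda = lambdas,
        standardize = FALSE, intercept = FALSE, thresh = 1e-8, maxit = 1e6
      )
      scores <- X[val, , drop = FALSE] %*% fit$beta
      for (j in seq_along(lambdas)) {
        aucs[pi, c_order[j], f] <- auc_roc(y[val], scores[, j])
      }
    }
  }
  apply(aucs, c(1, 2), mean, na.rm = TRUE)
}

#' Nested grid search for (phi, C)
#'
#' Exhaustive search over `phi_grid x C_grid` using group-aware inner
#' cross-validation (no subject straddles an inner train/validation split).
#' Selection criterion: mean inner validation AUC-ROC; ties prefer smaller C
#' (stronger penalty), then smaller phi (smoother penalty).
#'
#' @param X Standardized training design matrix.
#' @param y Binary training response.
#' @param groups Subject identifier per training row.
#' @param config A `"model_config"`.
#' @return List with `phi_star`, `C_star` and the mean-AUC `grid`.
#' @export
nested_grid_search <- function(X, y, groups, config = model_config()) {
  if (length(config$phi_grid) == 1L && length(config$C_grid) == 1L) {
    return(list(
      phi_star = config$phi_grid, C_star = config$C_grid, grid = NULL
    ))
  }
  grid <- inner_grid_scores(X, y, groups, config)
  cand <- expand.grid(
    pi = seq_along(config$phi_grid), ci = seq_along(config$C_grid)
  )
  cand$auc <- grid[as.matrix(cand)]
  cand$C <- config$C_grid[cand$ci]
  cand$phi <- config$phi_grid[cand$pi]
  cand <- cand[is.finite(cand$auc), ]
  if (nrow(cand) == 0) stop_hw("no inner fold produced a usable validation AUC")
  best <- cand[order(-cand$auc, cand$C, cand$phi), ][1L, ]
  list(phi_star = best$phi, C_star = best$C, grid = grid)
}

#' Leave-one-subject-out cross-validation for one emotion
#'
#' One fold per subject. Per fold: ANOVA-F selection on training rows,
#' z-scoring fitted on training rows, nested grid search, a final
#' elastic-net logistic fit, and metrics on both sets. Coefficients are
#' re-embedded into the canonical 135-length vector with zeros at
#' unselected positions.
#'
#' @param features An `"asymmetry_features"` table.
#' @param emotion Target emotion (positive class).
#' @param config A `"model_config"`.
#' @return List of per-fold results, class `"logo_result"`; each element has
#'   `emotion`, `held_out_subject`, `omega` (length 135), `selected_mask`,
#'   `phi_star`, `C_star`, `metrics_train`, `metrics_test`. Attributes
#'   `emotion`, `center` and `scale` (pooled feature statistics over the
#'   full dataset, frozen for external validation) and `config`.
#' @export
logo_cv <- function(features, emotion, config = model_config()) {
  X <- feature_matrix(features)
  y <- binarize_labels(features$emotion, emotion)
  groups <- features$subject_id
  subs <- sort(unique(groups))
  if (length(subs) < 2L) stop_hw("LOGO needs >= 2 subjects")
  pooled_center <- colMeans(X)
  pooled_scale <- apply(X, 2L, stats::sd)
  pooled_scale[pooled_scale == 0] <- 1
  folds <- lapply(subs, function(held_out) {
    test <- groups == held_out
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    mask <- anova_f_select(Xtr, ytr, config$select_alpha)
    omega <- numeric(ncol(X))
    if (!any(mask)) {
      warning(sprintf(
        "fold %s: no feature passed selection; null model used", held_out
      ), call. = FALSE)
      phi_star <- NA_real_
      C_star <- NA_real_
      scores_tr <- rep(0.5, sum(!test))
      scores_te <- rep(0.5, sum(test))
    } else {
      Xs <- Xtr[, mask, drop = FALSE]
      ctr <- colMeans(Xs)
      scl <- apply(Xs, 2L, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(Xs, center = ctr, scale = scl)
      search <- nested_grid_search(Xs, ytr, groups[!test], config)
      phi_star <- search$phi_star
      C_star <- search$C_star
      beta <- fit_elasticnet_logistic(Xs, ytr, phi_star, C_star)
      omega[mask] <- beta
      Xte <- scale(X[test, mask, drop = FALSE], center = ctr, scale = scl)
      scores_tr <- stats::plogis(as.numeric(Xs %*% beta))
      scores_te <- stats::plogis(as.numeric(Xte %*% beta))
    }
    names(omega) <- colnames(X)
    list(
      emotion = emotion,
      held_out_subject = held_out,
      omega = omega,
      selected_mask = as.logical(mask),
      phi_star = phi_star,
      C_star = C_star,
      metrics_train = compute_metrics(ytr, scores_tr, config$decision_threshold),
      metrics_test = compute_metrics(y[test], scores_te, config$decision_threshold)
    )
  })
  structure(
    folds,
    class = c("logo_result", "list"),
    emotion = emotion,
    center = pooled_center,
    scale = pooled_scale,
    config = config
  )
}

#' Binary classification metric set
#'
#' Confusion metrics at a fixed threshold plus ranking metrics: AUC-ROC
#' (rank-based, equivalent to the trapezoidal area with tie handling) and
#' AUC-PR as average precision (step-wise interpolation).
#'
#' @param y_true Binary ground truth.
#' @param scores Predicted scores or probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector: sensitivity, specificity, ppv, npv, f1,
#'   g_mean, auc_roc, auc_pr. AUCs are NA when `y_true` has one class; PPV
#'   and F1 are 0 (with a warning) when nothing is predicted positive.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (tp + fp == 0) {
    warning("no predicted positives; PPV and F1 set to 0", call. = FALSE)
    ppv <- 0
    f1 <- 0
  } else {
    ppv <- tp / (tp + fp)
    f1 <- if (!is.na(sens) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  }
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  g <- sqrt(sens * spec)
  c(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    f1 = f1, g_mean = g,
    auc_roc = auc_roc(y_true, scores),
    auc_pr = auc_pr(y_true, scores)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; ties in scores contribute 1/2.
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`, or NA if one class is absent.
#' @export
auc_roc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores.
#' @return Average precision in `[0, 1]`, or NA if no positives.
#' @export
auc_pr <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  if (n1 == 0 || n1 == length(y_true)) {
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  # evaluate at the last index of each distinct score (thresholds)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / k[last]
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}
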