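# External validation: apply averaged coefficients as a fixed logistic model
# (no refit, no intercept) to an independent dataset and summarize
# per-subject discrimination.

#' Apply a fixed averaged model to external data
#'
#' Scores every external segment via the logistic link with the frozen
#' averaged coefficients; features are standardized with the TRAINING
#' dataset's pooled statistics (carried on the model), never with external
#' statistics. AUC-ROC is computed per external subject against one-vs-all
#' labels.
#'
#' @param model An `"averaged_model"` from [average_coefficients()].
#' @param features External `"asymmetry_features"` table (same canonical 135
#'   feature ordering). Segments of excluded emotions (e.g. disgust) must be
#'   removed upstream.
#' @param emotion Positive class; defaults to the model's emotion.
#' @return Object of class `"validation_report"`: list with `emotion`,
#'   `per_subject_auc` (named vector), `mean_auc`, `n_above_chance`, and
#'   `scores` (per-segment). Subjects lacking both classes get NA AUC and
#'   are excluded from the mean with a warning.
#' @export
apply_fixed_model <- function(model, features, emotion = model$emotion) {
  stopifnot(inherits(model, "averaged_model"))
  X <- feature_matrix(features)
  if (is.null(model$center) || is.null(model$scale)) {
    stop_hw("model carries no frozen standardization statistics")
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  scores <- stats::plogis(as.numeric(Xs %*% model$omega_bar))
  y <- binarize_labels(features$emotion, emotion)
  subjects <- sort(unique(features$subject_id))
  auc <- vapply(subjects, function(s) {
    rows <- features$subject_id == s
    auc_roc(y[rows], scores[rows])
  }, 0)
  if (anyNA(auc)) {
    warning(sprintf(
      "subject(s) %s lack both classes; excluded from the mean AUC",
      paste(subjects[is.na(auc)], collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(
      emotion = emotion,
      per_subject_auc = auc,
      mean_auc = mean(auc, na.rm = TRUE),
      n_above_chance = count_above_chance_vec(auc),
      scores = scores
    ),
    class = "validation_report"
  )
}

count_above_chance_vec <- function(auc, threshold = 0.5) {
  sum(auc >= threshold, na.rm = TRUE)
}

#' Count subjects at or above chance discrimination
#'
#' @param report A `"validation_report"`.
#' @param threshold AUC threshold, inclusive (default 0.5).
#' @return Integer count of subjects with `AUC >= threshold`.
#' @export
count_above_chance <- function(report, threshold = 0.5) {
  stopifnot(inherits(report, "validation_report"))
  if (length(report$per_subject_auc) == 0) stop_hw("empty validation report")
  count_above_chance_vec(report$per_subject_auc, threshold)
}
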