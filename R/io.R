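# Plain-text I/O: per-recording CSV containers with a manifest, feature
# tables, generator-spec and pipeline-config YAML, and the end-to-end
# experiment driver.

fmt_num <- function(x) sprintf("%.17g", x) # lossless double round-trip

#' Write recordings to disk as a fixture
#'
#' One CSV container per recording (samples x channels, header = labels,
#' 17-significant-digit text so doubles round-trip exactly) plus a
#' `manifest.csv` with columns subject_id, session_id, trial_id, emotion,
#' fs, n_channels, n_samples, file.
#'
#' @param recordings Non-empty list of `"eeg_recording"` objects.
#' @param path Directory to create/write into.
#' @return Invisibly, the manifest path.
#' @export
write_fixture <- function(recordings, path) {
  if (length(recordings) == 0) stop_hw("refusing to write an empty fixture")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop_hw("cannot create fixture directory '%s'", path)
  manifest <- recording_manifest(recordings)
  manifest$file <- sprintf(
    "rec_%s_%s_%s.csv",
    manifest$subject_id, manifest$session_id, manifest$trial_id
  )
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    m <- apply(t(rec$data), c(1, 2), fmt_num)
    colnames(m) <- rec$channels
    utils::write.table(
      m,
      file.path(path, manifest$file[i]),
      sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE
    )
  }
  mpath <- file.path(path, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read recordings from a fixture manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_fixture()]; container files are resolved relative to it.
#' @return List of validated `"eeg_recording"` objects (an `"eeg_dataset"`).
#' @export
read_recordings <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_hw("manifest not found: %s", manifest_path)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c(
    "subject_id", "session_id", "trial_id", "emotion", "fs",
    "n_channels", "n_samples", "file"
  )
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    stop_hw("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  }
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    fpath <- file.path(base, row$file)
    if (!file.exists(fpath)) {
      stop_hw("manifest row %d points to missing file '%s'", i, row$file)
    }
    m <- as.matrix(utils::read.csv(fpath, colClasses = "numeric", check.names = FALSE))
    if (ncol(m) != row$n_channels || nrow(m) != row$n_samples) {
      stop_hw(
        "row %d: container shape %dx%d disagrees with manifest (%dx%d)",
        i, nrow(m), ncol(m), row$n_samples, row$n_channels
      )
    }
    eeg_recording(
      t(m), row$fs, colnames(m),
      row$subject_id, row$session_id, row$trial_id, row$emotion
    )
  })
  class(out) <- c("eeg_dataset", "list")
  out
}

#' Write a feature table to CSV
#'
#' @param features An `"asymmetry_features"` table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  for (col in feature_names()) df[[col]] <- fmt_num(df[[col]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_features()].
#' @return An `"asymmetry_features"` data.frame.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("subject_id", "session_id", "trial_id", "emotion")) {
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("asymmetry_features", "data.frame")
  df
}

#' Serialize a generator spec to YAML
#'
#' @param spec A `"generator_spec"`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_generator_spec <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  obj <- unclass(spec)
  obj$band_profiles <- as.list(spec$band_profiles) # keep names in YAML
  obj$asymmetry_effects <- lapply(spec$asymmetry_effects, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a generator spec from YAML
#'
#' @param path YAML written by [write_generator_spec()] (or hand-authored
#'   with the same fields).
#' @return A validated `"generator_spec"`.
#' @export
read_generator_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  effects <- lapply(obj$asymmetry_effects, function(e) {
    asymmetry_effect(e$emotion, e$band, if (identical(e$pairs, "all")) "all" else unlist(e$pairs), e$log_effect)
  })
  obj$asymmetry_effects <- effects
  obj$band_profiles <- unlist(obj$band_profiles)
  obj$montage <- unlist(obj$montage)
  obj$emotions <- unlist(obj$emotions)
  do.call(generator_spec, obj)
}

# tiny FNV-1a hash of a string, for tagging outputs with their config
config_hash <- function(text) {
  h <- 2166136261
  for (code in utf8ToInt(text)) {
    h <- bitwAnd(bitwXor(as.integer(h %% 2^31), code) * 16777619, 2147483647)
  }
  sprintf("%08x", h)
}

#' Run the full two-experiment pipeline
#'
#' Generates (or loads) recordings, extracts asymmetry features, runs the
#' Wilcoxon/Bonferroni screen (Experiment 1), trains one LOGO elastic-net
#' model per emotion (Experiment 2), averages and expands coefficients, and
#' optionally validates the averaged models on an independently generated
#' dataset. All artifacts are written as CSV under `out_dir`.
#'
#' @param spec A `"generator_spec"` for the training dataset, or a manifest
#'   path to load recordings from disk.
#' @param out_dir Output directory (created if absent).
#' @param config A `"model_config"`.
#' @param emotions Emotions to model (default: all labels present).
#' @param validation_spec Optional second `"generator_spec"` (or manifest
#'   path) for fixed-model external validation.
#' @param alpha_family Family-wise alpha for Experiment 1.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `features`, `asymmetry` (Experiment 1
#'   table), `models` (per-emotion averaged models), `folds`, and
#'   `validation` reports (if requested).
#' @export
run_experiment <- function(spec, out_dir, config = model_config(),
                           emotions = NULL, validation_spec = NULL,
                           alpha_family = 0.05, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  load_feats <- function(src, tag) {
    if (inherits(src, "generator_spec")) {
      say("[%s] generating + extracting features (seed %d)...", tag, src$seed)
      simulate_features(src)
    } else {
      say("[%s] loading recordings from %s ...", tag, src)
      compute_features(read_recordings(src))
    }
  }
  features <- load_feats(spec, "train")
  say(
    "[features] %d segments x %d features", nrow(features),
    length(feature_names())
  )
  write_features(features, file.path(out_dir, "features.csv"))
  asym <- build_asymmetry_matrix(features, alpha_family = alpha_family)
  utils::write.csv(asym, file.path(out_dir, "asymmetry_matrix.csv"), row.names = FALSE)
  say(
    "[stats] %d tests, corrected alpha %.3g, %d significant",
    attr(asym, "n_tests"), attr(asym, "corrected_alpha"), sum(asym$significant)
  )
  if (is.null(emotions)) emotions <- unique(features$emotion)
  models <- list()
  folds_all <- list()
  for (emo in emotions) {
    say("[train] %s one-vs-all LOGO ...", emo)
    folds <- logo_cv(features, emo, config)
    folds_all[[emo]] <- folds
    model <- average_coefficients(folds)
    models[[emo]] <- model
    coefs <- vapply(folds, function(f) f$omega, numeric(135L))
    colnames(coefs) <- vapply(folds, function(f) f$held_out_subject, "")
    utils::write.csv(
      data.frame(feature = feature_names(), coefs, check.names = FALSE),
      file.path(out_dir, sprintf("coefficients_%s.csv", emo)),
      row.names = FALSE
    )
    met <- t(vapply(folds, function(f) f$metrics_test, numeric(8L)))
    metr <- data.frame(
      held_out_subject = vapply(folds, function(f) f$held_out_subject, ""),
      phi_star = vapply(folds, function(f) f$phi_star, 0),
      C_star = vapply(folds, function(f) f$C_star, 0),
      met
    )
    utils::write.csv(
      metr, file.path(out_dir, sprintf("metrics_%s.csv", emo)),
      row.names = FALSE
    )
    map <- normalize_map(expand_to_channels(model))
    export_topography(map, file.path(out_dir, sprintf("topography_%s.csv", emo)))
  }
  validation <- NULL
  if (!is.null(validation_spec)) {
    ext_features <- load_feats(validation_spec, "validate")
    validation <- lapply(models, function(model) {
      apply_fixed_model(model, ext_features)
    })
    vtab <- do.call(rbind, lapply(validation, function(v) {
      data.frame(
        emotion = v$emotion,
        subject = names(v$per_subject_auc),
        auc_roc = v$per_subject_auc,
        mean_auc = v$mean_auc,
        n_above_chance = v$n_above_chance,
        stringsAsFactors = FALSE
      )
    }))
    utils::write.csv(vtab, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  say("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(
    features = features, asymmetry = asym, models = models,
    folds = folds_all, validation = validation
  ))
}
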