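#' Train the full decoder from a training session
#'
#' End-to-end training: MVC calibration from the MVC trials, rest profile
#' from the resting recording, preprocessing and feature extraction on
#' every training trial, correlation-based selection of
#' `config$n_features` features for the posture classifier, one-vs-one
#' RBF-SVM training with a grid search, and per-digit random forests on the
#' 15 RMS-type features. A window-level held-out fraction (seeded) is set
#' aside before selection and model fitting and used to report held-out
#' posture accuracy and per-digit force correlations.
#'
#' @param session An `emg_session` (see [generate_training_session()]) or a
#'   compatible list with `mvc_trials`, `rest_recording` and `trials`.
#' @param config An [run_config()].
#' @param holdout_frac Fraction of windows held out for the reported
#'   metrics (0 disables).
#' @return An `emg_decoder` bundle: calibrations, feature selection and
#'   imputation means, posture and force models, config, and `holdout`
#'   metrics (`accuracy`, `force_cor`, `n`).
#' @export
train_decoder <- function(session, config = run_config(),
                          holdout_frac = 1 / 3) {
  mvc <- compute_mvc(session$mvc_trials, config$window_s)
  rest_prof <- compute_rest_profile(session$rest_recording, mvc, config)

  feats <- list(); forces <- list(); labels <- list()
  for (tr in session$trials) {
    ws <- preprocess_recording(tr$recording, mvc, config)
    f <- compute_features(ws, config)
    fw <- segment_windows(tr$forces, config$window_s)
    target <- t(apply(fw$values, c(3), colMeans))
    w <- min(nrow(f), nrow(target))
    feats[[length(feats) + 1]] <- f[seq_len(w), , drop = FALSE]
    forces[[length(forces) + 1]] <- target[seq_len(w), , drop = FALSE]
    labels[[length(labels) + 1]] <- rep(tr$pose, w)
  }
  X <- do.call(rbind, feats)
  Yf <- do.call(rbind, forces)
  y <- unlist(labels)

  set.seed(config$seed)
  n <- nrow(X)
  hold <- if (holdout_frac > 0) {
    sort(sample.int(n, round(n * holdout_frac)))
  } else integer(0)
  tr_idx <- setdiff(seq_len(n), hold)

  selection <- select_least_correlated(X[tr_idx, , drop = FALSE],
                                       k = config$n_features)
  rms_selection <- structure(
    list(descriptors = grep("^RMS:", colnames(X), value = TRUE),
         index = grep("^RMS:", colnames(X)),
         max_abs_cor = NA_real_, method = "fixed"),
    class = "feature_selection"
  )
  impute_means <- colMeans(X[tr_idx, , drop = FALSE], na.rm = TRUE)

  xsel <- apply_selection(X[tr_idx, , drop = FALSE], selection,
                          impute_means)
  posture <- train_posture_model(xsel, y[tr_idx], seed = config$seed)
  xrms <- apply_selection(X[tr_idx, , drop = FALSE], rms_selection,
                          impute_means)
  force <- train_force_model(xrms, Yf[tr_idx, , drop = FALSE],
                             n_trees = config$n_trees, seed = config$seed)

  holdout <- NULL
  if (length(hold)) {
    hsel <- apply_selection(X[hold, , drop = FALSE], selection,
                            impute_means)
    acc <- mean(predict_posture(posture, hsel)$pose == y[hold])
    hrms <- apply_selection(X[hold, , drop = FALSE], rms_selection,
                            impute_means)
    pred_f <- predict_digit_forces(force, hrms)
    force_cor <- vapply(seq_len(5), function(d) {
      stats::cor(pred_f[, d], Yf[hold, d])
    }, 0)
    names(force_cor) <- digit_names()
    holdout <- list(accuracy = acc, force_cor = force_cor,
                    n = length(hold))
  }

  structure(
    list(config = config, mvc = mvc, rest_profile = rest_prof,
         selection = selection, rms_selection = rms_selection,
         impute_means = impute_means, posture_model = posture,
         force_model = force, holdout = holdout, seed = config$seed),
    class = "emg_decoder"
  )
}

#' @export
print.emg_decoder <- function(x, ...) {
  cat("emg_decoder bundle\n")
  cat(sprintf("  posture: %d one-vs-one RBF SVMs (gamma %g, cost %g)\n",
              length(x$posture_model$classifiers), x$posture_model$gamma,
              x$posture_model$cost))
  cat(sprintf("  force: 5 random forests (%d trees)\n",
              x$force_model$n_trees))
  cat(sprintf("  features: %s\n",
              paste(x$selection$descriptors, collapse = ", ")))
  if (!is.null(x$holdout)) {
    cat(sprintf(
      "  held-out: accuracy %.1f%%, force r %s (n = %d windows)\n",
      100 * x$holdout$accuracy,
      paste(sprintf("%.2f", x$holdout$force_cor), collapse = "/"),
      x$holdout$n))
  }
  invisible(x)
}

#' Save / load a decoder bundle
#'
#' The bundle (feature selection, calibrations, SVM ensemble, forests,
#' config snapshot and seed) is serialized as a single RDS archive.
#'
#' @param decoder An `emg_decoder`.
#' @param path File path.
#' @return `load_decoder()` returns the bundle; `save_decoder()` returns
#'   `path` invisibly.
#' @export
save_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "emg_decoder"))
  saveRDS(decoder, path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "emg_decoder")) stop("not a decoder bundle", call. = FALSE)
  x
}

#' Write / read a training session as plain files
#'
#' A session directory holds one signal CSV per MVC trial, the rest
#' recording, one EMG + force CSV pair per training trial, and a
#' `session.yaml` manifest with the pose labels, focus annotations and the
#' generator spec.
#'
#' @param session An `emg_session`.
#' @param dir Directory (created if needed).
#' @return `read_session()` returns the session; `write_session()` returns
#'   `dir` invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(session$mvc_trials)) {
    write_signal_csv(session$mvc_trials[[i]],
                     file.path(dir, sprintf("mvc_%02d.csv", i)))
  }
  write_signal_csv(session$rest_recording, file.path(dir, "rest.csv"))
  manifest <- list(n_mvc = length(session$mvc_trials),
                   n_trials = length(session$trials), trials = list())
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    write_signal_csv(tr$recording,
                     file.path(dir, sprintf("trial_%02d_emg.csv", i)))
    write_signal_csv(tr$forces,
                     file.path(dir, sprintf("trial_%02d_force.csv", i)))
    manifest$trials[[i]] <- list(pose = tr$pose,
                                 focus = unique(stats::na.omit(tr$focus)))
  }
  yaml::write_yaml(manifest, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "session.yaml"))
  mvc <- lapply(seq_len(manifest$n_mvc), function(i) {
    read_signal_csv(file.path(dir, sprintf("mvc_%02d.csv", i)))
  })
  rest <- read_signal_csv(file.path(dir, "rest.csv"))
  trials <- lapply(seq_len(manifest$n_trials), function(i) {
    list(recording = read_signal_csv(
           file.path(dir, sprintf("trial_%02d_emg.csv", i))),
         forces = read_signal_csv(
           file.path(dir, sprintf("trial_%02d_force.csv", i))),
         pose = manifest$trials[[i]]$pose,
         focus = manifest$trials[[i]]$focus)
  })
  structure(list(mvc_trials = mvc, rest_recording = rest, trials = trials),
            class = "emg_session")
}
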