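#' Run the closed-loop decoding simulation over a task script
#'
#' Consumes one 50-ms window of the EMG stream per loop iteration:
#' preprocess (center, MVC-normalize, stateful notch), extract features,
#' apply the rest gate, predict posture and digit forces, smooth the total
#' grip force over the last three iterations, and record everything.
#' Iterations inside the post-command-change pause are flagged excluded.
#'
#' The rest gate dominates: when every channel's window RMS is below its
#' resting threshold the pose is `REST` and all forces are zero, regardless
#' of the model outputs. Otherwise the window is labeled according to
#' `config$fusion`: `"svm-template"` takes the one-vs-one SVM vote;
#' `"sign-pattern"` maps the signs of the predicted digit forces to a pose
#' (which can yield `UNCLASSIFIED`).
#'
#' @param decoder A trained [train_decoder()] bundle.
#' @param recording EMG [raw_recording()], at least `total_iterations *
#'   window` samples long (a shorter stream yields a truncated trace with a
#'   warning).
#' @param script A [task_script()].
#' @param config An [run_config()]; defaults to the decoder's.
#' @return A `decode_trace` data frame, one row per iteration: commanded
#'   pose/target, predicted pose, the five predicted digit forces, raw and
#'   smoothed total grip force, vote ties and the excluded flag.
#' @export
run_online_simulation <- function(decoder, recording, script,
                                  config = decoder$config) {
  stopifnot(inherits(decoder, "emg_decoder"),
            inherits(script, "task_script"))
  it <- iteration_table(script, config)
  win <- round(config$window_s * config$fs)
  n_avail <- nrow(recording$samples) %/% win
  if (n_avail < nrow(it)) {
    warning(sprintf("stream underrun: %d of %d iterations available",
                    n_avail, nrow(it)))
    it <- it[seq_len(n_avail), , drop = FALSE]
  }
  n_it <- nrow(it)
  stream <- raw_recording(
    recording$samples[seq_len(n_it * win), , drop = FALSE],
    fs = recording$fs, channel_labels = recording$channel_labels
  )
  # the per-iteration pipeline is open-loop in the signal path, so the
  # stateful preprocessing and batched prediction are exactly equivalent to
  # the iteration-by-iteration loop
  dec <- decode_windows(decoder, stream, config)

  grip <- numeric(n_it)
  smoothed <- numeric(n_it)
  for (i in seq_len(n_it)) {
    grip[i] <- as.numeric(total_grip_force(dec$forces[i, ], dec$pose[i]))
    smoothed[i] <- smooth_grip_force(grip[max(1, i - 2):i])
  }
  forces <- dec$forces
  colnames(forces) <- paste0("force_", digit_names())
  out <- data.frame(
    iteration = it$iteration,
    task = it$task,
    commanded_pose = it$commanded_pose,
    target_force = it$target_force,
    focus = it$focus,
    predicted_pose = dec$pose,
    forces,
    grip_force = grip,
    grip_smoothed = smoothed,
    tie = dec$tie,
    rest_gated = dec$rest,
    excluded = it$pause,
    stringsAsFactors = FALSE
  )
  class(out) <- c("decode_trace", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.decode_trace <- function(x, ...) {
  ok <- !x$excluded
  cat(sprintf(
    "decode_trace: %d iterations (%d excluded as pause), accuracy %.1f%%\n",
    nrow(x), sum(x$excluded),
    100 * mean(x$predicted_pose[ok] == x$commanded_pose[ok])))
  invisible(x)
}

#' Decode a recording window by window
#'
#' Offline counterpart of the online loop: preprocesses the whole stream
#' (the notch state carries across windows), extracts features, applies the
#' rest gate and predicts pose and digit forces for every window.
#'
#' @param decoder A [train_decoder()] bundle.
#' @param recording An EMG [raw_recording()].
#' @param config An [run_config()].
#' @return List with `pose` (character), `votes`, `tie`, `forces`
#'   (windows x 5) and `rest` (logical).
#' @export
decode_windows <- function(decoder, recording, config = decoder$config) {
  ws <- preprocess_recording(recording, decoder$mvc, config)
  feats <- compute_features(ws, config)
  rms <- window_rms(ws)
  rest <- detect_rest(rms, decoder$rest_profile)

  xsel <- apply_selection(feats, decoder$selection, decoder$impute_means)
  vote <- predict_posture(decoder$posture_model, xsel)
  xrms <- apply_selection(feats, decoder$rms_selection, decoder$impute_means)
  forces <- predict_digit_forces(decoder$force_model, xrms, rest = rest)

  pose <- if (config$fusion == "sign-pattern") {
    as.character(pose_from_force_signs(forces, config$dead_zone))
  } else {
    vote$pose
  }
  pose[rest] <- "REST"
  list(pose = pose, votes = vote$votes, tie = vote$tie,
       forces = forces, rest = rest)
}
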