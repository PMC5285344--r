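#' Pipeline run configuration
#'
#' Collects every tunable constant of the decoding pipeline in one list.
#' Defaults follow the reference acquisition setup: 5 EMG channels sampled
#' at 1 kHz, non-overlapping 50-ms analysis windows, a 60-Hz notch with a
#' 20-Hz bandwidth, a resting threshold at 1.5 times the mean resting RMS,
#' 15 selected features, 50-tree random forests, a 0.5-N force dead zone,
#' ~300-ms loop iterations and 4-s pauses after command changes.
#'
#' @param fs Sampling frequency in Hz.
#' @param channels Number of EMG channels (>= 2).
#' @param window_s Analysis window length in seconds.
#' @param notch_f0 Notch center frequency in Hz.
#' @param notch_bw Notch -3 dB bandwidth in Hz.
#' @param rest_multiplier Resting threshold as a multiple of the mean
#'   resting window RMS.
#' @param n_features Number of features retained by correlation-based
#'   selection.
#' @param n_trees Trees per random-forest digit regressor.
#' @param dead_zone Force magnitude (N) below which a predicted digit force
#'   is treated as non-committal by the sign-pattern pose logic.
#' @param iteration_s Nominal online loop iteration duration in seconds.
#' @param pause_s Pause after a command change in seconds.
#' @param seed Integer seed driving all stochastic steps (data splits,
#'   forest bootstraps, synthetic generation defaults).
#' @param fusion How the online loop labels a window: `"svm-template"`
#'   (SVM vote selects the pose and its flexed-digit template) or
#'   `"sign-pattern"` (the signs of the predicted digit forces select the
#'   pose, which can yield `UNCLASSIFIED`).
#' @param if_variant Irregularity-factor convention: `"ratio"` for
#'   m2/sqrt(m0*m4) (bounded by 1) or `"squared"` for m2^2/(m0*m4).
#' @param f_log_variant Reading of the two log features: `"quotient"` for
#'   log(m0/N) and log(IF/WL), `"product"` for log(m0*N) and log(IF*WL).
#'
#' @return A list of class `emg_config`.
#' @export
run_config <- function(fs = 1000, channels = 5, window_s = 0.05,
                       notch_f0 = 60, notch_bw = 20,
                       rest_multiplier = 1.5, n_features = 15,
                       n_trees = 50, dead_zone = 0.5,
                       iteration_s = 0.3, pause_s = 4, seed = 1L,
                       fusion = c("svm-template", "sign-pattern"),
                       if_variant = c("ratio", "squared"),
                       f_log_variant = c("quotient", "product")) {
  cfg <- list(
    fs = fs, channels = channels, window_s = window_s,
    notch_f0 = notch_f0, notch_bw = notch_bw,
    rest_multiplier = rest_multiplier, n_features = n_features,
    n_trees = n_trees, dead_zone = dead_zone,
    iteration_s = iteration_s, pause_s = pause_s, seed = as.integer(seed),
    fusion = match.arg(fusion), if_variant = match.arg(if_variant),
    f_log_variant = match.arg(f_log_variant)
  )
  class(cfg) <- "emg_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks every field of an [run_config()] list and stops with a message
#' listing all offending keys.
#'
#' @param config An `emg_config` list.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(config$fs) && config$fs > 0, "fs")
  chk(num1(config$channels) && config$channels >= 2, "channels")
  chk(num1(config$window_s) && config$window_s * config$fs >= 2, "window_s")
  chk(num1(config$notch_f0) && config$notch_f0 > 0 &&
        config$notch_f0 < config$fs / 2, "notch_f0")
  chk(num1(config$notch_bw) && config$notch_bw > 0, "notch_bw")
  chk(num1(config$rest_multiplier) && config$rest_multiplier > 0,
      "rest_multiplier")
  chk(num1(config$n_features) && config$n_features >= 1, "n_features")
  chk(num1(config$n_trees) && config$n_trees >= 1, "n_trees")
  chk(num1(config$dead_zone) && config$dead_zone >= 0, "dead_zone")
  chk(num1(config$iteration_s) && config$iteration_s > 0, "iteration_s")
  chk(num1(config$pause_s) && config$pause_s >= 0, "pause_s")
  chk(num1(config$seed), "seed")
  chk(is.character(config$fusion) &&
        config$fusion %in% c("svm-template", "sign-pattern"), "fusion")
  chk(config$if_variant %in% c("ratio", "squared"), "if_variant")
  chk(config$f_log_variant %in% c("quotient", "product"), "f_log_variant")
  if (length(bad)) {
    stop("invalid configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

#' Read / write a run configuration
#'
#' Configurations are stored as plain YAML. Unknown keys are rejected;
#' missing keys take their defaults.
#'
#' @param path File path.
#' @return `read_config()` returns an `emg_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config An `emg_config` list.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.emg_config <- function(x, ...) {
  cat("EMG decoding run configuration\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}
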