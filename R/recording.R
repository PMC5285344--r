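#' Multichannel raw recording
#'
#' Container for a multichannel EMG (or digit force) time series sampled at
#' a fixed rate. Samples are stored as a numeric matrix with one row per
#' sample and one column per channel, so all channels are equal length by
#' construction.
#'
#' @param samples Numeric matrix (samples x channels) or a vector for a
#'   single channel.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channel_labels Optional character vector of channel names;
#'   defaults to `ch1..chK` (EMG) — force files conventionally use
#'   `thumb, index, middle, ring, little`.
#' @param trigger_index Optional sample index of the synchronization pulse.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs = 1000, channel_labels = NULL,
                          trigger_index = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix (samples x channels)",
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("recording is empty", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  k <- ncol(samples)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(k))
  }
  if (length(channel_labels) != k) {
    stop("channel_labels length must match channel count", call. = FALSE)
  }
  if (!is.null(trigger_index)) {
    stopifnot(trigger_index >= 1, trigger_index <= nrow(samples))
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         trigger_index = trigger_index),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec A `raw_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) ncol(rec$samples)

#' @rdname n_channels
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Read / write the delimited signal format
#'
#' Signals travel as plain CSV: a first comment line `# fs: <Hz>` carrying
#' the sampling frequency, a header row of channel labels, then one row per
#' sample. Force files use the same layout with columns thumb..little in
#' Newtons.
#'
#' @param path File path.
#' @return `read_signal_csv()` returns a [raw_recording()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*fs\\s*[:=]\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) {
    stop("signal file must start with a '# fs: <Hz>' line: ", path,
         call. = FALSE)
  }
  fs <- as.numeric(m[2])
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  raw_recording(as.matrix(df), fs = fs, channel_labels = names(df))
}

#' @rdname read_signal_csv
#' @param rec A `raw_recording`.
#' @export
write_signal_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", rec$fs), con)
  utils::write.csv(as.data.frame(rec$samples), con, row.names = FALSE)
  invisible(path)
}

#' Read / write calibration artifacts
#'
#' MVC calibrations and rest profiles are serialized as human-readable
#' `key: value` text, one channel per line, with a `type:` line naming the
#' artifact class.
#'
#' @param x An `mvc_calibration` or `rest_profile` object.
#' @param path File path.
#' @return `read_calibration()` returns the restored object;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(x, path) {
  lines <- c(paste0("type: ", class(x)[1]))
  if (inherits(x, "mvc_calibration")) {
    lines <- c(lines, sprintf("%s: %.17g", names(x$mvc_rms), x$mvc_rms))
  } else if (inherits(x, "rest_profile")) {
    lines <- c(lines,
               sprintf("rest_multiplier: %.17g", x$rest_multiplier),
               sprintf("%s: %.17g", names(x$rest_mean_rms), x$rest_mean_rms))
  } else {
    stop("unsupported calibration object", call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  type <- vals[keys == "type"]
  body <- keys != "type"
  if (identical(type, "mvc_calibration")) {
    v <- as.numeric(vals[body])
    names(v) <- keys[body]
    mvc_calibration(v)
  } else if (identical(type, "rest_profile")) {
    mult <- as.numeric(vals[keys == "rest_multiplier"])
    body <- body & keys != "rest_multiplier"
    v <- as.numeric(vals[body])
    names(v) <- keys[body]
    rest_profile(v, rest_multiplier = mult)
  } else {
    stop("unknown calibration type in ", path, call. = FALSE)
  }
}
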