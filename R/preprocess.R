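#' Segment a recording into non-overlapping windows
#'
#' Partitions the stream into consecutive, non-overlapping windows of
#' `window_s` seconds (`round(window_s * fs)` samples). A trailing partial
#' window is discarded. The analysis convention is 50-ms windows at 1 kHz,
#' i.e. 50 samples per window.
#'
#' @param rec A [raw_recording()].
#' @param window_s Window length in seconds.
#' @return A `window_set`: list with `values` (array of dim
#'   `n_samples x channels x n_windows`), `n_samples`, `window_s`, `fs`,
#'   `start_index` (first sample of each window), `channel_labels` and a
#'   `normalized` flag.
#' @export
segment_windows <- function(rec, window_s = 0.05) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- round(window_s * rec$fs)
  if (n < 2) stop("window must span at least 2 samples", call. = FALSE)
  total <- nrow(rec$samples)
  w <- total %/% n
  if (w == 0) {
    warning("window longer than recording; returning empty window set")
  }
  # samples are (time x channel); reshape so window index is the slowest-
  # varying dimension: (samples-in-window, channel, window)
  vals <- aperm(array(rec$samples[seq_len(w * n), , drop = FALSE],
                      dim = c(n, w, ncol(rec$samples))),
                c(1, 3, 2))
  structure(
    list(values = vals, n_samples = n, window_s = window_s, fs = rec$fs,
         start_index = if (w > 0) seq(1, by = n, length.out = w) else integer(0),
         channel_labels = rec$channel_labels, normalized = FALSE),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d samples x %d channels @ %g Hz%s\n",
              n_windows(x), x$n_samples, dim(x$values)[2], x$fs,
              if (x$normalized) " (MVC-normalized)" else ""))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$values)[3]

#' Per-window, per-channel RMS
#'
#' RMS over each window: `sqrt(mean(x^2))` per channel, the amplitude
#' feature underlying MVC calibration and rest detection.
#'
#' @param ws A `window_set`.
#' @return Numeric matrix, windows x channels.
#' @export
window_rms <- function(ws) {
  d <- dim(ws$values)
  m <- matrix(ws$values^2, nrow = d[1])
  out <- matrix(sqrt(colMeans(m)), nrow = d[3], ncol = d[2], byrow = TRUE)
  colnames(out) <- ws$channel_labels
  out
}

#' MVC calibration
#'
#' Holds the per-channel maximum window RMS observed across the maximum
#' voluntary contraction (MVC) trials; subsequent signals are expressed as
#' fractions of these magnitudes.
#'
#' @param mvc_rms Named (or unnamed) positive numeric vector, one entry per
#'   channel.
#' @return An `mvc_calibration` object.
#' @export
mvc_calibration <- function(mvc_rms) {
  if (any(!is.finite(mvc_rms)) || any(mvc_rms <= 0)) {
    stop("MVC magnitudes must be positive", call. = FALSE)
  }
  if (is.null(names(mvc_rms))) {
    names(mvc_rms) <- paste0("ch", seq_along(mvc_rms))
  }
  structure(list(mvc_rms = mvc_rms), class = "mvc_calibration")
}

#' @export
print.mvc_calibration <- function(x, ...) {
  cat("mvc_calibration (max window RMS per channel):\n")
  print(signif(x$mvc_rms, 4))
  invisible(x)
}

#' Compute the MVC calibration from MVC trials
#'
#' RMS is computed on every window of every trial; the calibration value
#' for a channel is the maximum across all windows of all trials.
#'
#' @param mvc_trials A list of [raw_recording()]s (or a single one).
#' @param window_s Window length in seconds.
#' @return An [mvc_calibration()].
#' @export
compute_mvc <- function(mvc_trials, window_s = 0.05) {
  if (inherits(mvc_trials, "raw_recording")) mvc_trials <- list(mvc_trials)
  stopifnot(length(mvc_trials) >= 1)
  k <- vapply(mvc_trials, n_channels, 0L)
  if (length(unique(k)) != 1) {
    stop("MVC trials must share the channel count", call. = FALSE)
  }
  per_trial <- lapply(mvc_trials, function(r) {
    apply(window_rms(segment_windows(r, window_s)), 2, max)
  })
  mx <- do.call(pmax, per_trial)
  if (any(mx <= 0)) {
    stop("MVC must be positive for every channel (all-zero channel?)",
         call. = FALSE)
  }
  names(mx) <- mvc_trials[[1]]$channel_labels
  mvc_calibration(mx)
}

#' Center and MVC-normalize windows
#'
#' Per window and channel, subtracts the window's own mean and divides by
#' the channel's MVC magnitude. The result is dimensionless with zero mean
#' per channel; +/-1 corresponds to the MVC-level RMS. Values are not
#' clipped: a window more energetic than the MVC reference may exceed +/-1.
#'
#' @param ws A `window_set` (not yet normalized).
#' @param mvc An [mvc_calibration()].
#' @return The normalized `window_set`.
#' @export
normalize_windows <- function(ws, mvc) {
  stopifnot(inherits(ws, "window_set"), inherits(mvc, "mvc_calibration"))
  if (ws$normalized) stop("window set is already normalized", call. = FALSE)
  d <- dim(ws$values)
  if (length(mvc$mvc_rms) != d[2]) {
    stop("MVC channel count does not match windows", call. = FALSE)
  }
  m <- matrix(ws$values, nrow = d[1])        # columns = channel-window pairs
  m <- sweep(m, 2, colMeans(m), "-")
  m <- sweep(m, 2, rep(mvc$mvc_rms, times = d[3]), "/")
  ws$values <- array(m, dim = d)
  ws$normalized <- TRUE
  ws
}

#' Second-order IIR notch design
#'
#' Standard digital notch biquad with unit gain at DC and Nyquist, a zero
#' at `f0` and the -3 dB points `bandwidth` Hz apart.
#'
#' @param f0 Notch center frequency (Hz), below Nyquist.
#' @param bandwidth Full -3 dB bandwidth (Hz).
#' @param fs Sampling frequency (Hz).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
design_notch <- function(f0 = 60, bandwidth = 20, fs = 1000) {
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist", call. = FALSE)
  w0 <- 2 * pi * f0 / fs
  k <- 1 / (1 + tan(pi * bandwidth / fs))
  list(b = k * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * k * cos(w0), 2 * k - 1))
}

#' Apply the notch filter, optionally carrying state across calls
#'
#' The filter is causal and stateful: feeding a stream in consecutive
#' chunks with the returned state reproduces whole-stream filtering
#' exactly, which is how the online loop filters consecutive 50-ms windows
#' without per-window transients.
#'
#' @param x Numeric vector or matrix (samples x channels).
#' @param f0,bandwidth,fs Notch design parameters, see [design_notch()].
#' @param state `NULL` for a zero-state start, or the `"notch_state"`
#'   attribute of a previous call on the same stream.
#' @return Filtered signal with attribute `"notch_state"` for chaining.
#' @export
notch_filter <- function(x, f0 = 60, bandwidth = 20, fs = 1000,
                         state = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  flt <- design_notch(f0, bandwidth, fs)
  k <- ncol(x)
  if (is.null(state)) {
    state <- list(x = matrix(0, 2, k), y = matrix(0, 2, k))
  }
  y <- x
  for (c in seq_len(k)) {
    y[, c] <- as.numeric(signal::filter(flt$b, flt$a, x[, c],
                                        init.x = state$x[, c],
                                        init.y = state$y[, c]))
  }
  n <- nrow(x)
  new_state <- list(
    x = rbind(state$x, x)[n + (1:2), , drop = FALSE],
    y = rbind(state$y, y)[n + (1:2), , drop = FALSE]
  )
  if (vec) y <- y[, 1]
  attr(y, "notch_state") <- new_state
  y
}

#' Preprocess a recording into analysis-ready windows
#'
#' The full preprocessing chain: segment into non-overlapping windows,
#' center each window at zero and scale by the MVC magnitude, then run the
#' 60-Hz notch statefully across the concatenated normalized stream (state
#' carries over window boundaries).
#'
#' @param rec A [raw_recording()].
#' @param mvc An [mvc_calibration()].
#' @param config An [run_config()].
#' @param notch_state Optional carried filter state (online use).
#' @return A normalized, filtered `window_set`; the final filter state is
#'   attached as attribute `"notch_state"`.
#' @export
preprocess_recording <- function(rec, mvc, config = run_config(),
                                 notch_state = NULL) {
  ws <- segment_windows(rec, config$window_s)
  ws <- normalize_windows(ws, mvc)
  d <- dim(ws$values)
  stream <- matrix(aperm(ws$values, c(1, 3, 2)), nrow = d[1] * d[3])
  filt <- notch_filter(stream, config$notch_f0, config$notch_bw, config$fs,
                       state = notch_state)
  st <- attr(filt, "notch_state")
  ws$values <- aperm(array(filt, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  attr(ws, "notch_state") <- st
  ws
}

#' Rest profile
#'
#' Per-channel mean resting window RMS (on normalized signal) and the
#' derived resting threshold, `rest_multiplier` times that mean.
#'
#' @param rest_mean_rms Non-negative numeric vector, one entry per channel.
#' @param rest_multiplier Threshold multiplier (default 1.5).
#' @return A `rest_profile` object with fields `rest_mean_rms`,
#'   `threshold` and `rest_multiplier`.
#' @export
rest_profile <- function(rest_mean_rms, rest_multiplier = 1.5) {
  if (any(!is.finite(rest_mean_rms)) || any(rest_mean_rms < 0)) {
    stop("resting RMS must be non-negative", call. = FALSE)
  }
  if (is.null(names(rest_mean_rms))) {
    names(rest_mean_rms) <- paste0("ch", seq_along(rest_mean_rms))
  }
  structure(
    list(rest_mean_rms = rest_mean_rms,
         threshold = rest_multiplier * rest_mean_rms,
         rest_multiplier = rest_multiplier),
    class = "rest_profile"
  )
}

#' @export
print.rest_profile <- function(x, ...) {
  cat(sprintf("rest_profile (threshold = %g x mean resting RMS):\n",
              x$rest_multiplier))
  print(signif(rbind(mean_rms = x$rest_mean_rms,
                     threshold = x$threshold), 4))
  invisible(x)
}

#' Compute the rest profile from a resting recording
#'
#' The resting recording (nominally 1 min) is preprocessed like any other
#' signal; the profile stores each channel's mean window RMS and the
#' threshold at `rest_multiplier` times that mean.
#'
#' @param rest_recording A [raw_recording()] of relaxed-hand EMG, at least
#'   one window long.
#' @param mvc An [mvc_calibration()].
#' @param config An [run_config()].
#' @return A [rest_profile()].
#' @export
compute_rest_profile <- function(rest_recording, mvc,
                                 config = run_config()) {
  if (nrow(rest_recording$samples) < round(config$window_s * config$fs)) {
    stop("rest recording shorter than one window", call. = FALSE)
  }
  ws <- preprocess_recording(rest_recording, mvc, config)
  mean_rms <- colMeans(window_rms(ws))
  rest_profile(mean_rms, rest_multiplier = config$rest_multiplier)
}

#' Threshold-based rest detection
#'
#' The hand is called at rest when the window RMS of every channel is
#' strictly below its resting threshold; a tie counts as activity.
#' Lowering any channel's RMS can never flip rest into activity.
#'
#' @param rms Numeric vector of per-channel window RMS (normalized units),
#'   or a windows x channels matrix for vectorized use.
#' @param profile A [rest_profile()].
#' @return Logical scalar (or vector, one per window).
#' @export
detect_rest <- function(rms, profile) {
  stopifnot(inherits(profile, "rest_profile"))
  if (is.matrix(rms)) {
    if (ncol(rms) != length(profile$threshold)) {
      stop("channel count mismatch", call. = FALSE)
    }
    return(rowSums(sweep(rms, 2, profile$threshold, "<")) == ncol(rms))
  }
  if (length(rms) != length(profile$threshold)) {
    stop("channel count mismatch", call. = FALSE)
  }
  all(rms < profile$threshold)
}
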