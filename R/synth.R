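#' Synthetic session specification
#'
#' Parameters of the seeded synthetic EMG/force generator. The surrogate is
#' amplitude-modulated band-limited Gaussian noise — the standard
#' phenomenological model of surface EMG — plus a 60-Hz line component and
#' a resting baseline; digit forces are Newton-scaled drives with additive
#' Gaussian noise.
#'
#' @param fs Sampling frequency (Hz).
#' @param channels EMG channel count.
#' @param band EMG passband (Hz), upper edge below Nyquist.
#' @param line_noise_amp 60-Hz line amplitude relative to the baseline
#'   noise level.
#' @param baseline_noise Resting noise level (arbitrary voltage units).
#' @param snr Activation-to-baseline ratio: the noise envelope at full
#'   activation is `baseline_noise * (1 + snr)`.
#' @param force_scale Force (N) of a unit-gain digit at full drive.
#' @param force_noise Force noise SD as a fraction of `force_scale`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 1000, channels = 5, band = c(20, 450),
                       line_noise_amp = 0.5, baseline_noise = 0.02,
                       snr = 8, force_scale = 10, force_noise = 0.05,
                       seed = 1L) {
  stopifnot(band[2] < fs / 2, band[1] > 0, baseline_noise > 0, snr >= 0)
  structure(list(fs = fs, channels = channels, band = band,
                 line_noise_amp = line_noise_amp,
                 baseline_noise = baseline_noise, snr = snr,
                 force_scale = force_scale, force_noise = force_noise,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default synergy map
#'
#' The pose-by-channel activation matrix (distinct, partially overlapping
#' rows so classification is nontrivial but solvable), the channel-by-digit
#' coupling matrix that ties digit drives to channel activation, and the
#' per-digit force gains (relative force capacity, thumb strongest).
#'
#' @return A list of class `synergy_map` with `activation` (5 poses x 5
#'   channels), `digit_coupling` (5 channels x 5 digits) and `digit_gain`
#'   (length 5).
#' @export
default_synergy_map <- function() {
  activation <- rbind(
    OPEN_HAND    = c(0.80, 0.10, 0.15, 0.10, 0.20),
    CLOSED_FIST  = c(0.10, 0.85, 0.70, 0.60, 0.50),
    GRASP_2DIGIT = c(0.15, 0.75, 0.10, 0.15, 0.60),
    GRASP_3DIGIT = c(0.20, 0.60, 0.65, 0.10, 0.15),
    FINGER_POINT = c(0.65, 0.30, 0.10, 0.55, 0.15)
  )
  colnames(activation) <- paste0("ch", 1:5)
  digit_coupling <- cbind(
    thumb  = c(0.7, 0.1, 0.1, 0.1, 0.1),
    index  = c(0.1, 0.7, 0.2, 0.1, 0.1),
    middle = c(0.1, 0.2, 0.7, 0.2, 0.1),
    ring   = c(0.1, 0.1, 0.2, 0.7, 0.2),
    little = c(0.1, 0.1, 0.1, 0.2, 0.7)
  )
  rownames(digit_coupling) <- paste0("ch", 1:5)
  structure(list(activation = activation,
                 digit_coupling = digit_coupling,
                 digit_gain = c(thumb = 1.2, index = 1.0, middle = 0.9,
                                ring = 0.6, little = 0.5)),
            class = "synergy_map")
}

# signed flexion/extension template of a pose (+1 flex, -1 extend)
pose_force_signs <- function(pose) {
  if (pose == "REST") return(rep(0, 5))
  ifelse(flexed_digits(pose), 1, -1)
}

# default per-digit drive weights for a pose: flexed digits full drive,
# extended digits a weaker antagonist drive
default_focus_weights <- function(pose, focus = NULL) {
  if (pose == "REST") return(rep(0, 5))
  if (!is.null(focus) && !identical(focus, "all")) {
    w <- rep(0.15, 5)
    w[match(focus, digit_names())] <- 1
    return(w)
  }
  ifelse(flexed_digits(pose), 1, 0.6)
}

# band-limited unit-variance Gaussian noise, one column per channel
bandlimited_noise <- function(n, channels, spec) {
  bf <- signal::butter(4, spec$band / (spec$fs / 2), type = "pass")
  z <- matrix(stats::rnorm(n * channels), n, channels)
  for (c in seq_len(channels)) {
    y <- as.numeric(signal::filter(bf, z[, c]))
    z[, c] <- y / stats::sd(y)
  }
  z
}

#' Generate a synthetic EMG/force segment for one pose
#'
#' Per channel, band-limited Gaussian noise is amplitude-modulated by the
#' pose's activation pattern and the drive profile, on top of the resting
#' baseline, plus a 60-Hz line component. Per digit, force is the
#' coupling-weighted drive scaled to Newtons with additive noise, signed by
#' the pose's flexion/extension template. Fully reproducible from the seed.
#'
#' @param pose A pose label (including `"REST"`).
#' @param duration_s Segment duration in seconds (>= one window).
#' @param force_profile Drive in `[0, 1]`: scalar or per-sample vector.
#' @param spec A [synth_spec()].
#' @param map A [default_synergy_map()]-shaped `synergy_map`.
#' @param focus Optional digit name to concentrate force on (fist trials),
#'   or `"all"`.
#' @param mvc Logical; `TRUE` drives every channel at full activation
#'   (maximum voluntary contraction trial).
#' @param seed Seed; `NULL` consumes the caller's RNG stream (used by the
#'   session generators).
#' @return List with `recording` (EMG [raw_recording()]), `forces` (5-column
#'   [raw_recording()], N), `pose`, `focus` and per-sample `drive`.
#' @export
generate_pose_segment <- function(pose, duration_s, force_profile = 1,
                                  spec = synth_spec(),
                                  map = default_synergy_map(),
                                  focus = NULL, mvc = FALSE,
                                  seed = spec$seed) {
  if (!pose %in% c(pose_levels(), "REST")) {
    stop("unknown pose: ", pose, call. = FALSE)
  }
  n <- round(duration_s * spec$fs)
  if (n < 2) stop("segment shorter than one window", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- spec$channels
  drive <- rep_len(force_profile, n)
  drive <- pmin(pmax(drive, 0), 1)

  w <- default_focus_weights(pose, focus)
  u <- outer(drive, w)                               # n x 5 digit drives
  if (mvc) {
    act <- matrix(1, n, k)
  } else if (pose == "REST") {
    act <- matrix(0, n, k)
  } else {
    arow <- map$activation[pose, seq_len(k)]
    kk <- min(k, nrow(map$digit_coupling))
    coup <- matrix(0, n, k)
    coup[, seq_len(kk)] <- u %*% t(map$digit_coupling[seq_len(kk), ,
                                                      drop = FALSE])
    act <- 0.6 * outer(drive, arow) + 0.4 * coup
  }
  envelope <- spec$baseline_noise * (1 + spec$snr * act)
  noise <- bandlimited_noise(n, k, spec)
  tt <- (seq_len(n) - 1) / spec$fs
  phase <- stats::runif(k, 0, 2 * pi)
  line <- spec$line_noise_amp * spec$baseline_noise *
    sin(outer(2 * pi * 60 * tt, rep(1, k)) +
          matrix(phase, n, k, byrow = TRUE))
  emg <- envelope * noise + line

  signs <- pose_force_signs(pose)
  force <- sweep(u, 2, signs * spec$force_scale * map$digit_gain, "*")
  if (pose != "REST") {
    force <- force + matrix(stats::rnorm(n * 5, 0,
                                         spec$force_noise * spec$force_scale),
                            n, 5)
  }
  colnames(force) <- digit_names()
  list(
    recording = raw_recording(emg, fs = spec$fs,
                              channel_labels = paste0("ch", seq_len(k))),
    forces = raw_recording(force, fs = spec$fs,
                           channel_labels = digit_names()),
    pose = pose, focus = focus, drive = drive
  )
}

# piecewise-linear drive profile: `points` is a matrix-like list of
# (time_s, value) knots; linear interpolation, constant extrapolation
drive_profile <- function(duration_s, fs, knots) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  stats::approx(knots[, 1], knots[, 2], xout = t, rule = 2)$y
}

#' Generate a full synthetic training session
#'
#' Emulates the 12-trial training protocol (30-s trials): two trials each
#' of open hand, 2-digit grasp, index point and 3-digit grasp with a
#' mid-trial force increase; two fist trials with per-digit force
#' concentration (index+middle, ring+little); two fist trials with a grip
#' ramp up, hold and ramp down; plus six short MVC recordings and a 1-min
#' rest recording.
#'
#' @param spec A [synth_spec()] (its `seed` fixes the session).
#' @param map A `synergy_map`.
#' @param trial_s Trial duration in seconds (protocol value 30).
#' @param mvc_s,rest_s MVC trial and rest recording durations in seconds.
#' @return An `emg_session`: list with `mvc_trials`, `rest_recording`,
#'   `trials` (each a [generate_pose_segment()] result plus labels), `spec`
#'   and `map`.
#' @export
generate_training_session <- function(spec = synth_spec(),
                                      map = default_synergy_map(),
                                      trial_s = 30, mvc_s = 3,
                                      rest_s = 60) {
  set.seed(spec$seed)
  fs <- spec$fs
  bump <- function(base, hi) {
    # ramp up at half-time, hold ~7-8 s, ramp back (scaled to trial length)
    s <- trial_s / 30
    drive_profile(trial_s, fs, cbind(
      c(0, 15, 16.5, 23, 24.5, trial_s) * s,
      c(base, base, hi, hi, base, base)
    ))
  }
  updown <- function(base, hi) {
    s <- trial_s / 30
    drive_profile(trial_s, fs, cbind(
      c(0, 8, 15, 20, 27, trial_s) * s,
      c(base, base, hi, hi, base, base)
    ))
  }
  half <- function(first_focus, second_focus, level) {
    list(f1 = first_focus, f2 = second_focus, d = level)
  }
  seg <- function(pose, profile, focus = NULL) {
    generate_pose_segment(pose, trial_s, profile, spec, map,
                          focus = focus, seed = NULL)
  }
  two_focus <- function(fa, fb) {
    # one fist trial, force concentrated on digit `fa` then `fb`
    n <- round(trial_s * fs)
    a <- seg("CLOSED_FIST", 0.6, focus = fa)
    b <- seg("CLOSED_FIST", 0.6, focus = fb)
    cut <- n %/% 2
    emg <- rbind(a$recording$samples[1:cut, ],
                 b$recording$samples[(cut + 1):n, ])
    frc <- rbind(a$forces$samples[1:cut, ],
                 b$forces$samples[(cut + 1):n, ])
    list(recording = raw_recording(emg, fs = fs),
         forces = raw_recording(frc, fs = fs,
                                channel_labels = digit_names()),
         pose = "CLOSED_FIST",
         focus = c(rep(fa, cut), rep(fb, n - cut)),
         drive = c(a$drive[1:cut], b$drive[(cut + 1):n]))
  }

  trials <- list(
    seg("OPEN_HAND", bump(0.35, 0.8)),
    seg("OPEN_HAND", bump(0.35, 0.8)),
    seg("GRASP_2DIGIT", bump(0.35, 0.8)),
    seg("GRASP_2DIGIT", bump(0.35, 0.8)),
    seg("FINGER_POINT", updown(0.3, 0.8)),
    seg("FINGER_POINT", updown(0.3, 0.8)),
    seg("GRASP_3DIGIT", bump(0.35, 0.8)),
    seg("GRASP_3DIGIT", bump(0.35, 0.8)),
    two_focus("index", "middle"),
    two_focus("ring", "little"),
    seg("CLOSED_FIST", updown(0.2, 0.8), focus = "all"),
    seg("CLOSED_FIST", updown(0.2, 0.8), focus = "all")
  )
  mvc_trials <- lapply(seq_len(6), function(i) {
    generate_pose_segment("CLOSED_FIST", mvc_s, 1, spec, map,
                          mvc = TRUE, seed = NULL)$recording
  })
  rest <- generate_pose_segment("REST", rest_s, 0, spec, map,
                                seed = NULL)$recording
  structure(list(mvc_trials = mvc_trials, rest_recording = rest,
                 trials = trials, spec = spec, map = map),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf(
    "emg_session: %d training trials, %d MVC trials, %.0f-s rest (seed %d)\n",
    length(x$trials), length(x$mvc_trials),
    n_samples(x$rest_recording) / x$rest_recording$fs, x$spec$seed))
  invisible(x)
}

#' Generate an EMG stream following a task script
#'
#' Produces the EMG (and true force) stream of a simulated subject
#' executing a [task_script()]: one 50-ms window's worth of samples per
#' iteration. During the pause iterations after each command change, the
#' generative state cross-fades linearly from the previous command to the
#' new one. Outside pauses, each iteration lapses with probability
#' `1 - compliance`, during which the subject briefly produces a random
#' other pose at half drive.
#'
#' @param script A [task_script()].
#' @param spec A [synth_spec()].
#' @param map A `synergy_map`.
#' @param compliance Probability in `[0, 1]` that a non-pause iteration
#'   realizes the commanded state.
#' @param config An [run_config()] (window length, iteration timing).
#' @return List with `recording` (EMG), `forces` (true generated forces),
#'   `iteration` metadata data.frame (`commanded_pose`, `target_force`,
#'   `pause`, `lapse`, `drive`).
#' @export
generate_task_stream <- function(script, spec = synth_spec(),
                                 map = default_synergy_map(),
                                 compliance = 1,
                                 config = run_config()) {
  stopifnot(inherits(script, "task_script"),
            compliance >= 0, compliance <= 1)
  set.seed(spec$seed)
  it <- iteration_table(script, config)
  n_it <- nrow(it)
  win <- round(config$window_s * spec$fs)

  # drive needed to realize a target grip force for a pose
  drive_for <- function(pose, target, drive_default) {
    if (is.na(target)) return(drive_default)
    flex <- flexed_digits(pose)
    w <- default_focus_weights(pose)
    gain <- sum(spec$force_scale * map$digit_gain[flex] * w[flex])
    if (gain <= 0) return(drive_default)
    min(1, target / gain)
  }

  lapse <- stats::runif(n_it) > compliance & !it$pause
  emg <- matrix(0, n_it * win, spec$channels)
  frc <- matrix(0, n_it * win, 5)
  poses <- c(pose_levels(), "REST")
  for (i in seq_len(n_it)) {
    pose <- it$commanded_pose[i]
    drv <- drive_for(pose, it$target_force[i], it$drive[i])
    focus <- it$focus[i]
    if (lapse[i]) {
      pose <- sample(setdiff(poses, pose), 1)
      drv <- 0.5
      focus <- NA_character_
    }
    if (it$pause[i] && i > 1) {
      # cross-fade from the previous event's state into the new command
      prev <- it$prev_pose[i]
      frac <- it$pause_frac[i]
      a <- generate_pose_segment(prev, config$window_s,
                                 it$prev_drive[i] * (1 - frac),
                                 spec, map, seed = NULL,
                                 focus = na_null(it$prev_focus[i]))
      b <- generate_pose_segment(pose, config$window_s, drv * frac,
                                 spec, map, seed = NULL,
                                 focus = na_null(focus))
      rows <- (i - 1) * win + seq_len(win)
      emg[rows, ] <- a$recording$samples + b$recording$samples
      frc[rows, ] <- a$forces$samples + b$forces$samples
    } else {
      sgm <- generate_pose_segment(pose, config$window_s, drv, spec, map,
                                   seed = NULL, focus = na_null(focus))
      rows <- (i - 1) * win + seq_len(win)
      emg[rows, ] <- sgm$recording$samples
      frc[rows, ] <- sgm$forces$samples
    }
  }
  it$lapse <- lapse
  list(
    recording = raw_recording(emg, fs = spec$fs,
                              channel_labels = paste0("ch",
                                                      seq_len(spec$channels))),
    forces = raw_recording(frc, fs = spec$fs,
                           channel_labels = digit_names()),
    iteration = it
  )
}

na_null <- function(x) if (is.na(x)) NULL else x
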