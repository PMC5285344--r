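#' Task script
#'
#' A timed sequence of commands for the online loop: each event commands a
#' pose, optionally a target grip force (N) and/or a force-concentration
#' digit, for a number of loop iterations. The loop pauses after every
#' command change; those iterations are flagged and excluded from the
#' statistics.
#'
#' @param events Data frame with columns `pose`, `target_force` (N or NA),
#'   `focus` (digit name, `"all"`, or NA), `drive` (relative effort in
#'   `[0, 1]` used by the synthetic subject when no target is set) and
#'   `n_iter` (> 0).
#' @param pause_s Pause after a command change, seconds.
#' @return The events data frame with class `task_script` and attribute
#'   `pause_s`.
#' @export
task_script <- function(events, pause_s = 4) {
  stopifnot(is.data.frame(events),
            all(c("pose", "n_iter") %in% names(events)))
  if (is.null(events$target_force)) events$target_force <- NA_real_
  if (is.null(events$focus)) events$focus <- NA_character_
  if (is.null(events$drive)) events$drive <- 0.5
  if (any(events$n_iter <= 0)) stop("iteration counts must be > 0",
                                    call. = FALSE)
  if (!all(events$pose %in% c(pose_levels(), "REST"))) {
    stop("unknown pose in script", call. = FALSE)
  }
  structure(events, class = c("task_script", "data.frame"),
            pause_s = pause_s)
}

#' @rdname task_script
#' @param script A `task_script`.
#' @export
total_iterations <- function(script) sum(script$n_iter)

# split `total` iterations over `m` command segments: floor share each,
# remainder to the earliest segments (deterministic)
split_iterations <- function(total, m) {
  base <- total %/% m
  extra <- total - base * m
  base + c(rep(1, extra), rep(0, m - extra))
}

#' Build the grasping-round task script
#'
#' The five grasp tasks in protocol order, 100 iterations each (500 total),
#' with 4-s pauses at command changes:
#' relax / open / 2-digit grasp at 6 then 12 N / open / relax;
#' open / 3-digit grasp at 10 then 20 N / open / relax;
#' open / power grasp down the 30, 25, 20, 15, 10 N ladder / open;
#' relax / open / power-point alternation at 12 N / open / relax;
#' open / power-2-digit alternation / open / relax.
#' Iterations divide equally over a task's command segments, earliest
#' segments taking the remainder.
#'
#' @param iterations_per_task Loop iterations per grasp task.
#' @param pause_s Pause after a command change, seconds.
#' @return A [task_script()] totalling `5 * iterations_per_task` iterations.
#' @export
build_grasping_round <- function(iterations_per_task = 100, pause_s = 4) {
  ev <- function(pose, target = NA_real_, drive = 0.5) {
    data.frame(pose = pose, target_force = target, focus = NA_character_,
               drive = drive, stringsAsFactors = FALSE)
  }
  tasks <- list(
    rbind(ev("REST", drive = 0), ev("OPEN_HAND"),
          ev("GRASP_2DIGIT", 6), ev("GRASP_2DIGIT", 12),
          ev("OPEN_HAND"), ev("REST", drive = 0)),
    rbind(ev("OPEN_HAND"),
          ev("GRASP_3DIGIT", 10), ev("GRASP_3DIGIT", 20),
          ev("OPEN_HAND"), ev("REST", drive = 0)),
    rbind(ev("OPEN_HAND"),
          ev("CLOSED_FIST", 30), ev("CLOSED_FIST", 25),
          ev("CLOSED_FIST", 20), ev("CLOSED_FIST", 15),
          ev("CLOSED_FIST", 10), ev("OPEN_HAND")),
    rbind(ev("REST", drive = 0), ev("OPEN_HAND"),
          ev("CLOSED_FIST", 12), ev("FINGER_POINT", 12),
          ev("CLOSED_FIST", 12), ev("FINGER_POINT", 12),
          ev("CLOSED_FIST", 12), ev("OPEN_HAND"), ev("REST", drive = 0)),
    rbind(ev("OPEN_HAND"),
          ev("CLOSED_FIST", drive = 0.6), ev("GRASP_2DIGIT", drive = 0.6),
          ev("CLOSED_FIST", drive = 0.6), ev("GRASP_2DIGIT", drive = 0.6),
          ev("CLOSED_FIST", drive = 0.6), ev("OPEN_HAND"),
          ev("REST", drive = 0))
  )
  events <- do.call(rbind, lapply(seq_along(tasks), function(t) {
    df <- tasks[[t]]
    df$n_iter <- split_iterations(iterations_per_task, nrow(df))
    df$task <- t
    df
  }))
  task_script(events, pause_s = pause_s)
}

#' Build the force-shifting task script
#'
#' 500 iterations of a maintained fist in five 100-iteration epochs:
#' epoch 1 alternates relaxed and tight fist every 20 iterations (toggles
#' at iterations 20, 40, 60, 80); epochs 2-5 command the force to be
#' concentrated on the little, ring, middle and index finger respectively.
#'
#' @param iterations_per_epoch Loop iterations per epoch.
#' @param pause_s Pause after a command change, seconds.
#' @return A [task_script()] totalling `5 * iterations_per_epoch`
#'   iterations.
#' @export
build_force_shift_round <- function(iterations_per_epoch = 100,
                                    pause_s = 4) {
  toggle_len <- max(1, iterations_per_epoch %/% 5)
  fist <- function(drive, focus, n) {
    data.frame(pose = "CLOSED_FIST", target_force = NA_real_,
               focus = focus, drive = drive, n_iter = n,
               stringsAsFactors = FALSE)
  }
  epoch1 <- do.call(rbind, lapply(seq_len(5), function(i) {
    fist(if (i %% 2 == 1) 0.2 else 0.8, "all", toggle_len)
  }))
  epoch1$task <- 1L
  shift <- do.call(rbind, lapply(seq_along(c("little", "ring", "middle",
                                             "index")), function(i) {
    f <- c("little", "ring", "middle", "index")[i]
    df <- fist(0.7, f, iterations_per_epoch)
    df$task <- i + 1L
    df
  }))
  task_script(rbind(epoch1, shift), pause_s = pause_s)
}

# expand a script into one row per loop iteration, with pause flags:
# the first ceil(pause_s / iteration_s) iterations of every event are
# pause (command-change) iterations
iteration_table <- function(script, config = run_config()) {
  pause_iters <- ceiling(attr(script, "pause_s") / config$iteration_s)
  rows <- lapply(seq_len(nrow(script)), function(e) {
    n <- script$n_iter[e]
    p <- pmin(seq_len(n), pause_iters + 1) <= pause_iters
    data.frame(
      event = e,
      iteration_in_event = seq_len(n),
      commanded_pose = script$pose[e],
      target_force = script$target_force[e],
      focus = script$focus[e],
      drive = script$drive[e],
      task = if (!is.null(script$task)) script$task[e] else 1L,
      pause = p,
      pause_frac = ifelse(p, seq_len(n) / pause_iters, 1),
      prev_pose = if (e > 1) script$pose[e - 1] else "REST",
      prev_drive = if (e > 1) script$drive[e - 1] else 0,
      prev_focus = if (e > 1) script$focus[e - 1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$iteration <- seq_len(nrow(out))
  out
}
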