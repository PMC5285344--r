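#' Confusion matrix of a decode trace
#'
#' Rows are the commanded poses, columns the predicted poses (including
#' `REST` and `UNCLASSIFIED`); entries are the percentage of non-excluded
#' iterations of each commanded pose, so every defined row sums to 100.
#' A commanded pose with no non-excluded iterations yields an NA row with a
#' warning.
#'
#' @param trace A `decode_trace` from [run_online_simulation()].
#' @return Numeric matrix of percentages with a `n_iterations` attribute
#'   (non-excluded iterations per row).
#' @export
confusion_matrix <- function(trace) {
  ok <- !trace$excluded
  if (!any(ok)) stop("no non-excluded iterations", call. = FALSE)
  lev <- all_pose_levels()
  commanded <- intersect(lev, unique(trace$commanded_pose))
  out <- matrix(NA_real_, length(commanded), length(lev),
                dimnames = list(commanded, lev))
  n <- integer(length(commanded))
  names(n) <- commanded
  for (cp in commanded) {
    sel <- ok & trace$commanded_pose == cp
    n[cp] <- sum(sel)
    if (n[cp] == 0) {
      warning("no non-excluded iterations for commanded pose ", cp)
      next
    }
    tab <- table(factor(trace$predicted_pose[sel], levels = lev))
    out[cp, ] <- 100 * as.numeric(tab) / n[cp]
  }
  attr(out, "n_iterations") <- n
  out
}

#' Normalized RMS error of grip force
#'
#' Root-mean-square deviation of the predicted (smoothed) grip force from
#' the target, as a percentage of the target:
#' `sqrt(mean((predicted - target)^2)) / target * 100`.
#'
#' @param predicted Numeric vector of predicted grip forces (N).
#' @param target Target force (N, > 0).
#' @return Percentage.
#' @export
grip_nrmse <- function(predicted, target) {
  if (!is.numeric(target) || length(target) != 1 || target <= 0) {
    stop("target force must be a positive scalar", call. = FALSE)
  }
  sqrt(mean((predicted - target)^2)) / target * 100
}

#' Grip-force NRMSE table of a decode trace
#'
#' Computes [grip_nrmse()] on the smoothed grip force of every targeted
#' command segment (non-excluded iterations), then averages per commanded
#' grasp type and overall.
#'
#' @param trace A `decode_trace`.
#' @return Data frame with one row per grasp type plus an `"average"` row:
#'   `pose`, `nrmse_pct`, `n_segments`.
#' @export
nrmse_table <- function(trace) {
  ok <- !trace$excluded & !is.na(trace$target_force)
  if (!any(ok)) stop("trace has no targeted iterations", call. = FALSE)
  seg_id <- cumsum(c(TRUE, diff(trace$iteration) != 1 |
                       trace$commanded_pose[-1] !=
                         trace$commanded_pose[-nrow(trace)] |
                       !identical2(trace$target_force[-1],
                                   trace$target_force[-nrow(trace)])))
  segs <- split(which(ok), seg_id[ok])
  per_seg <- do.call(rbind, lapply(segs, function(i) {
    data.frame(pose = trace$commanded_pose[i[1]],
               target = trace$target_force[i[1]],
               nrmse = grip_nrmse(trace$grip_smoothed[i],
                                  trace$target_force[i[1]]),
               stringsAsFactors = FALSE)
  }))
  by_pose <- stats::aggregate(nrmse ~ pose, per_seg, mean)
  out <- rbind(
    data.frame(pose = by_pose$pose, nrmse_pct = by_pose$nrmse,
               n_segments = as.numeric(table(per_seg$pose)[by_pose$pose])),
    data.frame(pose = "average", nrmse_pct = mean(per_seg$nrmse),
               n_segments = nrow(per_seg))
  )
  rownames(out) <- NULL
  out
}

# elementwise equality treating NA == NA as TRUE
identical2 <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

#' Finger force fractions
#'
#' Shares of the summed finger force (index, middle, ring, little — the
#' thumb is excluded) contributed by each finger. Negative finger forces
#' are floored at zero before normalization; the fractions sum to 1. If no
#' finger force is positive the distribution is undefined (all-NA,
#' flagged).
#'
#' @param forces Numeric vector of 5 digit forces (N, thumb..little).
#' @return A `force_distribution`: list with `fractions` (named length-4
#'   vector) and `undefined` flag.
#' @export
force_fractions <- function(forces) {
  stopifnot(length(forces) == 5)
  f <- pmax(forces[2:5], 0)
  names(f) <- digit_names()[2:5]
  tot <- sum(f)
  if (tot <= 0) {
    return(structure(list(fractions = f * NA_real_, undefined = TRUE),
                     class = "force_distribution"))
  }
  structure(list(fractions = f / tot, undefined = FALSE),
            class = "force_distribution")
}

#' @export
print.force_distribution <- function(x, ...) {
  if (x$undefined) {
    cat("force_distribution: undefined (no positive finger force)\n")
  } else {
    cat("force_distribution:",
        paste(sprintf("%s %.2f", names(x$fractions), x$fractions),
              collapse = ", "),
        sprintf("(Fdist = %.3f)\n", force_distribution_index(x)))
  }
  invisible(x)
}

#' Force distribution index
#'
#' Weighted combination of the finger force fractions:
#' `Fdist = F_index * 1 + F_middle * 0.5 - F_ring * 0.5 - F_little * 1`.
#' Equals -1 with all force on the little finger, +1 with all force on the
#' index finger, and 0 for an even distribution.
#'
#' @param dist A [force_fractions()] result, or a numeric vector of the
#'   four finger fractions (index, middle, ring, little).
#' @return Numeric scalar in `[-1, 1]` (NA if the distribution is
#'   undefined).
#' @export
force_distribution_index <- function(dist) {
  fr <- if (inherits(dist, "force_distribution")) dist$fractions else dist
  stopifnot(length(fr) == 4)
  sum(fr * c(1, 0.5, -0.5, -1))
}

#' Unwanted hand-opening rate
#'
#' Percentage of non-excluded iterations with a grasp commanded (closed
#' fist, 2- or 3-digit grasp) during which the decoder predicted an open
#' hand — the failure mode corresponding to dropping a held object.
#'
#' @param trace A `decode_trace`.
#' @return Percentage (0 if no grasp was commanded).
#' @export
unwanted_opening_rate <- function(trace) {
  grasps <- c("CLOSED_FIST", "GRASP_2DIGIT", "GRASP_3DIGIT")
  sel <- !trace$excluded & trace$commanded_pose %in% grasps
  if (!any(sel)) return(0)
  100 * mean(trace$predicted_pose[sel] == "OPEN_HAND")
}

#' Epoch-wise mean force distribution index
#'
#' Splits a force-shifting trace into its tasks/epochs and returns the mean
#' [force_distribution_index()] over the non-excluded fist iterations with
#' a defined distribution in each epoch.
#'
#' @param trace A `decode_trace` from a force-shifting script.
#' @return Data frame with `task`, `focus` (modal commanded focus) and
#'   `mean_fdist`.
#' @export
epoch_fdist <- function(trace) {
  fcols <- paste0("force_", digit_names())
  ok <- !trace$excluded
  tasks <- sort(unique(trace$task))
  out <- lapply(tasks, function(tk) {
    sel <- which(ok & trace$task == tk)
    vals <- vapply(sel, function(i) {
      fd <- force_fractions(as.numeric(trace[i, fcols]))
      if (fd$undefined) NA_real_ else force_distribution_index(fd)
    }, 0)
    foc <- trace$focus[trace$task == tk]
    foc <- foc[!is.na(foc)]
    data.frame(task = tk,
               focus = if (length(foc)) names(sort(table(foc),
                                                   decreasing = TRUE))[1]
                       else NA_character_,
               mean_fdist = mean(vals, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a decode trace and its evaluation reports
#'
#' Writes the per-iteration trace as CSV, plus the confusion matrix, the
#' NRMSE table (when the trace has targets) and the epoch Fdist table as
#' CSV reports.
#'
#' @param trace A `decode_trace`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trace_reports <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  cm <- confusion_matrix(trace)
  utils::write.csv(cbind(commanded = rownames(cm), as.data.frame(cm)),
                   file.path(dir, "confusion_matrix.csv"),
                   row.names = FALSE)
  if (any(!is.na(trace$target_force))) {
    utils::write.csv(nrmse_table(trace), file.path(dir, "nrmse.csv"),
                     row.names = FALSE)
  }
  if (any(!is.na(trace$focus))) {
    utils::write.csv(epoch_fdist(trace), file.path(dir, "fdist.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
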