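#' Pose and digit conventions
#'
#' The five actively classified hand poses in their fixed (tie-breaking)
#' order, plus `REST` (producible only by the rest detector) and
#' `UNCLASSIFIED` (producible only by the sign-pattern logic). Digits are
#' ordered thumb to little.
#'
#' @return Character vectors.
#' @export
pose_levels <- function() {
  c("OPEN_HAND", "CLOSED_FIST", "GRASP_2DIGIT", "GRASP_3DIGIT",
    "FINGER_POINT")
}

#' @rdname pose_levels
#' @export
all_pose_levels <- function() c(pose_levels(), "REST", "UNCLASSIFIED")

#' @rdname pose_levels
#' @export
digit_names <- function() c("thumb", "index", "middle", "ring", "little")

#' Digits flexed in a pose
#'
#' The flexed-digit template of each pose: none for `OPEN_HAND` and `REST`,
#' all five for `CLOSED_FIST`, thumb+index for the 2-digit grasp,
#' thumb+index+middle for the 3-digit grasp, and all but the index for the
#' finger point.
#'
#' @param pose A pose label.
#' @return Logical vector of length 5 (thumb..little).
#' @export
flexed_digits <- function(pose) {
  switch(pose,
    OPEN_HAND    = rep(FALSE, 5),
    REST         = rep(FALSE, 5),
    CLOSED_FIST  = rep(TRUE, 5),
    GRASP_2DIGIT = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    GRASP_3DIGIT = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    FINGER_POINT = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stop("no flexed-digit template for pose ", pose, call. = FALSE)
  )
}

#' Train the one-vs-one RBF-SVM posture classifier
#'
#' Trains one binary radial-basis-kernel SVM per unordered pair of pose
#' labels (C(5,2) = 10 for the full pose set). Hyperparameters (`gamma`,
#' `cost`) are chosen by a logarithmic grid search scored on a held-out
#' third of the training windows; the final classifiers are refit on all
#' supplied windows with the winning pair. To bound grid-search cost, each
#' class is subsampled to at most `grid_cap` windows during the sweep.
#'
#' @param x Numeric feature matrix (windows x selected features).
#' @param labels Character/factor pose labels, one per window; at least two
#'   distinct non-rest classes.
#' @param gamma_grid,cost_grid Hyperparameter grids.
#' @param holdout_frac Fraction of windows held out for grid scoring.
#' @param grid_cap Per-class window cap during the sweep.
#' @param seed Integer seed for the grid-search split and subsampling.
#' @return A `posture_model`: binary classifiers keyed `"A|B"`, the class
#'   set, chosen hyperparameters and the grid table.
#' @export
train_posture_model <- function(x, labels,
                                gamma_grid = c(0.01, 0.1, 1),
                                cost_grid = c(1, 10, 100),
                                holdout_frac = 1 / 3,
                                grid_cap = 300, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  classes <- intersect(pose_levels(), unique(labels))
  if (length(classes) < 2) {
    stop("need at least two distinct pose classes", call. = FALSE)
  }
  pairs <- utils::combn(classes, 2)

  set.seed(seed)
  # per-class subsample for the sweep, then a held-out split within it
  sweep_idx <- unlist(lapply(classes, function(cl) {
    i <- which(labels == cl)
    if (length(i) > grid_cap) sample(i, grid_cap) else i
  }))
  hold <- sample(sweep_idx, max(1, round(length(sweep_idx) * holdout_frac)))
  tr <- setdiff(sweep_idx, hold)

  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  grid$error <- vapply(seq_len(nrow(grid)), function(g) {
    fits <- fit_ovo(x[tr, , drop = FALSE], labels[tr], pairs,
                    gamma = grid$gamma[g], cost = grid$cost[g])
    pred <- ovo_vote(fits, x[hold, , drop = FALSE], classes)$pose
    mean(pred != labels[hold])
  }, 0)
  best <- grid[which.min(grid$error), ]

  fits <- fit_ovo(x, labels, pairs, gamma = best$gamma, cost = best$cost)
  structure(
    list(classifiers = fits, classes = classes,
         gamma = best$gamma, cost = best$cost, grid = grid,
         n_features = ncol(x), feature_names = colnames(x)),
    class = "posture_model"
  )
}

fit_ovo <- function(x, labels, pairs, gamma, cost) {
  fits <- vector("list", ncol(pairs))
  names(fits) <- apply(pairs, 2, paste, collapse = "|")
  for (p in seq_len(ncol(pairs))) {
    sel <- labels %in% pairs[, p]
    fits[[p]] <- e1071::svm(
      x = x[sel, , drop = FALSE],
      y = factor(labels[sel], levels = pairs[, p]),
      kernel = "radial", gamma = gamma, cost = cost, scale = TRUE
    )
  }
  fits
}

ovo_vote <- function(fits, x, classes) {
  votes <- matrix(0L, nrow(x), length(classes),
                  dimnames = list(NULL, classes))
  for (nm in names(fits)) {
    pred <- as.character(predict(fits[[nm]], x))
    for (cl in strsplit(nm, "|", fixed = TRUE)[[1]]) {
      votes[, cl] <- votes[, cl] + (pred == cl)
    }
  }
  # argmax with ties broken by the fixed pose order of `classes`
  win <- apply(votes, 1, which.max)
  tied <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  list(pose = classes[win], votes = votes, tie = tied)
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("posture_model: %d one-vs-one RBF SVMs over {%s}\n",
              length(x$classifiers), paste(x$classes, collapse = ", ")))
  cat(sprintf("  gamma = %g, cost = %g, %d features\n",
              x$gamma, x$cost, x$n_features))
  invisible(x)
}

#' Predict hand posture by one-vs-one voting
#'
#' Every binary classifier casts one vote; the pose with the most votes
#' wins. Votes sum to C(K, 2) per window. Ties are broken by the fixed pose
#' order (`pose_levels()`) and flagged.
#'
#' @param model A [train_posture_model()] result.
#' @param x Feature matrix (windows x features) or a single feature vector.
#' @return List with `pose` (character vector), `votes` (windows x classes
#'   integer matrix) and `tie` (logical vector).
#' @export
predict_posture <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         call. = FALSE)
  }
  ovo_vote(model$classifiers, x, model$classes)
}

#' Train the per-digit random-forest force regressors
#'
#' One random-forest regressor per digit (thumb..little), each with
#' `n_trees` trees and all supplied features available at every split
#' (`mtry = ncol(x)`). Bootstraps are seeded for reproducibility.
#'
#' @param x Numeric feature matrix — conventionally the 15 RMS-type
#'   features (5 channels + 10 pairwise differences).
#' @param forces Numeric matrix, windows x 5 digit forces in Newtons
#'   (positive flexion, negative extension).
#' @param n_trees Trees per forest.
#' @param seed Integer seed.
#' @return A `force_model` with 5 fitted forests.
#' @export
train_force_model <- function(x, forces, n_trees = 50, seed = 1L) {
  stopifnot(is.matrix(x), is.matrix(forces), nrow(x) == nrow(forces))
  if (ncol(forces) != 5) {
    stop("forces must have 5 digit columns (thumb..little)", call. = FALSE)
  }
  if (any(!is.finite(forces))) stop("missing force values", call. = FALSE)
  set.seed(seed)
  forests <- lapply(seq_len(5), function(d) {
    randomForest::randomForest(x = x, y = forces[, d],
                               ntree = n_trees, mtry = ncol(x))
  })
  names(forests) <- digit_names()
  structure(
    list(forests = forests, n_trees = n_trees, n_features = ncol(x),
         feature_names = colnames(x)),
    class = "force_model"
  )
}

#' @export
print.force_model <- function(x, ...) {
  cat(sprintf(
    "force_model: 5 random-forest regressors (%d trees, %d features/tree)\n",
    x$n_trees, x$n_features))
  invisible(x)
}

#' Predict per-digit flexion forces
#'
#' Returns the 5 digit force predictions (N, thumb..little; positive =
#' flexion, negative = extension). Windows gated as rest are overridden to
#' all zeros — zero force encodes the resting state.
#'
#' @param model A [train_force_model()] result.
#' @param x Feature matrix (windows x features) or a single vector.
#' @param rest Logical scalar or vector (one per window) from
#'   [detect_rest()]; gated rows are zeroed.
#' @return Numeric matrix, windows x 5, columns `digit_names()`.
#' @export
predict_digit_forces <- function(model, x, rest = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         call. = FALSE)
  }
  out <- vapply(model$forests, function(f) {
    as.numeric(predict(f, x))
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), ncol = 5,
                dimnames = list(NULL, digit_names()))
  rest <- rep_len(rest, nrow(x))
  out[rest, ] <- 0
  out
}

#' Pose from the signs of the predicted digit forces
#'
#' Maps the sign pattern of the five digit forces (thumb..little) to a pose.
#' Forces with magnitude at or below `dead_zone` are non-committal (sign 0).
#' Patterns: all negative = open hand; all positive = closed fist;
#' thumb & index positive with ring & little negative and middle
#' non-positive = 2-digit grasp; thumb, index & middle positive with ring &
#' little negative = 3-digit grasp; index negative with all others
#' positive = finger point; all zero = rest; anything else = unclassified.
#'
#' @param forces Numeric vector of 5 digit forces (N) or a windows x 5
#'   matrix.
#' @param dead_zone Non-negative dead-zone half-width in Newtons.
#' @return Pose label (character), vectorized over rows.
#' @export
pose_from_force_signs <- function(forces, dead_zone = 0.5) {
  stopifnot(dead_zone >= 0)
  if (is.null(dim(forces))) forces <- matrix(forces, nrow = 1, ncol = 5)
  if (ncol(forces) != 5) stop("need 5 digit forces", call. = FALSE)
  s <- sign(forces) * (abs(forces) > dead_zone)
  one <- function(sg) {
    if (all(sg == 0)) return("REST")
    if (all(sg < 0)) return("OPEN_HAND")
    if (all(sg > 0)) return("CLOSED_FIST")
    if (sg[1] > 0 && sg[2] > 0 && sg[3] <= 0 && sg[4] < 0 && sg[5] < 0) {
      return("GRASP_2DIGIT")
    }
    if (sg[1] > 0 && sg[2] > 0 && sg[3] > 0 && sg[4] < 0 && sg[5] < 0) {
      return("GRASP_3DIGIT")
    }
    if (sg[2] < 0 && all(sg[-2] > 0)) return("FINGER_POINT")
    "UNCLASSIFIED"
  }
  out <- apply(s, 1, one)
  if (length(out) == 1) out[[1]] else out
}

#' Smooth the grip force over recent loop iterations
#'
#' Arithmetic mean of the most recent three grip-force values (fewer when
#' the history is shorter), damping iteration-to-iteration prediction
#' noise in the online loop.
#'
#' @param history Numeric vector of grip-force values, oldest first.
#' @return Numeric scalar.
#' @export
smooth_grip_force <- function(history) {
  if (length(history) < 1) stop("history is empty", call. = FALSE)
  mean(utils::tail(history, 3))
}

#' Total grip force of a pose
#'
#' Sum of the predicted digit forces over the digits flexed in the pose's
#' template (e.g. thumb+index for the 2-digit grasp, all five for the
#' fist). `REST` and `OPEN_HAND` have no flexed digits (0 N). For
#' `UNCLASSIFIED` the positive-force digits are summed and the result is
#' flagged with attribute `flagged = TRUE`.
#'
#' @param forces Numeric vector of 5 digit forces (N, thumb..little).
#' @param pose Pose label.
#' @return Numeric scalar (possibly with a `flagged` attribute).
#' @export
total_grip_force <- function(forces, pose) {
  stopifnot(length(forces) == 5)
  if (pose == "UNCLASSIFIED") {
    out <- sum(forces[forces > 0])
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(forces[flexed_digits(pose)])
}
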