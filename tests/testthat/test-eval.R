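# minimal hand-built trace for the statistics
toy_trace <- function(commanded, predicted, excluded = NULL,
                      grip = NULL, target = NA_real_, task = 1L,
                      focus = NA_character_) {
  n <- length(commanded)
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  if (is.null(grip)) grip <- rep(0, n)
  f <- matrix(0, n, 5,
              dimnames = list(NULL, paste0("force_", digit_names())))
  out <- data.frame(iteration = seq_len(n), task = task,
                    commanded_pose = commanded, target_force = target,
                    focus = focus, predicted_pose = predicted, f,
                    grip_force = grip, grip_smoothed = grip,
                    tie = FALSE, rest_gated = FALSE, excluded = excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("decode_trace", "data.frame")
  out
}

test_that("confusion matrix rows are percentages summing to 100", {
  tr <- toy_trace(
    commanded = rep("OPEN_HAND", 100),
    predicted = c(rep("OPEN_HAND", 80), rep("CLOSED_FIST", 20))
  )
  cm <- confusion_matrix(tr)
  expect_equal(unname(cm["OPEN_HAND", "OPEN_HAND"]), 80)
  expect_equal(unname(cm["OPEN_HAND", "CLOSED_FIST"]), 20)
  expect_equal(sum(cm["OPEN_HAND", ]), 100, tolerance = 1e-9)

  # perfect trace -> 100% diagonal
  cmd <- rep(pose_levels(), each = 10)
  cm2 <- confusion_matrix(toy_trace(cmd, cmd))
  expect_equal(unname(diag(cm2[pose_levels(), pose_levels()])), rep(100, 5))
  # excluded iterations are not counted
  tr3 <- toy_trace(rep("REST", 10),
                   c(rep("OPEN_HAND", 5), rep("REST", 5)),
                   excluded = c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(unname(confusion_matrix(tr3)["REST", "REST"]), 100)
  # random traces: every defined row sums to 100
  set.seed(31)
  for (i in 1:20) {
    tri <- toy_trace(sample(pose_levels(), 50, TRUE),
                     sample(all_pose_levels(), 50, TRUE))
    cmi <- confusion_matrix(tri)
    expect_equal(unname(rowSums(cmi, na.rm = TRUE)),
                 rep(100, nrow(cmi)), tolerance = 1e-9)
  }
})

test_that("grip NRMSE matches worked examples and is scale-invariant", {
  expect_equal(grip_nrmse(rep(6, 20), 6), 0)
  expect_equal(grip_nrmse(rep(7.5, 20), 6), 25)
  expect_equal(grip_nrmse(rep(c(5, 7), 10), 6), 100 / 6, tolerance = 1e-9)
  expect_error(grip_nrmse(c(1, 2), 0), "positive")
  set.seed(32)
  p <- runif(30, 2, 10)
  s <- runif(1, 0.5, 4)
  expect_equal(grip_nrmse(s * p, s * 6), grip_nrmse(p, 6), tolerance = 1e-9)
})

test_that("nrmse_table aggregates per grasp type over targeted segments", {
  tr <- toy_trace(
    commanded = c(rep("GRASP_2DIGIT", 10), rep("CLOSED_FIST", 10)),
    predicted = c(rep("GRASP_2DIGIT", 10), rep("CLOSED_FIST", 10)),
    grip = c(rep(7.5, 10), rep(24, 10)),
    target = c(rep(6, 10), rep(30, 10))
  )
  tab <- nrmse_table(tr)
  expect_equal(tab$nrmse_pct[tab$pose == "GRASP_2DIGIT"], 25)
  expect_equal(tab$nrmse_pct[tab$pose == "CLOSED_FIST"], 20)
  expect_equal(tab$nrmse_pct[tab$pose == "average"], 22.5)
})

test_that("force fractions floor negatives and sum to 1", {
  fd <- force_fractions(c(9, 1, 1, 1, 1))      # thumb excluded
  expect_equal(unname(fd$fractions), rep(0.25, 4))
  expect_equal(sum(fd$fractions), 1)
  fd2 <- force_fractions(c(0, 0, 0, 0, 3))     # only little finger
  expect_equal(unname(fd2$fractions), c(0, 0, 0, 1))
  fd3 <- force_fractions(c(5, 2, 1, 1, 0))
  expect_equal(unname(fd3$fractions), c(0.5, 0.25, 0.25, 0))
  fd4 <- force_fractions(c(5, 2, -3, 1, -1))   # negatives floored
  expect_equal(unname(fd4$fractions), c(2, 0, 1, 0) / 3)
  expect_true(force_fractions(c(4, -1, -1, 0, 0))$undefined)
})

test_that("force distribution index hits its anchor points and bounds", {
  expect_equal(force_distribution_index(c(0, 0, 0, 1)), -1)  # all little
  expect_equal(force_distribution_index(c(1, 0, 0, 0)), 1)   # all index
  expect_equal(force_distribution_index(rep(0.25, 4)), 0)    # even
  # linear and bounded on random simplex points
  set.seed(33)
  for (i in 1:100) {
    g <- -log(runif(4))
    fr <- g / sum(g)
    v <- force_distribution_index(fr)
    expect_true(v >= -1 - 1e-12 && v <= 1 + 1e-12)
    a <- -log(runif(4)); a <- a / sum(a)
    lam <- runif(1)
    expect_equal(force_distribution_index(lam * fr + (1 - lam) * a),
                 lam * v + (1 - lam) * force_distribution_index(a),
                 tolerance = 1e-12)
  }
})

test_that("unwanted opening counts only grasp-commanded iterations", {
  cmd <- c(rep("GRASP_2DIGIT", 50), rep("CLOSED_FIST", 50))
  pred <- cmd
  pred[c(1:3, 51:52)] <- "OPEN_HAND"
  expect_equal(unwanted_opening_rate(toy_trace(cmd, pred)), 5)
  # opens during commanded open are never counted
  tr2 <- toy_trace(rep("OPEN_HAND", 50), rep("OPEN_HAND", 50))
  expect_equal(unwanted_opening_rate(tr2), 0)
  # perfect trace -> 0
  expect_equal(unwanted_opening_rate(toy_trace(cmd, cmd)), 0)
})
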