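test_that("segment_windows partitions exactly, in order, dropping the tail", {
  rec <- raw_recording(matrix(seq_len(2050), ncol = 2), fs = 1000)
  ws <- segment_windows(rec, 0.05)
  expect_equal(n_windows(ws), 20)          # 1025 samples -> 20 windows
  expect_equal(ws$n_samples, 50)
  # order-preserving, per channel: window w holds samples (w-1)*50 + 1..50
  expect_equal(ws$values[, 1, 1], as.numeric(rec$samples[1:50, 1]))
  expect_equal(ws$values[, 2, 3], as.numeric(rec$samples[101:150, 2]))
  # concatenating windows plus the dropped tail reconstructs the stream
  rebuilt <- matrix(aperm(ws$values, c(1, 3, 2)), ncol = 2)
  expect_equal(rbind(rebuilt, rec$samples[1001:1025, ]),
               rec$samples, ignore_attr = TRUE)

  rec2 <- raw_recording(matrix(rnorm(2000), ncol = 2), fs = 1000)
  expect_equal(n_windows(segment_windows(rec2, 0.05)), 20)
  # 30-s trial at 1 kHz -> 600 windows
  rec30 <- raw_recording(matrix(0, 30000, 1), fs = 1000)
  expect_equal(n_windows(segment_windows(rec30, 0.05)), 600)
})

test_that("segment_windows rejects degenerate inputs", {
  expect_error(raw_recording(matrix(numeric(0), 0, 2)), "empty")
  short <- raw_recording(matrix(1:20, ncol = 2), fs = 1000)
  expect_warning(ws <- segment_windows(short, 0.05), "longer than")
  expect_equal(n_windows(ws), 0)
  expect_error(segment_windows(short, 0.001), "at least 2")
})

test_that("compute_mvc takes the max window RMS across trials per channel", {
  # one channel whose window RMS values are 0.1, 0.3, 0.2
  x <- c(rep(0.1, 50), rep(0.3, 50), rep(0.2, 50))
  mvc <- compute_mvc(raw_recording(x, fs = 1000))
  expect_equal(unname(mvc$mvc_rms), 0.3)
  # constant signal of amplitude c -> |c|
  mvc2 <- compute_mvc(raw_recording(rep(-0.7, 200), fs = 1000))
  expect_equal(unname(mvc2$mvc_rms), 0.7)
  # two trials with maxima 0.25 and 0.4 -> 0.4
  tr <- list(raw_recording(rep(0.25, 100)), raw_recording(rep(0.4, 100)))
  expect_equal(unname(compute_mvc(tr)$mvc_rms), 0.4)
  # all-zero channel is an error
  expect_error(compute_mvc(raw_recording(rep(0, 100))), "positive")
})

test_that("normalize_windows centers to zero mean and scales by MVC", {
  M <- 0.4
  mvc <- mvc_calibration(c(ch1 = M))
  w <- segment_windows(raw_recording(rep(5, 50)), 0.05)
  nw <- normalize_windows(w, mvc)
  expect_equal(as.numeric(nw$values), rep(0, 50))   # constant -> zeros
  # window split between -M/2 and +M/2 maps to -0.5 / +0.5
  w2 <- segment_windows(raw_recording(c(rep(-M / 2, 25), rep(M / 2, 25))),
                        0.05)
  nw2 <- normalize_windows(w2, mvc)
  expect_equal(sort(unique(as.numeric(nw2$values))), c(-0.5, 0.5))
  # arbitrary window: per-channel mean 0 within 1e-12; idempotent centering
  set.seed(3)
  w3 <- segment_windows(raw_recording(matrix(rnorm(500), ncol = 2)), 0.05)
  nw3 <- normalize_windows(w3, mvc_calibration(c(1, 1)))
  means <- apply(nw3$values, c(2, 3), mean)
  expect_lt(max(abs(means)), 1e-12)
  recentered <- sweep(nw3$values, c(2, 3), apply(nw3$values, c(2, 3), mean))
  expect_equal(recentered, nw3$values)
  expect_error(normalize_windows(nw3, mvc_calibration(c(1, 1))),
               "already normalized")
  expect_error(mvc_calibration(c(1, 0)), "positive")
})

test_that("notch filter attenuates 60 Hz >= 20 dB and passes the passband", {
  fs <- 1000
  x60 <- sinusoid(60, fs, 5000)
  y60 <- as.numeric(notch_filter(x60, 60, 20, fs))
  ss <- 1000:5000                           # discard transient
  atten <- 20 * log10(sqrt(mean(y60[ss]^2)) / sqrt(mean(x60[ss]^2)))
  expect_lt(atten, -20)
  # 10-Hz sinusoid within 3 dB
  x10 <- sinusoid(10, fs, 5000)
  y10 <- as.numeric(notch_filter(x10, 60, 20, fs))
  expect_gt(20 * log10(sqrt(mean(y10[ss]^2)) / sqrt(mean(x10[ss]^2))), -3)
  # DC essentially unchanged
  ydc <- as.numeric(notch_filter(rep(1, 2000), 60, 20, fs))
  expect_equal(mean(ydc[500:2000]), 1, tolerance = 1e-6)
  expect_error(notch_filter(x10, 600, 20, fs), "Nyquist")
})

test_that("notch preserves broadband white-noise RMS within 15%", {
  set.seed(9)
  x <- rnorm(20000)
  y <- as.numeric(notch_filter(x, 60, 20, 1000))
  expect_equal(sqrt(mean(y^2)) / sqrt(mean(x^2)), 1, tolerance = 0.15)
})

test_that("stateful chunked filtering equals whole-stream filtering", {
  set.seed(4)
  x <- matrix(rnorm(600), ncol = 2)
  whole <- notch_filter(x, 60, 20, 1000)
  st <- NULL
  parts <- lapply(split(seq_len(300), rep(1:6, each = 50)), function(i) {
    y <- notch_filter(x[i, ], 60, 20, 1000, state = st)
    st <<- attr(y, "notch_state")
    y
  })
  expect_equal(do.call(rbind, parts), whole, ignore_attr = TRUE)
})

test_that("rest profile threshold is exactly 1.5x the mean resting RMS", {
  # per-window RMS 0.01 and 0.03 -> mean 0.02, threshold 0.03 (unit MVC,
  # no notch distortion on these scales: use rest_profile directly too)
  p <- rest_profile(c(ch1 = 0.02))
  expect_equal(unname(p$threshold), 0.03)
  expect_equal(unname(rest_profile(c(a = 0))$threshold), 0)   # silent channel
  expect_error(rest_profile(c(-0.1)), "non-negative")

  mvc <- mvc_calibration(rep(1, 2))
  set.seed(5)
  rec <- flat_recording(n = 2000, k = 2, amp = c(0.05, 0.02))
  prof <- compute_rest_profile(rec, mvc, run_config())
  expect_equal(unname(prof$threshold), unname(1.5 * prof$rest_mean_rms))
  expect_error(
    compute_rest_profile(raw_recording(matrix(0.1, 10, 2)), mvc,
                         run_config()),
    "shorter")
})

test_that("detect_rest requires every channel strictly below threshold", {
  prof <- rest_profile(rep(0.02, 5))        # thresholds 0.03
  expect_true(detect_rest(c(0.01, 0.02, 0.01, 0.015, 0.02), prof))
  expect_false(detect_rest(c(0.01, 0.02, 0.05, 0.015, 0.02), prof))
  # tie counts as activity
  expect_false(detect_rest(rep(0.03, 5), prof))
  # monotone: lowering any channel RMS never flips rest -> not rest
  set.seed(6)
  for (i in 1:50) {
    rms <- runif(5, 0, 0.06)
    lowered <- rms
    j <- sample(5, 1)
    lowered[j] <- lowered[j] * runif(1)
    if (detect_rest(rms, prof)) expect_true(detect_rest(lowered, prof))
  }
  # matrix form agrees with row-wise calls
  m <- matrix(runif(20, 0, 0.06), 4, 5)
  expect_equal(detect_rest(m, prof),
               apply(m, 1, detect_rest, profile = prof))
})
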