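test_that("emg_rms matches the definition", {
  expect_equal(emg_rms(rep(0, 10)), 0)
  expect_equal(emg_rms(rep(-3, 7)), 3)
  expect_equal(emg_rms(c(3, 4)), sqrt(12.5))
  expect_error(emg_rms(numeric(0)), "empty")
})

test_that("spectral moments follow the discrete difference convention", {
  x <- c(1, 3, 2, 5, 4)
  m <- spectral_moments(x)
  expect_equal(m$m0, sum(x^2))
  expect_equal(m$m2, sum(diff(x)^2))
  expect_equal(m$m4, sum(diff(x, differences = 2)^2))
  expect_equal(m$WL, sum(abs(diff(x))))
  expect_equal(m$IF, m$m2 / sqrt(m$m0 * m$m4))
  # constant signal: zero derivatives, IF undefined
  mc <- spectral_moments(rep(2, 10))
  expect_equal(mc$m2, 0)
  expect_equal(mc$m4, 0)
  expect_equal(mc$WL, 0)
  expect_true(is.na(mc$IF))
  expect_error(spectral_moments(c(1, 2)), "at least 3")
  # squared variant
  ms <- spectral_moments(x, if_variant = "squared")
  expect_equal(ms$IF, m$IF^2)
})

test_that("IF is ~1 for a slow pure sinusoid and < 1 for white noise", {
  m <- spectral_moments(sinusoid(10, 1000, 2000))
  expect_equal(m$IF, 1, tolerance = 0.02)
  set.seed(11)
  mn <- spectral_moments(rnorm(2000))
  expect_lt(mn$IF, 1)
})

test_that("IF is bounded by 1 and scale-invariant; order sensitivity holds", {
  set.seed(12)
  for (i in 1:30) {
    x <- rnorm(50) * runif(1, 0.1, 10)
    m <- spectral_moments(x)
    expect_true(m$IF >= 0 && m$IF <= 1 + 1e-12)
    s <- runif(1, 0.5, 20)
    ms <- spectral_moments(s * x)
    expect_equal(ms$IF, m$IF, tolerance = 1e-12)      # scale-invariant
    expect_equal(ms$m0, s^2 * m$m0, tolerance = 1e-9) # m0 scales by s^2
    expect_equal(emg_rms(s * x), s * emg_rms(x), tolerance = 1e-9)
    # RMS/m0 permutation-invariant, m2/m4/WL order-sensitive
    p <- sample(x)
    mp <- spectral_moments(p)
    expect_equal(mp$m0, m$m0)
    if (!isTRUE(all.equal(p, x))) expect_false(isTRUE(all.equal(mp$WL, m$WL)))
  }
})

test_that("log features follow the quotient reading with guards", {
  n <- 50
  expect_equal(feature_f2(list(m0 = n, n = n)), 0)         # log(1)
  expect_equal(feature_f2(list(m0 = exp(1) * n, n = n)), 1)
  m <- spectral_moments(rep(1, n))                          # m0 = 50
  expect_equal(feature_f2(m), 0)
  expect_error(feature_f2(list(m0 = 0, n = 10)), "positive")

  expect_equal(feature_f3(list(IF = 0.5, WL = 0.5)), 0)     # IF = WL
  expect_equal(feature_f3(list(IF = 1, WL = exp(1))), -1)
  expect_true(is.na(feature_f3(list(IF = NA_real_, WL = 3))))
  expect_true(is.na(feature_f3(list(IF = 0.5, WL = 0))))
  # sinusoid fixture: matches straight-from-definition recomputation
  x <- sinusoid(25, 1000, 500)
  m <- spectral_moments(x)
  direct <- log((sum(diff(x)^2) /
                   sqrt(sum(x^2) * sum(diff(x, differences = 2)^2))) /
                  sum(abs(diff(x))))
  expect_equal(feature_f3(m), direct, tolerance = 1e-9)
  # product reading switch
  expect_equal(feature_f3(m, variant = "product"),
               log(m$IF * m$WL), tolerance = 1e-12)
})

test_that("expand_channel_pairs yields singles then ordered differences", {
  v <- c(1, 2, 3, 4, 5)
  out <- expand_channel_pairs(v)
  expect_length(out, 15)                     # 5 singles + 10 pairs
  expect_equal(out[1:5], v)
  expect_equal(out[6], -1)                   # pair (1,2) = v1 - v2
  expect_equal(out[15], -1)                  # pair (4,5)
  expect_equal(unname(expand_channel_pairs(rep(7, 5))[6:15]), rep(0, 10))
  for (k in 2:8) {
    expect_length(expand_channel_pairs(seq_len(k)), k + k * (k - 1) / 2)
  }
  expect_error(expand_channel_pairs(1), "at least 2")
})

test_that("compute_features matches per-window scalar computation", {
  set.seed(13)
  rec <- flat_recording(n = 200, k = 3, amp = c(1, 2, 0.5))
  ws <- segment_windows(rec, 0.05)
  f <- compute_features(ws, run_config(channels = 3))
  expect_equal(ncol(f), 3 * (3 + 3))         # 3 types x (3 singles + 3 pairs)
  expect_equal(nrow(f), 4)
  # spot-check window 2 channel 3 against scalar path
  x <- ws$values[, 3, 2]
  m <- spectral_moments(x)
  expect_equal(unname(f[2, "RMS:3"]), emg_rms(x))
  expect_equal(unname(f[2, "F2:3"]), feature_f2(m))
  expect_equal(unname(f[2, "F3:3"]), feature_f3(m))
  expect_equal(unname(f[2, "RMS:1-3"]),
               emg_rms(ws$values[, 1, 2]) - emg_rms(x))
})

test_that("least-correlated selection matches the exhaustive oracle", {
  # features A, B = A, C independent; k = 2 -> {A, C}
  set.seed(14)
  A <- rnorm(100); C <- rnorm(100)
  x <- cbind(A = A, B = A, C = C)
  sel <- select_least_correlated(x, 2)
  expect_setequal(sel$descriptors, c("A", "C"))
  # k = all features -> everything
  x2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_length(select_least_correlated(x2, 4)$index, 4)
  # near-orthogonal features: objective ~ 0
  expect_lt(select_least_correlated(x2, 2)$max_abs_cor, 0.5)
  # zero-variance columns excluded before selection
  x3 <- cbind(x2, const = rep(1, 50))
  sel3 <- select_least_correlated(x3, 4)
  expect_false("const" %in% sel3$descriptors)

  # oracle equivalence on random instances with <= 10 features, k <= 4
  for (i in 1:20) {
    set.seed(100 + i)
    p <- sample(6:10, 1); k <- sample(2:4, 1)
    xi <- matrix(rnorm(60 * p), 60, p,
                 dimnames = list(NULL, paste0("f", seq_len(p))))
    if (i %% 2 == 0) {
      xi[, 2] <- xi[, 1] + 0.3 * rnorm(60)
      xi[, p] <- 0.8 * xi[, p - 1] + 0.4 * rnorm(60)
    }
    got <- select_least_correlated(xi, k)
    oracle <- exhaustive_selection(xi, k)
    expect_equal(got$max_abs_cor, oracle$objective, tolerance = 1e-12)
  }
})

test_that("apply_selection imputes NAs with supplied training means", {
  x <- cbind(a = c(1, NA, 3), b = c(4, 5, 6))
  sel <- structure(list(descriptors = c("a", "b"), index = 1:2,
                        max_abs_cor = 0, method = "all"),
                   class = "feature_selection")
  out <- apply_selection(x, sel, impute_means = c(a = 2, b = 5))
  expect_equal(unname(out[2, "a"]), 2)
  expect_error(apply_selection(x[, 2, drop = FALSE], sel), "lacks")
})
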