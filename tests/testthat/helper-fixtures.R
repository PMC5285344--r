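# Shared fixtures, built once per test run and cached.
#
# The small session uses 6-s trials (vs the 30-s protocol) so the model-level
# unit tests stay fast; the full-protocol session is exercised in the
# acceptance tests. Scripts in tests shrink the pause to keep non-excluded
# iterations at reduced scale.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(seed = 42L) synth_spec(seed = seed)

small_config <- function(seed = 42L, ...) {
  run_config(seed = seed, pause_s = 1.2, ...)
}

get_small_session <- function() {
  if (is.null(.fixtures$session)) {
    .fixtures$session <- generate_training_session(
      small_spec(), trial_s = 6, mvc_s = 1, rest_s = 10
    )
  }
  .fixtures$session
}

get_small_decoder <- function() {
  if (is.null(.fixtures$decoder)) {
    .fixtures$decoder <- train_decoder(get_small_session(), small_config())
  }
  .fixtures$decoder
}

# deterministic sinusoid test signal
sinusoid <- function(f, fs = 1000, n = 1000, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# 5-channel recording with constant per-channel amplitude noise
flat_recording <- function(n = 500, k = 5, amp = rep(1, k), fs = 1000,
                           seed = 1) {
  set.seed(seed)
  raw_recording(matrix(rnorm(n * k), n, k) %*% diag(amp, k), fs = fs)
}

# independent brute-force oracle: minimum achievable max |r| over all
# k-subsets, plus the lexicographically first optimal subset
exhaustive_selection <- function(x, k) {
  A <- abs(stats::cor(x))
  diag(A) <- 0
  combs <- utils::combn(ncol(x), k)
  ut <- upper.tri(matrix(0, k, k))
  obj <- apply(combs, 2, function(s) max(A[s, s][ut]))
  list(best = combs[, which.min(obj)], objective = min(obj))
}
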