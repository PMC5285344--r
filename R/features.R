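#' Root mean square of a window
#'
#' @param x Numeric vector (one channel of one window).
#' @return `sqrt(mean(x^2))`.
#' @export
emg_rms <- function(x) {
  if (length(x) < 1) stop("empty input", call. = FALSE)
  sqrt(mean(x^2))
}

#' Time-domain spectral moments of a window
#'
#' Discrete convention with unit sample spacing: the zero-order moment is
#' the window energy `m0 = sum(x^2)`, the second-order moment the energy of
#' the first difference `m2 = sum(diff(x)^2)`, and the fourth-order moment
#' the energy of the second difference `m4 = sum(diff(x, differences = 2)^2)`.
#' From these, the irregularity factor `IF = m2 / sqrt(m0 * m4)` (or its
#' squared variant `m2^2 / (m0 * m4)`) and the waveform length
#' `WL = sum(abs(diff(x)))`. `IF` equals 1 for a pure slow sinusoid and is
#' below 1 for broadband signals; it is `NA` (flagged undefined) when
#' `m0 * m4 == 0`.
#'
#' @param x Numeric vector of at least 3 samples.
#' @param if_variant `"ratio"` (default, bounded by 1) or `"squared"`.
#' @return A list of class `moment_set` with `m0`, `m2`, `m4`, `IF`, `WL`
#'   and `n` (sample count).
#' @export
spectral_moments <- function(x, if_variant = c("ratio", "squared")) {
  if_variant <- match.arg(if_variant)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for second differences",
                  call. = FALSE)
  d1 <- diff(x)
  d2 <- diff(d1)
  m0 <- sum(x^2)
  m2 <- sum(d1^2)
  m4 <- sum(d2^2)
  IF <- if (m0 * m4 > 0) {
    r <- m2 / sqrt(m0 * m4)
    if (if_variant == "squared") r^2 else r
  } else NA_real_
  structure(list(m0 = m0, m2 = m2, m4 = m4, IF = IF,
                 WL = sum(abs(d1)), n = n),
            class = "moment_set")
}

#' Log-energy feature
#'
#' `f2 = log(m0 / N)` under the default quotient reading, `log(m0 * N)`
#' under the product reading.
#'
#' @param moments A [spectral_moments()] `moment_set` (or a list with `m0`
#'   and `n`).
#' @param n Sample count; defaults to `moments$n`.
#' @param variant `"quotient"` (default) or `"product"`.
#' @return Numeric scalar.
#' @export
feature_f2 <- function(moments, n = moments$n,
                       variant = c("quotient", "product")) {
  variant <- match.arg(variant)
  if (!is.finite(moments$m0) || moments$m0 <= 0) {
    stop("m0 must be positive", call. = FALSE)
  }
  if (variant == "quotient") log(moments$m0 / n) else log(moments$m0 * n)
}

#' Log irregularity-to-length feature
#'
#' `f3 = log(IF / WL)` under the default quotient reading, `log(IF * WL)`
#' under the product reading. Undefined (NA) when `IF` is undefined or
#' `WL` is zero; such values are imputed with training means downstream.
#'
#' @param moments A [spectral_moments()] `moment_set`.
#' @param variant `"quotient"` (default) or `"product"`.
#' @return Numeric scalar, possibly `NA`.
#' @export
feature_f3 <- function(moments, variant = c("quotient", "product")) {
  variant <- match.arg(variant)
  if (is.na(moments$IF) || moments$WL <= 0) return(NA_real_)
  if (variant == "quotient") log(moments$IF / moments$WL)
  else log(moments$IF * moments$WL)
}

#' Expand per-channel values with pairwise differences
#'
#' Given one feature value per channel, returns the K per-channel values
#' followed by `value[i] - value[j]` for every ordered pair `i < j` in
#' lexicographic order: `K + K*(K-1)/2` values (15 for 5 channels).
#'
#' @param values Numeric vector (K >= 2) or a windows x K matrix for
#'   vectorized use.
#' @return Vector of length `K + K*(K-1)/2`, or the corresponding matrix.
#' @export
expand_channel_pairs <- function(values) {
  mat <- is.matrix(values)
  v <- if (mat) values else matrix(values, nrow = 1)
  k <- ncol(v)
  if (k < 2) stop("need at least 2 channels", call. = FALSE)
  pairs <- pair_index(k)
  out <- cbind(v, v[, pairs[, 1], drop = FALSE] - v[, pairs[, 2], drop = FALSE])
  if (mat) out else out[1, ]
}

# ordered channel pairs (i < j), lexicographic
pair_index <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Feature descriptor labels
#'
#' Descriptors name a feature type (`RMS`, `F2`, `F3`) applied to a single
#' channel (`"RMS:2"`) or to an ordered channel pair difference
#' (`"RMS:1-3"`).
#'
#' @param k Channel count.
#' @param types Feature type names.
#' @return Character vector of `length(types) * (k + k*(k-1)/2)` labels,
#'   type-major, singles before pairs.
#' @export
feature_descriptors <- function(k, types = c("RMS", "F2", "F3")) {
  pairs <- pair_index(k)
  scopes <- c(as.character(seq_len(k)),
              paste0(pairs[, 1], "-", pairs[, 2]))
  as.vector(vapply(types, function(t) paste0(t, ":", scopes),
                   character(length(scopes))))
}

#' Compute the full feature matrix of a window set
#'
#' For each window: per-channel RMS, f2 and f3, each expanded with pairwise
#' channel differences — `3 * (K + K*(K-1)/2)` columns (45 for 5 channels),
#' labeled with [feature_descriptors()]. `f3` entries are `NA` where
#' undefined (e.g. silent windows).
#'
#' @param ws A `window_set` (normally preprocessed, see
#'   [preprocess_recording()]).
#' @param config An [run_config()] (irregularity/log-variant switches).
#' @return Numeric matrix, windows x descriptors.
#' @export
compute_features <- function(ws, config = run_config()) {
  d <- dim(ws$values)
  n <- d[1]; k <- d[2]; w <- d[3]
  flat <- matrix(ws$values, nrow = n)           # columns: ch varies fastest
  m0 <- colSums(flat^2)
  d1 <- flat[-1, , drop = FALSE] - flat[-n, , drop = FALSE]
  m2 <- colSums(d1^2)
  m4 <- colSums((d1[-1, , drop = FALSE] - d1[-(n - 1), , drop = FALSE])^2)
  WL <- colSums(abs(d1))
  IF <- ifelse(m0 * m4 > 0, m2 / sqrt(m0 * m4), NA_real_)
  if (config$if_variant == "squared") IF <- IF^2
  rms <- sqrt(m0 / n)
  if (config$f_log_variant == "quotient") {
    f2 <- log(m0 / n)
    f3 <- ifelse(!is.na(IF) & WL > 0, log(IF / WL), NA_real_)
  } else {
    f2 <- log(m0 * n)
    f3 <- ifelse(!is.na(IF) & WL > 0, log(IF * WL), NA_real_)
  }
  as_wk <- function(v) matrix(v, nrow = w, ncol = k, byrow = TRUE)
  out <- cbind(expand_channel_pairs(as_wk(rms)),
               expand_channel_pairs(as_wk(f2)),
               expand_channel_pairs(as_wk(f3)))
  colnames(out) <- feature_descriptors(k)
  out
}

#' Select the least mutually correlated feature subset
#'
#' Chooses `k` feature columns approximately minimizing the maximum
#' absolute pairwise Pearson correlation. Zero-variance columns are
#' excluded before selection. When the subset space is small
#' (`choose(p, k) <= max_exhaustive`) the search is exact over all
#' subsets; otherwise a deterministic greedy procedure is used: start from
#' the feature pair with the smallest `|r|`, then repeatedly add the
#' feature whose maximum `|r|` against the chosen set is smallest, breaking
#' ties by lowest column index.
#'
#' @param x Numeric matrix, windows x features, with column names.
#' @param k Number of features to keep.
#' @param max_exhaustive Subset-count bound below which the search is
#'   exact.
#' @return A `feature_selection`: list with `descriptors` (column names),
#'   `index` (columns of `x`), `max_abs_cor` (achieved objective) and
#'   `method` (`"exhaustive"` or `"greedy"`).
#' @export
select_least_correlated <- function(x, k = 15, max_exhaustive = 1e5) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  keep <- which(apply(x, 2, stats::var, na.rm = TRUE) > 0 &
                  colSums(is.na(x)) < nrow(x))
  if (k > length(keep)) {
    stop("k exceeds the number of usable (non-constant) features",
         call. = FALSE)
  }
  A <- abs(stats::cor(x[, keep, drop = FALSE],
                      use = "pairwise.complete.obs"))
  A[is.na(A)] <- 0
  diag(A) <- 0
  p <- length(keep)
  if (k == p) {
    sel <- seq_len(p)
    method <- "all"
  } else if (k == 1) {
    sel <- 1L
    method <- "all"
  } else if (choose(p, k) <= max_exhaustive) {
    combs <- utils::combn(p, k)
    ut <- upper.tri(matrix(0, k, k))
    obj <- apply(combs, 2, function(s) max(A[s, s][ut]))
    sel <- combs[, which.min(obj)]            # which.min = first = lexicographic
    method <- "exhaustive"
  } else {
    start <- arrayInd(which.min(t(A + diag(Inf, p))), c(p, p))
    sel <- sort(c(start[1, 2], start[1, 1]))  # row-major scan => lowest index
    while (length(sel) < k) {
      cand <- setdiff(seq_len(p), sel)
      scores <- apply(A[cand, sel, drop = FALSE], 1, max)
      sel <- c(sel, cand[which.min(scores)])
    }
    sel <- sort(sel)
    method <- "greedy"
  }
  idx <- keep[sort(sel)]
  ut <- upper.tri(matrix(0, length(idx), length(idx)))
  structure(
    list(descriptors = colnames(x)[idx], index = idx,
         max_abs_cor = if (length(idx) > 1) {
           Asel <- A[sort(sel), sort(sel)]
           max(Asel[ut])
         } else 0,
         method = method),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection: %d features (%s search), max |r| = %.3f\n",
              length(x$index), x$method, x$max_abs_cor))
  cat(" ", paste(x$descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a feature selection to a feature matrix
#'
#' Subsets the selected columns and imputes undefined (`NA`) entries with
#' the supplied per-feature means (learned on training data).
#'
#' @param x Feature matrix from [compute_features()].
#' @param selection A [select_least_correlated()] result.
#' @param impute_means Named numeric vector of training means used to fill
#'   `NA`s; `NULL` leaves `NA`s in place.
#' @return Numeric matrix, windows x selected features.
#' @export
apply_selection <- function(x, selection, impute_means = NULL) {
  miss <- setdiff(selection$descriptors, colnames(x))
  if (length(miss)) {
    stop("feature matrix lacks selected descriptors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- x[, selection$descriptors, drop = FALSE]
  if (!is.null(impute_means)) {
    for (j in seq_len(ncol(out))) {
      nas <- is.na(out[, j])
      if (any(nas)) out[nas, j] <- impute_means[[colnames(out)[j]]]
    }
  }
  out
}
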