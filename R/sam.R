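#' One-class SAM d statistic
#'
#' `d_i = xbar_i / (se_i + s0)` per row, where `xbar_i` is the row mean over
#' replicate columns, `se_i` the row standard error (sample SD / sqrt(k)),
#' and `s0` the exchangeability fudge factor that keeps small-variance rows
#' from dominating.
#'
#' @param x An `sscore_set` or a numeric matrix (rows = clusters, columns =
#'   replicates, k >= 2).
#' @param s0 Fudge factor (>= 0).
#' @return Named numeric vector of d statistics.
#' @export
sam_d <- function(x, s0) {
  m <- if (is.matrix(x)) x else sscore_matrix(x)
  k <- ncol(m)
  if (k < 2) abort("need >= 2 replicate columns for a standard error")
  xbar <- rowMeans(m)
  se <- sqrt(apply(m, 1, var) / k)
  den <- se + s0
  if (any(den == 0)) {
    abort("zero denominator: constant row with s0 = 0",
          class = "probescore_degenerate_error")
  }
  setNames(xbar / den, rownames(m))
}

row_se <- function(m) {
  k <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2) / (k - 1), 0) / k)
}

#' Choose the SAM fudge factor s0
#'
#' Tusher-style tuning: candidate values are the percentiles 0, 5, ..., 100
#' of the per-row standard errors; rows are binned into standard-error
#' quantile windows, and the candidate minimizing the coefficient of
#' variation of the d statistic's MAD across windows is selected. Falls back
#' to the median standard error when the windowing is ill-conditioned
#' (too few rows, or constant standard errors).
#'
#' @inheritParams sam_d
#' @param n_windows Target number of standard-error windows.
#' @return The selected s0, with attribute `"percentile"` (NA for the
#'   median-se fallback).
#' @export
choose_s0 <- function(x, n_windows = 100) {
  m <- if (is.matrix(x)) x else sscore_matrix(x)
  xbar <- rowMeans(m)
  se <- row_se(m)
  fallback <- structure(median(se), percentile = NA_real_)
  n <- length(se)
  nw <- max(2, min(n_windows, floor(n / 10)))
  if (n < 20 || length(unique(se)) < 2) return(fallback)
  brk <- unique(quantile(se, seq(0, 1, length.out = nw + 1), names = FALSE))
  if (length(brk) < 3) return(fallback)
  win <- cut(se, brk, include.lowest = TRUE)
  probs <- seq(0, 1, 0.05)
  cand <- quantile(se, probs, names = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- xbar / (se + s0)
    mads <- tapply(d, win, mad)
    mads <- mads[is.finite(mads)]
    mu <- mean(mads)
    if (length(mads) < 2 || !is.finite(mu) || mu == 0) return(Inf)
    sd(mads) / mu
  }, numeric(1))
  if (all(!is.finite(cv))) return(fallback)
  i <- which.min(cv)
  structure(cand[i], percentile = 100 * probs[i])
}

sign_patterns <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  dimnames(g) <- NULL
  t(g)  # k x 2^k
}

#' Sign-flip permutation null for one-class SAM
#'
#' Each permutation multiplies each replicate column by +/-1 and recomputes
#' the d statistic with the same s0 (a one-class analysis has no group
#' labels to permute). When `2^k <= n_perm` all sign patterns are enumerated
#' exactly and the result is seed-independent; otherwise `n_perm` random
#' patterns are drawn.
#'
#' @inheritParams sam_d
#' @param n_perm Number of permutations requested.
#' @param seed Seed for the sampled (non-exhaustive) case.
#' @return Matrix of null d values (rows = clusters, columns =
#'   permutations), with attribute `"exact"`.
#' @export
sam_permutation_null <- function(x, s0, n_perm = 1000, seed = 1L) {
  m <- if (is.matrix(x)) x else sscore_matrix(x)
  k <- ncol(m)
  if (k < 2) abort("need >= 2 replicate columns")
  exact <- 2^k <= n_perm
  signs <- if (exact) {
    sign_patterns(k)
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), k, n_perm))
  }
  p <- ncol(signs)
  mu <- (m %*% signs) / k          # row means under each sign pattern
  ss <- rowSums(m^2)               # invariant to sign flips
  v <- pmax((ss - k * mu^2) / (k - 1), 0)
  d <- mu / (sqrt(v / k) + s0)
  attr(d, "exact") <- exact
  d
}

sam_fdr_curve <- function(d_obs, d_null, pi0) {
  cand <- sort(unique(abs(d_obs)))
  abs_obs_sorted <- sort(abs(d_obs))
  n <- length(d_obs)
  r_obs <- n - findInterval(cand, abs_obs_sorted, left.open = TRUE)
  # count |d_null| >= delta with a one-ulp-scale tie tolerance: the identity
  # sign pattern reproduces the observed d up to floating-point noise and
  # must count as an exceedance of its own threshold
  thr <- cand - 1e-9 * pmax(cand, 1)
  counts <- vapply(seq_len(ncol(d_null)), function(j) {
    s <- sort(abs(d_null[, j]))
    n - findInterval(thr, s, left.open = TRUE)
  }, numeric(length(cand)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(cand))
  v_null <- rowMeans(counts)
  fdr <- pmin(1, pi0 * v_null / pmax(r_obs, 1))
  tibble::tibble(delta = cand, n_called = r_obs, null_mean = v_null, fdr = fdr)
}

#' Call significant clusters at a target FDR (one-class SAM)
#'
#' For a symmetric threshold delta the estimated FDR is
#' `pi0 * mean_b #{|d_null_b| >= delta} / #{|d_obs| >= delta}`, with
#' `pi0` estimated from the proportion of observed d inside the central 50%
#' of the permutation null (capped at 1). The selected delta is the smallest
#' achieving the target; a cluster's q-value is the smallest estimated FDR
#' at which it would be called. If no threshold achieves the target the
#' called set is empty and `delta = Inf`.
#'
#' @param d_obs Observed d vector (named by cluster).
#' @param d_null Null d matrix from [sam_permutation_null()] (same s0).
#' @param target_fdr Target false discovery rate.
#' @param s0 The s0 used (stored in the result).
#' @param side `"both"` for symmetric two-sided calling, `"up"`/`"down"`
#'   for one-sided calling on signed d.
#' @return A `sam_result` object; see [tidy.sam_result()] and
#'   [glance.sam_result()].
#' @export
sam_call_significant <- function(d_obs, d_null, target_fdr = 0.05, s0 = NA_real_,
                                 side = c("both", "up", "down")) {
  side <- match.arg(side)
  sgn <- switch(side, both = abs, up = identity, down = function(x) -x)
  qs <- quantile(d_null, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d_obs >= qs[1] & d_obs <= qs[2]) / 0.5)
  curve <- sam_fdr_curve(sgn(d_obs), matrix(sgn(d_null), nrow = nrow(d_null)),
                         pi0)
  ok <- which(curve$fdr <= target_fdr)
  delta <- if (length(ok) > 0) curve$delta[min(ok)] else Inf
  # q_i = min FDR over thresholds <= |d_i|; running minimum over the
  # ascending candidate grid gives it and enforces monotonicity in |d|.
  q_at_cand <- cummin(curve$fdr)
  idx <- findInterval(sgn(d_obs), curve$delta)
  q <- ifelse(idx >= 1, q_at_cand[pmax(idx, 1)], 1)
  called <- sgn(d_obs) >= delta
  table <- tibble::tibble(
    cluster_id = names(d_obs) %||% as.character(seq_along(d_obs)),
    d = unname(d_obs), q = unname(q), called = unname(called)
  )
  structure(list(table = table, s0 = s0, delta = delta, pi0 = pi0,
                 target_fdr = target_fdr, side = side,
                 n_perm = ncol(d_null), exact = isTRUE(attr(d_null, "exact")),
                 fdr_curve = curve),
            class = "sam_result")
}

#' One-Class SAM on a replicate S-score matrix
#'
#' Convenience pipeline: choose s0, compute observed d, build the sign-flip
#' permutation null, and call significance at the target FDR. With k
#' replicates and `n_perm >= 2^k` the null is enumerated exactly (e.g. all
#' 512 sign patterns for the nine-replicate design).
#'
#' @inheritParams sam_d
#' @inheritParams sam_permutation_null
#' @inheritParams sam_call_significant
#' @param s0 Fudge factor; chosen by [choose_s0()] when `NULL`.
#' @return A `sam_result` object.
#' @export
sam_oneclass <- function(x, target_fdr = 0.05, n_perm = 1000, s0 = NULL,
                         seed = 1L, side = "both") {
  m <- if (is.matrix(x)) x else sscore_matrix(x)
  if (is.null(s0)) s0 <- choose_s0(m)
  d_obs <- sam_d(m, s0)
  d_null <- sam_permutation_null(m, s0, n_perm = n_perm, seed = seed)
  res <- sam_call_significant(d_obs, d_null, target_fdr = target_fdr,
                              s0 = as.numeric(s0), side = side)
  res$seed <- seed
  res
}

#' @export
print.sam_result <- function(x, ...) {
  cat("One-Class SAM: ", nrow(x$table), " clusters, k-replicate null with ",
      x$n_perm, if (x$exact) " (exact) " else " (sampled) ", "sign patterns\n",
      "s0 = ", signif(x$s0, 4), ", pi0 = ", signif(x$pi0, 3),
      ", delta = ", signif(x$delta, 4), " at target FDR ", x$target_fdr,
      ": ", sum(x$table$called), " called\n", sep = "")
  invisible(x)
}

#' Tidy a One-Class SAM result
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return Per-cluster tibble: `cluster_id`, `d`, `q`, `called`.
#' @export
tidy.sam_result <- function(x, ...) x$table

#' One-row summary of a One-Class SAM run
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return A one-row tibble: `s0`, `pi0`, `delta`, `target_fdr`, `n_called`,
#'   `n_perm`, `exact`.
#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(s0 = x$s0, pi0 = x$pi0, delta = x$delta,
                 target_fdr = x$target_fdr, n_called = sum(x$table$called),
                 n_perm = x$n_perm, exact = x$exact)
}

#' Clusters called significant by a SAM run
#'
#' @param x A `sam_result`.
#' @return Character vector of called cluster ids.
#' @export
sam_called <- function(x) x$table$cluster_id[x$table$called]
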