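# Independent oracles: naive re-derivations kept deliberately separate from
# the package's vectorized implementations.

# Exhaustive one-class SAM by explicit loops over all 2^k sign patterns.
brute_sam_oneclass <- function(m, s0, target_fdr = 0.05) {
  k <- ncol(m)
  d_fun <- function(v) mean(v) / (stats::sd(v) / sqrt(k) + s0)
  d_obs <- apply(m, 1, d_fun)
  pats <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  d_null <- sapply(seq_len(nrow(pats)), function(p) {
    apply(sweep(m, 2, pats[p, ], `*`), 1, d_fun)
  })
  qs <- stats::quantile(d_null, c(0.25, 0.75))
  pi0 <- min(1, mean(d_obs >= qs[1] & d_obs <= qs[2]) / 0.5)
  cand <- sort(unique(abs(d_obs)))
  fdr <- sapply(cand, function(del) {
    r <- sum(abs(d_obs) >= del)
    v <- mean(colSums(abs(d_null) >= del))
    min(1, pi0 * v / max(r, 1))
  })
  fdr_min <- cummin(fdr)
  q <- sapply(abs(d_obs), function(a) fdr_min[max(which(cand <= a))])
  delta <- if (any(fdr <= target_fdr)) cand[min(which(fdr <= target_fdr))] else Inf
  list(d = d_obs, pi0 = pi0, delta = delta, fdr = fdr, q = q,
       called = abs(d_obs) >= delta, null_sorted = sort(as.numeric(d_null)))
}

# Closed-form balanced two-way ANOVA with interaction from cell sums.
closed_form_two_way <- function(y, f1, f2) {
  stopifnot(length(unique(table(f1, f2))) == 1)  # balanced
  n <- unique(table(f1, f2))[1]
  grand <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  a <- nlevels(factor(f1)); b <- nlevels(factor(f2))
  ss1 <- b * n * sum((m1 - grand)^2)
  ss2 <- a * n * sum((m2 - grand)^2)
  cell_means <- outer(m1, m2, function(x1, x2) x1 + x2 - grand)
  obs_cells <- tapply(y, list(factor(f1), factor(f2)), mean)
  ss12 <- n * sum((obs_cells - cell_means)^2)
  fit_cells <- obs_cells[cbind(as.integer(factor(f1)), as.integer(factor(f2)))]
  sse <- sum((y - fit_cells)^2)
  dfe <- length(y) - a * b
  mse <- sse / dfe
  f <- c(treatment = ss1 / ((a - 1) * mse), sex = ss2 / ((b - 1) * mse),
         interaction = ss12 / ((a - 1) * (b - 1) * mse))
  p <- stats::pf(f, c(a - 1, b - 1, (a - 1) * (b - 1)), dfe, lower.tail = FALSE)
  list(F = f, p = p, mse = mse, df_error = dfe)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
enumerate_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "set"
  mean(hits >= k)
}
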