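#' Summarize probe intensities to cluster-level log2 expression
#'
#' A documented stand-in for vendor signal summarization: probe intensities
#' are log2-transformed (with an offset), optionally quantile-normalized
#' across samples, and each cluster's probes-by-samples block is decomposed
#' by median polish into probe and sample effects; the returned expression is
#' overall + sample effect, so fixed per-probe affinities are absorbed by the
#' probe effects.
#'
#' @param pm A [probe_matrix()].
#' @param offset Added before the log2 transform (default 1).
#' @param normalize `"quantile"` (default) or `"none"`.
#' @return An `expression_matrix` tibble: `cluster_id` plus one log2 column
#'   per sample.
#' @export
summarize_clusters <- function(pm, offset = 1, normalize = c("quantile", "none")) {
  pm <- probe_matrix(pm)
  normalize <- match.arg(normalize)
  m <- log2(probe_intensity_matrix(pm) + offset)
  if (normalize == "quantile") m <- limma::normalizeQuantiles(m)
  cl <- factor(pm$cluster_id, levels = unique(pm$cluster_id))
  blocks <- split.data.frame(m, cl)
  expr <- t(vapply(blocks, function(b) {
    if (nrow(b) == 1) return(as.numeric(b))
    mp <- medpolish(b, trace.iter = FALSE, maxiter = 50)
    mp$overall + mp$col
  }, numeric(ncol(m))))
  out <- dplyr::bind_cols(tibble::tibble(cluster_id = levels(cl)),
                          tibble::as_tibble(expr, .name_repair = "minimal"))
  names(out) <- c("cluster_id", colnames(m))
  class(out) <- c("expression_matrix", class(tibble::tibble()))
  out
}

expression_values <- function(expr) {
  m <- as.matrix(as.data.frame(expr[setdiff(names(expr), "cluster_id")]))
  rownames(m) <- expr$cluster_id
  m
}

#' Per-cluster two-factor (treatment x sex) linear models
#'
#' Fits `~ treatment * sex` with sum-to-zero contrasts to every cluster of a
#' log2 expression matrix within one age group and reports Type-III F tests
#' for the treatment and sex main effects and their interaction (each 1 df
#' for two-level factors, so the Type-III F equals the squared Wald t of the
#' corresponding sum-to-zero coefficient). By default residual variances are
#' shrunk toward a pooled prior by empirical-Bayes moderation
#' (limma-style squeezing); `moderate = FALSE` gives the ordinary per-cluster
#' ANOVA.
#'
#' @param expr An `expression_matrix` from [summarize_clusters()].
#' @param design A [design_table()] covering the expression samples.
#' @param age Optional single age group to restrict to (the two ages are
#'   analyzed separately).
#' @param moderate Apply empirical-Bayes variance moderation.
#' @param prior_df Override the moderation prior degrees of freedom
#'   (`Inf` replaces every residual variance by the pooled prior; `NULL`
#'   estimates it from the data).
#' @return An `lm_result` tibble, one row per cluster x term
#'   (`treatment`, `sex`, `interaction`) with `estimate` (sum-to-zero
#'   coefficient), `statistic` (F), `p.value`, `df1`, `df2`, `moderated`;
#'   per-cluster residual and posterior variances are attached as attribute
#'   `"variances"`.
#' @export
fit_two_factor <- function(expr, design, age = NULL, moderate = TRUE,
                           prior_df = NULL) {
  design <- design_table(design)
  if (!is.null(age)) design <- design[design$age_group %in% age, ]
  samples <- intersect(design$sample_id, setdiff(names(expr), "cluster_id"))
  design <- design[match(samples, design$sample_id), ]
  y <- expression_values(expr)[, samples, drop = FALSE]
  cells <- table(design$treatment, design$sex)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(paste0("empty design cell: treatment=", rownames(cells)[empty[1]],
                 ", sex=", colnames(cells)[empty[2]],
                 " (interaction model needs all four cells)"),
          class = "probescore_validation_error")
  }
  if (sum(cells >= 2) < 3) {
    abort("need >= 2 samples in at least 3 of the 4 design cells",
          class = "probescore_validation_error")
  }
  df <- data.frame(
    treatment = factor(design$treatment, levels = treatment_levels),
    sex = factor(design$sex, levels = sex_levels)
  )
  x <- stats::model.matrix(~ treatment * sex, df,
                           contrasts.arg = list(treatment = "contr.sum",
                                                sex = "contr.sum"))
  n <- nrow(x)
  p <- ncol(x)
  df_resid <- n - p
  if (df_resid < 1) abort("no residual degrees of freedom")
  xtx_inv <- solve(crossprod(x))
  beta <- y %*% x %*% xtx_inv          # m x p coefficient matrix
  fitted <- beta %*% t(x)
  s2 <- rowSums((y - fitted)^2) / df_resid
  # constant rows: numerically zero coefficients and variance, F = 0, p = 1
  const_row <- apply(y, 1, var) == 0
  if (any(const_row)) {
    beta[const_row, -1] <- 0
    s2[const_row] <- 0
  }
  if (moderate) {
    if (is.null(prior_df)) {
      sq <- limma::squeezeVar(s2, df_resid)
      s2_post <- sq$var.post
      d0 <- sq$df.prior
    } else {
      s2_prior <- mean(s2)
      d0 <- prior_df
      s2_post <- if (is.infinite(d0)) rep(s2_prior, length(s2)) else {
        (d0 * s2_prior + df_resid * s2) / (d0 + df_resid)
      }
    }
    df_total <- df_resid + d0
  } else {
    s2_post <- s2
    df_total <- df_resid
  }
  terms <- c(treatment = 2L, sex = 3L, interaction = 4L)
  cjj <- diag(xtx_inv)
  rows <- lapply(names(terms), function(tm) {
    b <- beta[, terms[[tm]]]
    den <- s2_post * cjj[[terms[[tm]]]]
    f <- ifelse(den > 0, b^2 / den, ifelse(b == 0, 0, Inf))
    pv <- ifelse(is.finite(f), pf(f, 1, df_total, lower.tail = FALSE),
                 0)
    pv[den <= 0 & b == 0] <- 1
    tibble::tibble(cluster_id = rownames(y), term = tm, estimate = unname(b),
                   statistic = unname(f), p.value = unname(pv),
                   df1 = 1, df2 = unname(df_total))
  })
  out <- dplyr::bind_rows(rows)
  out$moderated <- isTRUE(moderate)
  out <- dplyr::arrange(out, match(.data$term, names(terms)), .data$cluster_id)
  class(out) <- c("lm_result", class(tibble::tibble()))
  attr(out, "variances") <- tibble::tibble(cluster_id = rownames(y),
                                           s2_resid = unname(s2),
                                           s2_post = unname(s2_post))
  attr(out, "df_resid") <- df_resid
  out
}

#' Select significant clusters from a two-factor fit
#'
#' Clusters with an uncorrected p-value below `alpha` for the requested
#' term, sorted by p-value.
#'
#' @param lm An `lm_result` from [fit_two_factor()].
#' @param alpha Uncorrected p-value cutoff (default 0.01).
#' @param term One of `"treatment"`, `"sex"`, `"interaction"`.
#' @return Tibble `cluster_id`, `p.value`, sorted ascending.
#' @export
select_significant <- function(lm, alpha = 0.01,
                               term = c("treatment", "sex", "interaction")) {
  term <- match.arg(term)
  out <- lm[lm$term == term & lm$p.value < alpha,
            c("cluster_id", "p.value")]
  dplyr::arrange(tibble::as_tibble(out), .data$p.value)
}

#' Intersect two significant-cluster lists
#'
#' Set semantics (duplicates ignored), with counts, for comparing calls from
#' two analysis tracks or two ages.
#'
#' @param a,b Character vectors of cluster ids.
#' @return List with `common`, `a_only`, `b_only` and a `counts` tibble.
#' @export
intersect_lists <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  out <- list(common = intersect(a, b), a_only = setdiff(a, b),
              b_only = setdiff(b, a))
  out$counts <- tibble::tibble(n_a = length(a), n_b = length(b),
                               n_common = length(out$common),
                               n_a_only = length(out$a_only),
                               n_b_only = length(out$b_only))
  out
}
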