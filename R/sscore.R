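#' Error-model parameters for a chip pair
#'
#' The S-score standardizes per-probe between-chip differences by an
#' intensity-dependent error estimate
#' `eps_j = gamma * (s_T I_jT + s_C I_jC) + alpha`: a multiplicative
#' coefficient `gamma` (> 0), an additive floor `alpha` (>= 0, intensity
#' units), and per-chip normalization multipliers `scale_factors` (> 0),
#' named by sample when fitted from a probe matrix.
#'
#' @param gamma Multiplicative-error coefficient.
#' @param alpha Additive-error floor.
#' @param scale_factors Length-2 positive multipliers, ordered (treated,
#'   control) or named by sample id.
#' @return An `error_model_params` object.
#' @export
error_model_params <- function(gamma, alpha, scale_factors) {
  if (!is.finite(gamma) || gamma <= 0) {
    abort("gamma must be > 0", class = "probescore_validation_error")
  }
  if (!is.finite(alpha) || alpha < 0) {
    abort("alpha must be >= 0", class = "probescore_validation_error")
  }
  if (length(scale_factors) != 2 || any(!is.finite(scale_factors)) ||
      any(scale_factors <= 0)) {
    abort("scale_factors must be 2 positive values",
          class = "probescore_validation_error")
  }
  structure(list(gamma = gamma, alpha = alpha, scale_factors = scale_factors),
            class = "error_model_params")
}

#' @export
print.error_model_params <- function(x, ...) {
  cat("Error model: gamma =", signif(x$gamma, 4), " alpha =", signif(x$alpha, 4),
      " scale factors =", paste(signif(x$scale_factors, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the chip-pair error model
#'
#' Per-chip scale factors equalize trimmed mean intensity between the two
#' chips (each chip is scaled to the geometric mean of the two trimmed
#' means). `gamma` is then calibrated robustly so that over the central 50%
#' of summed intensities the median absolute standardized difference equals
#' the standard-normal reference value 0.6745; `alpha` is set from the
#' low-intensity quartile so that standardized differences there are not
#' over-dispersed. Median-based calibration keeps genuinely differential
#' probes, which are outliers under the null fit, from inflating the error
#' model.
#'
#' @param chip_a,chip_b Intensity vectors over a shared probe set (treated
#'   first by convention), or a [probe_matrix()] with two sample ids.
#' @param trim Trim fraction for the scale-factor means.
#' @return An [error_model_params()] object.
#' @export
estimate_error_model <- function(chip_a, chip_b, trim = 0.02) {
  nms <- NULL
  if (inherits(chip_a, "probe_matrix")) {
    pm <- chip_a
    ids <- chip_b
    if (length(ids) != 2 || !all(ids %in% probe_samples(pm))) {
      abort("chip_b must give two sample ids present in the probe matrix")
    }
    nms <- ids
    chip_a <- pm[[ids[1]]]
    chip_b <- pm[[ids[2]]]
  }
  if (length(chip_a) != length(chip_b)) {
    abort("chips must share the probe set", class = "probescore_validation_error")
  }
  ma <- mean(chip_a, trim = trim)
  mb <- mean(chip_b, trim = trim)
  if (ma <= 0 || mb <= 0) {
    abort("degenerate input: chip with non-positive trimmed mean intensity",
          class = "probescore_degenerate_error")
  }
  target <- sqrt(ma * mb)
  sf <- c(target / ma, target / mb)
  if (!is.null(nms)) names(sf) <- nms
  a <- sf[[1]] * chip_a
  b <- sf[[2]] * chip_b
  d <- a - b
  tt <- a + b
  qs <- quantile(tt, c(0.25, 0.75), names = FALSE)
  central <- tt >= qs[1] & tt <= qs[2] & tt > 0
  gamma <- median(abs(d[central]) / tt[central]) / 0.6745
  if (!is.finite(gamma) || gamma <= 0) gamma <- 1e-8
  low <- tt < qs[1]
  alpha <- 0
  if (sum(low) >= 10) {
    alpha <- max(0, median(abs(d[low])) / 0.6745 - gamma * median(tt[low]))
  }
  error_model_params(gamma = gamma, alpha = alpha, scale_factors = sf)
}

#' Per-cluster S-scores between a treated and a control chip
#'
#' For each probe j,
#' `z_j = (s_T I_jT - s_C I_jC) / (gamma (s_T I_jT + s_C I_jC) + alpha)`;
#' per transcript cluster g the probe measurements are summed and scaled,
#' `S_g = sum(z_j) / sqrt(n_g)`, so that under the null (equalized,
#' independent probe errors) S is standard normal. Positive scores mean
#' higher intensity in the treated chip. By default a final per-pair
#' standardization (subtract the median, divide by MAD/0.6745 of the score
#' vector) is applied, which enforces the advertised N(0,1) null even when
#' the error model is misspecified; disable with `standardize = FALSE`.
#'
#' @param pm A [probe_matrix()].
#' @param treated_id,control_id Sample ids of the pair.
#' @param params Optional fixed [error_model_params()]; fitted from the pair
#'   when `NULL`.
#' @param standardize Apply the final median/MAD standardization.
#' @return A tibble `cluster_id`, `n_probes`, `sscore`, with the fitted
#'   `params` and the `standardize` flag as attributes.
#' @export
compute_sscore_pair <- function(pm, treated_id, control_id, params = NULL,
                                standardize = TRUE) {
  pm <- probe_matrix(pm)
  for (id in c(treated_id, control_id)) {
    if (!id %in% probe_samples(pm)) abort(paste0("no sample '", id, "'"))
  }
  if (is.null(params)) {
    params <- estimate_error_model(pm, c(treated_id, control_id))
  }
  sf <- params$scale_factors
  if (!is.null(names(sf))) {
    if (!all(c(treated_id, control_id) %in% names(sf))) {
      abort("params scale_factors do not name this pair's samples")
    }
    s_t <- sf[[treated_id]]
    s_c <- sf[[control_id]]
  } else {
    s_t <- sf[[1]]
    s_c <- sf[[2]]
  }
  it <- s_t * pm[[treated_id]]
  ic <- s_c * pm[[control_id]]
  eps <- params$gamma * (it + ic) + params$alpha
  if (any(eps == 0)) {
    abort("degenerate input: zero error estimate (zero intensities with alpha = 0)",
          class = "probescore_degenerate_error")
  }
  z <- (it - ic) / eps
  cl <- factor(pm$cluster_id, levels = unique(pm$cluster_id))
  n_g <- as.integer(table(cl))
  s <- as.numeric(rowsum(z, cl)) / sqrt(n_g)
  if (isTRUE(standardize)) {
    scale <- mad(s)  # = median absolute deviation / 0.6745
    if (is.finite(scale) && scale > 0) s <- (s - median(s)) / scale
  }
  out <- tibble::tibble(cluster_id = levels(cl), n_probes = n_g, sscore = s)
  attr(out, "params") <- params
  attr(out, "standardized") <- isTRUE(standardize)
  out
}

#' Assemble the replicate S-score matrix for a design
#'
#' One pairwise S-score vector per treated/control pair in the design, each
#' pair fitted and computed within its own sex (pairs are same-sex by
#' construction); sexes enter as separate columns of the same matrix and are
#' only pooled downstream by One-Class SAM. Each pair is treated as one
#' biological replicate. Treated samples without a `pair_id` are excluded
#' with a warning.
#'
#' @param pm A [probe_matrix()].
#' @param design A [design_table()] with pair assignments.
#' @param age Optional age group to restrict the analysis to (the two ages
#'   are analyzed separately).
#' @inheritParams compute_sscore_pair
#' @return An `sscore_set`: a tibble `cluster_id`, `n_probes`, then one
#'   column of S-scores per `pair_id`; per-pair [error_model_params()] are
#'   attached as attribute `"params"`.
#' @export
assemble_replicate_sscores <- function(pm, design, age = NULL,
                                       standardize = TRUE) {
  pm <- probe_matrix(pm)
  design <- design_table(design)
  d <- design
  if (!is.null(age)) d <- d[d$age_group %in% age, ]
  unpaired <- d$sample_id[d$treatment == "ethanol" & is.na(d$pair_id)]
  if (length(unpaired) > 0) {
    warn(paste0("excluding unpaired treated sample(s): ",
                paste(unpaired, collapse = ", ")))
  }
  pairs <- design_pairs(d)
  if (nrow(pairs) == 0) {
    abort("design has no treated/control pairs", class = "probescore_validation_error")
  }
  cols <- list()
  params <- list()
  base <- NULL
  for (i in seq_len(nrow(pairs))) {
    s <- compute_sscore_pair(pm, pairs$treated_id[i], pairs$control_id[i],
                             standardize = standardize)
    if (is.null(base)) base <- s[c("cluster_id", "n_probes")]
    cols[[pairs$pair_id[i]]] <- s$sscore
    params[[pairs$pair_id[i]]] <- attr(s, "params")
  }
  out <- dplyr::bind_cols(base, tibble::as_tibble(cols))
  class(out) <- c("sscore_set", class(tibble::tibble()))
  attr(out, "params") <- params
  attr(out, "pairs") <- pairs
  attr(out, "standardized") <- isTRUE(standardize)
  out
}

#' S-score replicate columns of an sscore_set as a numeric matrix
#'
#' @param x An `sscore_set` (or any tibble with `cluster_id` and score
#'   columns).
#' @return Numeric matrix, rows named by `cluster_id`, one column per
#'   replicate pair.
#' @export
sscore_matrix <- function(x) {
  cols <- setdiff(names(x), c("cluster_id", "n_probes"))
  m <- as.matrix(as.data.frame(x[cols]))
  rownames(m) <- x$cluster_id
  m
}

#' @export
tidy.sscore_set <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = -c("cluster_id", "n_probes"),
                      names_to = "pair_id", values_to = "sscore")
}
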