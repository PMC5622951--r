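#' Relative qPCR expression against multiple reference genes
#'
#' Delta-delta-Ct quantification: technical wells are averaged per
#' sample x gene; each target's delta-Ct is its Ct minus the arithmetic mean
#' of the reference-gene Cts for that sample (equivalent to geometric-mean
#' normalization on the expression scale); relative quantity `2^-deltaCt` is
#' then rescaled per target so that the baseline group's mean is exactly 1.
#' Adding a constant to every Ct of one sample cancels in the reference
#' normalization.
#'
#' @param ct A `ct_table` (columns `sample_id`, `target`, `well`, `ct`).
#' @param refs Reference (endogenous control) gene names.
#' @param groups A data frame `sample_id`, `group`.
#' @param baseline_group Group whose mean relative quantity is fixed at 1
#'   (e.g. the control male group).
#' @return Tibble `sample_id`, `group`, `target`, `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct, refs, groups, baseline_group) {
  ct <- tibble::as_tibble(ct)
  groups <- tibble::as_tibble(groups)
  if (!baseline_group %in% groups$group) {
    abort(paste0("baseline group '", baseline_group, "' not in groups"),
          class = "probescore_validation_error")
  }
  avg <- ct |>
    dplyr::group_by(.data$sample_id, .data$target) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref_ct <- avg |>
    dplyr::filter(.data$target %in% refs) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_ref = dplyr::n(), ref_ct = mean(.data$ct), .groups = "drop")
  bad <- ref_ct$sample_id[ref_ct$n_ref < length(refs)]
  no_ref <- setdiff(unique(avg$sample_id), ref_ct$sample_id)
  if (length(c(bad, no_ref)) > 0) {
    missing_pairs <- tidyr::expand_grid(sample_id = c(bad, no_ref), target = refs) |>
      dplyr::anti_join(avg, by = c("sample_id", "target"))
    abort(paste0("missing reference Ct: ",
                 paste(paste0(missing_pairs$sample_id, "/", missing_pairs$target),
                       collapse = ", ")),
          class = "probescore_validation_error")
  }
  out <- avg |>
    dplyr::filter(!.data$target %in% refs) |>
    dplyr::left_join(ref_ct[c("sample_id", "ref_ct")], by = "sample_id") |>
    dplyr::left_join(groups, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct,
                  rel_expr = 2^(-.data$delta_ct))
  out <- out |>
    dplyr::group_by(.data$target) |>
    dplyr::mutate(rel_expr = .data$rel_expr /
                    mean(.data$rel_expr[.data$group == baseline_group])) |>
    dplyr::ungroup()
  out[, c("sample_id", "group", "target", "delta_ct", "rel_expr")]
}

#' Back-calculate ELISA concentrations from a linear standard curve
#'
#' Fits optical density on standard concentration by least squares and
#' inverts the line for the samples; the per-sample amount is divided by the
#' protein input to give ng per microgram. Sample ODs outside the standards'
#' OD range are rejected unless extrapolation is allowed.
#'
#' @param plate An `elisa_plate` (see [simulate_elisa_plate()]) or a list
#'   with `standards` (`concentration`, `od`) and `samples`
#'   (`sample_id`, `od`, `protein_ug`).
#' @param allow_extrapolation Permit sample ODs outside the standard range.
#' @return Tibble `sample_id`, `od`, `concentration`, `ng_per_ug`; the
#'   fitted curve (`slope`, `intercept`, `r_squared`) is attached as
#'   attribute `"curve"`.
#' @export
elisa_concentration <- function(plate, allow_extrapolation = FALSE) {
  std <- tibble::as_tibble(plate$standards)
  smp <- tibble::as_tibble(plate$samples)
  if (nrow(std) < 3 || any(diff(std$concentration) <= 0)) {
    abort("need >= 3 standards with strictly increasing concentration",
          class = "probescore_validation_error")
  }
  fit <- lm(od ~ concentration, data = std)
  slope <- coef(fit)[["concentration"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (slope <= 0) {
    abort("standard-curve failure: non-positive slope",
          class = "probescore_degenerate_error")
  }
  rng <- range(std$od)
  out_of_range <- smp$od < rng[1] | smp$od > rng[2]
  if (any(out_of_range) && !allow_extrapolation) {
    abort(paste0("sample OD outside standard range: ",
                 paste(smp$sample_id[out_of_range], collapse = ", ")),
          class = "probescore_validation_error")
  }
  conc <- (smp$od - intercept) / slope
  out <- tibble::tibble(sample_id = smp$sample_id, od = smp$od,
                        concentration = conc,
                        ng_per_ug = conc / smp$protein_ug)
  sst <- sum((std$od - mean(std$od))^2)
  attr(out, "curve") <- tibble::tibble(
    slope = slope, intercept = intercept,
    r_squared = if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  )
  out
}
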