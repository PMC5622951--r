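# Seeded generators with known ground truth for every downstream stage.
# All generators are pure functions of (spec, seed): RNG state is isolated
# and restored, so the same seed is byte-reproducible.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Default paired study design
#'
#' Two ages by two sexes by ethanol/control with 5 male and 4 female
#' treated-control pairs per age, mirroring the structure under which nine
#' pairwise S-score replicates per age arise.
#'
#' @param ages Age groups to include.
#' @param pairs_per_sex Named integer vector of pairs per sex.
#' @return A [design_table()].
#' @export
default_study_design <- function(ages = c("adolescent_PND43", "adult_PND66"),
                                 pairs_per_sex = c(M = 5, F = 4)) {
  rows <- list()
  for (age in ages) {
    age_tag <- if (startsWith(age, "adolescent")) "adol" else "adult"
    for (sex in names(pairs_per_sex)) {
      for (i in seq_len(pairs_per_sex[[sex]])) {
        pid <- paste(age_tag, sex, i, sep = "_")
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste0(pid, c("_E", "_C")),
          age_group = age, sex = sex,
          treatment = c("ethanol", "control"),
          pair_id = pid
        )
      }
    }
  }
  design_table(dplyr::bind_rows(rows))
}

#' Specification for the synthetic probe-level array generator
#'
#' Defaults emulate the study scale at desk size: 2 ages x 2 sexes x 2
#' treatments with 5 male + 4 female treated-control pairs per age, 5,000
#' transcript clusters x 4 probes. The noise model is
#' multiplicative-plus-additive with fixed per-probe affinities:
#' `I = a_j * x_gc * exp(eta) + N(background, add_noise_sd^2)`, truncated at
#' zero, where `a_j ~ logNormal(0, affinity_sd^2)` and
#' `eta ~ N(0, mult_noise_sd^2)`. Differential clusters carry a
#' multiplicative `effect_size` in ethanol-treated samples.
#'
#' @param n_clusters Number of transcript clusters.
#' @param probes_per_cluster Probes per cluster; a single count or a
#'   `c(min, max)` range sampled uniformly.
#' @param design A [design_table()] template.
#' @param n_de Number of differential clusters (`<= n_clusters`).
#' @param effect_size Multiplicative fold change in treated samples for
#'   differential clusters (> 0).
#' @param affinity_sd Log-scale spread of fixed per-probe affinities.
#' @param mult_noise_sd Log-scale sigma of multiplicative noise.
#' @param add_noise_sd SD of additive background noise (intensity units).
#' @param background Mean additive background offset (intensity units).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-cluster
#'   baseline expression.
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_clusters = 5000,
                            probes_per_cluster = 4,
                            design = default_study_design(),
                            n_de = 0,
                            effect_size = 2,
                            affinity_sd = 0.5,
                            mult_noise_sd = 0.1,
                            add_noise_sd = 20,
                            background = 50,
                            baseline_meanlog = log(300),
                            baseline_sdlog = 1,
                            seed = 1L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               probes_per_cluster = as.integer(probes_per_cluster),
               design = design_table(design), n_de = as.integer(n_de),
               effect_size = effect_size, affinity_sd = affinity_sd,
               mult_noise_sd = mult_noise_sd, add_noise_sd = add_noise_sd,
               background = background, baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog, seed = as.integer(seed))
  if (spec$n_clusters < 1) abort("n_clusters must be >= 1")
  if (spec$n_de > spec$n_clusters) {
    abort("n_de must not exceed n_clusters", class = "probescore_validation_error")
  }
  if (spec$effect_size <= 0) {
    abort("effect_size must be > 0", class = "probescore_validation_error")
  }
  for (f in c("affinity_sd", "mult_noise_sd", "add_noise_sd")) {
    if (spec[[f]] < 0) {
      abort(paste(f, "must be >= 0"), class = "probescore_validation_error")
    }
  }
  if (!length(spec$probes_per_cluster) %in% c(1, 2) ||
      any(spec$probes_per_cluster < 1)) {
    abort("probes_per_cluster must be a positive count or c(min, max) range",
          class = "probescore_validation_error")
  }
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate probe-level array data with known ground truth
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `probes` (a [probe_matrix()]), `design`
#'   (the spec's [design_table()]) and `truth` (a tibble of differential
#'   clusters with their true fold changes).
#' @export
simulate_probe_data <- function(spec) {
  spec <- do.call(simulation_spec, unclass(spec))
  design <- spec$design
  with_seed(spec$seed, {
    npc <- if (length(spec$probes_per_cluster) == 1) {
      rep(spec$probes_per_cluster, spec$n_clusters)
    } else {
      sample(spec$probes_per_cluster[1]:spec$probes_per_cluster[2],
             spec$n_clusters, replace = TRUE)
    }
    cluster_ids <- sprintf("TC%05d", seq_len(spec$n_clusters))
    cluster_of <- rep(cluster_ids, npc)
    n_probes <- length(cluster_of)
    probe_ids <- paste0(cluster_of, "_p",
                        unlist(lapply(npc, seq_len), use.names = FALSE))
    baseline <- rlnorm(spec$n_clusters, spec$baseline_meanlog, spec$baseline_sdlog)
    de_idx <- if (spec$n_de > 0) sample.int(spec$n_clusters, spec$n_de) else integer()
    fold <- rep(1, spec$n_clusters)
    fold[de_idx] <- spec$effect_size
    affinity <- rlnorm(n_probes, 0, spec$affinity_sd)
    n_samp <- nrow(design)
    expr <- outer(baseline, rep(1, n_samp))
    treated <- design$treatment == "ethanol"
    expr[, treated] <- expr[, treated] * fold
    signal <- affinity * expr[rep(seq_len(spec$n_clusters), npc), , drop = FALSE]
    mult <- if (spec$mult_noise_sd > 0) {
      matrix(exp(rnorm(n_probes * n_samp, 0, spec$mult_noise_sd)), n_probes, n_samp)
    } else 1
    addv <- matrix(rnorm(n_probes * n_samp, spec$background, spec$add_noise_sd),
                   n_probes, n_samp)
    intensities <- pmax(signal * mult + addv, 0)
    colnames(intensities) <- design$sample_id
    pm <- probe_matrix(dplyr::bind_cols(
      tibble::tibble(probe_id = probe_ids, cluster_id = cluster_of),
      tibble::as_tibble(intensities)
    ))
    truth <- tibble::tibble(cluster_id = cluster_ids[de_idx],
                            fold = spec$effect_size)
    list(probes = pm, design = design, truth = truth)
  })
}

#' Simulate a behavioral cohort with known group means
#'
#' Gaussian per-animal draws around specified group means. Every column of
#' `groups` other than `n`, `mean`, `sd` is treated as a grouping factor and
#' carried onto the per-animal rows.
#'
#' @param groups A data frame with factor columns plus `n` (>= 2 per group),
#'   `mean` and `sd` (>= 0).
#' @param measure Name of the measured endpoint.
#' @param seed Integer seed.
#' @return A tibble with one row per animal (`animal_id`, factor columns,
#'   `measure`, `value`); the ground-truth group table is attached as
#'   attribute `"truth"`.
#' @export
simulate_behavior_cohort <- function(groups, measure = "value", seed = 1L) {
  groups <- tibble::as_tibble(groups)
  req <- c("n", "mean", "sd")
  if (!all(req %in% names(groups))) {
    abort("groups must have columns n, mean, sd", class = "probescore_format_error")
  }
  if (any(groups$sd < 0)) {
    abort("group sd must be >= 0", class = "probescore_validation_error")
  }
  if (any(groups$n < 2)) {
    abort("each group needs n >= 2", class = "probescore_validation_error")
  }
  factors <- setdiff(names(groups), req)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      out <- g[rep(1, g$n), factors, drop = FALSE]
      out$value <- rnorm(g$n, g$mean, g$sd)
      out
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::bind_cols(
      tibble::tibble(animal_id = sprintf("A%03d", seq_len(nrow(out)))), out
    )
    out$measure <- measure
    out <- out[, c("animal_id", factors, "measure", "value")]
    attr(out, "truth") <- groups
    out
  })
}

#' Simulate a qPCR Ct table with known expression ratios
#'
#' Each gene has a baseline Ct; expression enters as
#' `Ct = base_ct - log2(expression) + N(0, ct_sd^2)` per technical well.
#' Reference genes have expression 1 in every sample; targets carry the
#' group-specific true ratio. Technical wells default to triplicate.
#'
#' @param targets Character vector of target gene names.
#' @param refs Endogenous control genes (default the three-reference panel
#'   PPP2r2p, Ublcp1, B2M).
#' @param design A data frame with columns `sample_id` and `group`.
#' @param true_ratios A data frame `target`, `group`, `ratio` (> 0); missing
#'   combinations default to ratio 1.
#' @param base_ct Optional named vector of per-gene baseline Cts; defaults
#'   stagger the references at distinct values.
#' @param ct_sd Per-well Ct noise SD (cycles).
#' @param n_tech Technical wells per sample x gene.
#' @param seed Integer seed.
#' @return A `ct_table` tibble (`sample_id`, `target`, `well`, `ct`) with the
#'   true ratio table attached as attribute `"truth"`.
#' @export
simulate_qpcr <- function(targets, refs = c("PPP2r2p", "Ublcp1", "B2M"),
                          design, true_ratios = NULL, base_ct = NULL,
                          ct_sd = 0.25, n_tech = 3, seed = 1L) {
  design <- tibble::as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("design must have columns sample_id, group",
          class = "probescore_format_error")
  }
  genes <- c(targets, refs)
  if (is.null(base_ct)) {
    base_ct <- setNames(c(rep(26, length(targets)),
                          20 + 2 * (seq_along(refs) - 1)), genes)
  }
  if (!all(genes %in% names(base_ct))) {
    abort("base_ct must name every target and reference gene")
  }
  ratios <- if (is.null(true_ratios)) {
    tibble::tibble(target = character(), group = character(), ratio = numeric())
  } else tibble::as_tibble(true_ratios)
  if (nrow(ratios) > 0 && any(ratios$ratio <= 0)) {
    abort("true ratios must be > 0", class = "probescore_validation_error")
  }
  grid <- tidyr::expand_grid(sample_id = design$sample_id, target = genes,
                             well = seq_len(n_tech))
  grid <- dplyr::left_join(grid, design, by = "sample_id")
  grid <- dplyr::left_join(grid, ratios, by = c("target", "group"))
  grid$ratio[is.na(grid$ratio) | grid$target %in% refs] <- 1
  with_seed(seed, {
    grid$ct <- base_ct[grid$target] - log2(grid$ratio) +
      rnorm(nrow(grid), 0, ct_sd)
    out <- grid[, c("sample_id", "target", "well", "ct")]
    attr(out, "truth") <- ratios
    class(out) <- c("ct_table", class(tibble::tibble()))
    out
  })
}

#' Simulate an ELISA plate read against a linear standard curve
#'
#' Optical density is `intercept + slope * concentration + N(0, od_sd^2)` for
#' standards and samples alike.
#'
#' @param standard_conc Strictly increasing standard concentrations (>= 3).
#' @param sample_conc True sample concentrations (named vector or unnamed).
#' @param slope,intercept Standard-curve parameters (OD per concentration
#'   unit; OD).
#' @param od_sd OD noise SD.
#' @param protein_ug Protein input per sample (micrograms), recycled.
#' @param seed Integer seed.
#' @return An `elisa_plate` list: `standards` tibble (`concentration`, `od`),
#'   `samples` tibble (`sample_id`, `od`, `protein_ug`), and `truth`.
#' @export
simulate_elisa_plate <- function(standard_conc, sample_conc, slope = 0.1,
                                 intercept = 0.05, od_sd = 0, protein_ug = 5,
                                 seed = 1L) {
  if (length(standard_conc) < 3) {
    abort("at least 3 standards are required", class = "probescore_validation_error")
  }
  if (any(diff(standard_conc) <= 0)) {
    abort("standard concentrations must be strictly increasing",
          class = "probescore_validation_error")
  }
  ids <- names(sample_conc) %||% sprintf("S%02d", seq_along(sample_conc))
  with_seed(seed, {
    plate <- list(
      standards = tibble::tibble(
        concentration = standard_conc,
        od = intercept + slope * standard_conc +
          rnorm(length(standard_conc), 0, od_sd)
      ),
      samples = tibble::tibble(
        sample_id = ids,
        od = intercept + slope * unname(sample_conc) +
          rnorm(length(sample_conc), 0, od_sd),
        protein_ug = rep_len(protein_ug, length(sample_conc))
      ),
      truth = tibble::tibble(sample_id = ids, concentration = unname(sample_conc))
    )
    class(plate) <- "elisa_plate"
    plate
  })
}
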