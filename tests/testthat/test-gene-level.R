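test_that("single-probe clusters summarize to their normalized log2 values", {
  pm <- probe_matrix(tibble::tibble(
    probe_id = paste0("P", 1:3), cluster_id = paste0("TC", 1:3),
    a = c(100, 200, 300), b = c(150, 250, 350)
  ))
  expr <- summarize_clusters(pm, normalize = "none")
  expect_equal(expr$a, log2(c(100, 200, 300) + 1))
  expect_equal(expr$b, log2(c(150, 250, 350) + 1))
})

test_that("summarization is invariant to probe order and probe affinity", {
  sim <- simulate_probe_data(simulation_spec(n_clusters = 40,
                                             probes_per_cluster = c(2, 6),
                                             design = nine_pair_design(),
                                             seed = 13))
  pm <- sim$probes
  e1 <- summarize_clusters(pm)
  set.seed(1)
  shuffled <- pm |>
    dplyr::group_by(cluster_id) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::ungroup()
  e2 <- summarize_clusters(probe_matrix(shuffled[names(pm)]))
  expect_equal(as.data.frame(e1[order(e1$cluster_id), ]),
               as.data.frame(e2[order(e2$cluster_id), ]),
               tolerance = 1e-12)

  # fixed per-probe affinities are absorbed by the polish row effects:
  # in noise-free data, scaling one probe's affinity leaves output unchanged
  spec0 <- simulation_spec(n_clusters = 10, probes_per_cluster = 3,
                           design = nine_pair_design(), mult_noise_sd = 0,
                           add_noise_sd = 0, background = 0, seed = 14)
  pm0 <- simulate_probe_data(spec0)$probes
  pm0b <- pm0
  for (s in probe_samples(pm0b)) {
    pm0b[[s]][1] <- 5 * pm0b[[s]][1]
  }
  e0a <- summarize_clusters(pm0, offset = 0, normalize = "none")
  e0b <- summarize_clusters(pm0b, offset = 0, normalize = "none")
  # affinity moves into the polish row effects; sample contrasts (the
  # expression differences the models consume) are unchanged
  ctr <- function(e) {
    m <- probescore:::expression_values(e)
    m - rowMeans(m)
  }
  expect_equal(ctr(e0a), ctr(e0b), tolerance = 1e-10)
})

test_that("a noise-free fold-2 spike summarizes to exactly one log2 unit", {
  spec <- simulation_spec(n_clusters = 50, probes_per_cluster = 4,
                          design = nine_pair_design(), n_de = 1,
                          effect_size = 2, mult_noise_sd = 0,
                          add_noise_sd = 0, background = 0, seed = 15)
  sim <- simulate_probe_data(spec)
  expr <- summarize_clusters(sim$probes, offset = 0, normalize = "none")
  de <- sim$truth$cluster_id
  d <- sim$design
  treated <- d$sample_id[d$treatment == "ethanol"]
  control <- d$sample_id[d$treatment == "control"]
  m <- probescore:::expression_values(expr)
  diff_de <- mean(m[de, treated]) - mean(m[de, control])
  expect_equal(diff_de, 1.0, tolerance = 1e-10)
})

test_that("two-factor fits equal the closed-form balanced ANOVA", {
  set.seed(16)
  d <- nine_pair_design()
  d <- design_table(d[d$sex == "M" | d$pair_id %in%
                        c("adol_F_1", "adol_F_2", "adol_F_3", "adol_F_4"), ])
  # build a balanced 2x2 (5 M pairs -> unbalanced; force balance with 4 + 4)
  d <- design_table(d[d$pair_id != "adol_M_5", ])
  n_cl <- 20
  vals <- matrix(rnorm(n_cl * nrow(d), sd = 0.4), n_cl) +
    outer(rep(1, n_cl), ifelse(d$treatment == "ethanol", 0.5, 0)) +
    outer(seq_len(n_cl) / 10, ifelse(d$sex == "F", 1, 0))
  expr <- dplyr::bind_cols(tibble::tibble(cluster_id = paste0("TC", 1:n_cl)),
                           tibble::as_tibble(`colnames<-`(vals, d$sample_id)))
  fit <- fit_two_factor(expr, d, moderate = FALSE)
  for (i in c(1, 7, 20)) {
    oracle <- closed_form_two_way(vals[i, ], d$treatment, d$sex)
    got <- fit[fit$cluster_id == paste0("TC", i), ]
    expect_equal(got$statistic[got$term == "treatment"],
                 unname(oracle$F["treatment"]), tolerance = 1e-10)
    expect_equal(got$statistic[got$term == "sex"],
                 unname(oracle$F["sex"]), tolerance = 1e-10)
    expect_equal(got$statistic[got$term == "interaction"],
                 unname(oracle$F["interaction"]), tolerance = 1e-10)
    expect_equal(got$p.value, unname(oracle$p[c("treatment", "sex",
                                                "interaction")]),
                 tolerance = 1e-10)
  }
})

test_that("constant responses give F = 0 and p = 1", {
  d <- nine_pair_design()
  expr <- dplyr::bind_cols(
    tibble::tibble(cluster_id = "TC1"),
    tibble::as_tibble(as.list(setNames(rep(3.14, nrow(d)), d$sample_id)))
  )
  fit <- fit_two_factor(expr, d, moderate = FALSE)
  expect_equal(fit$statistic, rep(0, 3))
  expect_equal(fit$p.value, rep(1, 3))
})

test_that("infinite prior df shrinks every residual variance to the pool", {
  set.seed(17)
  d <- nine_pair_design()
  vals <- matrix(rnorm(30 * nrow(d), sd = rep(seq(0.1, 2, length.out = 30),
                                              nrow(d))), 30)
  expr <- dplyr::bind_cols(tibble::tibble(cluster_id = paste0("TC", 1:30)),
                           tibble::as_tibble(`colnames<-`(vals, d$sample_id)))
  fit <- fit_two_factor(expr, d, moderate = TRUE, prior_df = Inf)
  v <- attr(fit, "variances")
  expect_equal(v$s2_post, rep(mean(v$s2_resid), 30))
})

test_that("an empty design cell is rejected by name", {
  d <- nine_pair_design()
  d$pair_id <- NA_character_
  d <- d[!(d$sex == "F" & d$treatment == "ethanol"), ]
  expr <- dplyr::bind_cols(
    tibble::tibble(cluster_id = "TC1"),
    tibble::as_tibble(as.list(setNames(rnorm(nrow(d)), d$sample_id)))
  )
  expect_error(fit_two_factor(expr, design_table(d)), "sex=F",
               class = "probescore_validation_error")
})

test_that("the p < alpha gate has the advertised type-I error on null data", {
  set.seed(18)
  d <- nine_pair_design()
  n_cl <- 2000
  vals <- matrix(rnorm(n_cl * nrow(d)), n_cl)
  expr <- dplyr::bind_cols(tibble::tibble(cluster_id = paste0("TC", 1:n_cl)),
                           tibble::as_tibble(`colnames<-`(vals, d$sample_id)))
  fit <- fit_two_factor(expr, d, moderate = FALSE)
  n_sig <- nrow(select_significant(fit, alpha = 0.01, term = "treatment"))
  # binomial(2000, 0.01): mean 20, sd ~4.45; allow 4 sd
  expect_lt(abs(n_sig - 20), 4 * sqrt(2000 * 0.01 * 0.99))
  expect_equal(nrow(select_significant(fit, alpha = 1, term = "sex")), n_cl)
})

test_that("spiked clusters are enriched among the selected", {
  sim <- simulate_probe_data(simulation_spec(
    n_clusters = 500, n_de = 25, effect_size = 2,
    design = nine_pair_design(), seed = 19
  ))
  expr <- summarize_clusters(sim$probes)
  fit <- fit_two_factor(expr, sim$design)
  sel <- select_significant(fit, 0.01, "treatment")
  k <- sum(sel$cluster_id %in% sim$truth$cluster_id)
  p_enrich <- phyper(k - 1, 25, 475, nrow(sel), lower.tail = FALSE)
  expect_lt(p_enrich, 1e-6)
})

test_that("list intersection echoes the two-track comparison structure", {
  expect_equal(intersect_lists(letters, letters)$counts$n_common, 26)
  expect_equal(intersect_lists(letters[1:5], letters[6:10])$counts$n_common, 0)

  shared <- paste0("shared", 1:300)
  a <- c(shared, paste0("a", 1:193))    # 493 ids
  b <- c(shared, paste0("b", 1:1512))   # 1812 ids
  out <- intersect_lists(a, b)
  expect_equal(out$counts$n_a, 493)
  expect_equal(out$counts$n_b, 1812)
  expect_equal(out$counts$n_common, 300)
  expect_setequal(out$common, shared)
})
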