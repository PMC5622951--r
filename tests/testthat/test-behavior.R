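test_that("discrimination index matches its definition and bounds", {
  expect_equal(discrimination_index(10, 10), 0)
  expect_equal(discrimination_index(15, 5), 0.5)
  expect_equal(discrimination_index(0, 10), -1)  # failure to recognize novelty
  expect_error(discrimination_index(0, 0), class = "probescore_validation_error")

  set.seed(1)
  tn <- runif(200, 0, 60)
  tf <- runif(200, 0.01, 60)
  di <- discrimination_index(tn, tf)
  expect_true(all(di >= -1 & di <= 1))
  expect_equal(di, -discrimination_index(tf, tn))  # antisymmetry
})

test_that("the 10-second training rule excludes boundary animals", {
  tab <- tibble::tibble(animal_id = paste0("A", 1:5),
                        training_time = c(10.0, 25, 9.9, 10.1, 30),
                        di = c(0.2, 0.4, -0.1, 0.3, 0.5))
  out <- apply_nor_exclusion(tab)
  expect_equal(out$animal_id, c("A2", "A4", "A5"))  # exactly 10 s is excluded
  expect_equal(exclusion_log(out)$animal_id, c("A1", "A3"))
  expect_equal(nrow(exclusion_log(out)), 2)

  all_good <- tibble::tibble(animal_id = "A1", training_time = 11)
  expect_equal(nrow(apply_nor_exclusion(all_good)), 1)
  expect_equal(nrow(exclusion_log(apply_nor_exclusion(all_good))), 0)
})

test_that("LORR duration and light-dark percentages are simple arithmetic", {
  expect_equal(lorr_duration(300, 2100), 1800)
  expect_equal(lorr_duration(300, 300), 0)
  expect_error(lorr_duration(300, 200), class = "probescore_validation_error")

  ld <- lightdark_metrics(30, 300, 100, 500)
  expect_equal(ld$pct_time_light, 10)
  expect_equal(ld$pct_distance_light, 20)
  expect_equal(lightdark_metrics(0, 300, 0, 500)$pct_time_light, 0)
  expect_equal(lightdark_metrics(300, 300, 500, 500)$pct_time_light, 100)
  expect_error(lightdark_metrics(301, 300, 1, 500),
               class = "probescore_validation_error")
})

test_that("two-way ANOVA matches the closed-form oracle to 1e-10", {
  tab <- simulate_behavior_cohort(cohort_groups(n = 8), seed = 23)
  res <- anova_factorial(tab, "value", c("treatment", "sex"))
  oracle <- closed_form_two_way(tab$value, tab$treatment, tab$sex)
  expect_equal(res$statistic[res$term == "treatment"],
               unname(oracle$F["treatment"]), tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "sex"],
               unname(oracle$F["sex"]), tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "treatment:sex"],
               unname(oracle$F["interaction"]), tolerance = 1e-10)
  expect_equal(attr(res, "mse"), oracle$mse, tolerance = 1e-10)

  # affine rescaling of the response leaves F unchanged
  tab2 <- dplyr::mutate(tab, value = 3.5 * value - 100)
  res2 <- anova_factorial(tab2, "value", c("treatment", "sex"))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
})

test_that("constant responses and aliased terms are handled explicitly", {
  tab <- simulate_behavior_cohort(cohort_groups(sd = 0, means = rep(5, 4)),
                                  seed = 1)
  res <- anova_factorial(tab, "value", c("treatment", "sex"))
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p.value, rep(1, 3))

  missing_cell <- dplyr::filter(
    simulate_behavior_cohort(cohort_groups(), seed = 2),
    !(sex == "F" & treatment == "ethanol")
  )
  expect_error(anova_factorial(missing_cell, "value", c("treatment", "sex")),
               "aliased", class = "probescore_validation_error")
})

test_that("a pure three-way interaction is detected as such", {
  g <- tidyr::expand_grid(sex = c("M", "F"), treatment = c("EtOH", "CON"),
                          challenge = c("saline", "ethanol"))
  sgn <- with(g, ifelse(sex == "M", 1, -1) * ifelse(treatment == "EtOH", 1, -1) *
                ifelse(challenge == "ethanol", 1, -1))
  g$n <- 40; g$mean <- 2 * sgn; g$sd <- 1
  tab <- simulate_behavior_cohort(g, seed = 29)
  res <- anova_factorial(tab, "value", c("sex", "treatment", "challenge"))
  expect_equal(nrow(res), 7)  # 3 mains + 3 two-way + 1 three-way
  p3 <- res$p.value[res$term == "sex:treatment:challenge"]
  expect_lt(p3, 1e-10)
  expect_true(all(res$p.value[res$term != "sex:treatment:challenge"] > 0.01))
})

test_that("SNK at two groups reduces to the pairwise t decision", {
  set.seed(31)
  tab <- tibble::tibble(grp = rep(c("a", "b"), each = 12),
                        y = rnorm(24) + rep(c(0, 1), each = 12))
  snk <- snk_posthoc(tab, "y", "grp", force = TRUE)
  tt <- stats::t.test(y ~ grp, tab, var.equal = TRUE)
  # q(alpha, 2, df) = sqrt(2) * t(alpha/2, df), so the decisions coincide
  expect_equal(qtukey(0.95, 2, 22), sqrt(2) * qt(0.975, 22), tolerance = 1e-6)
  expect_equal(snk$comparisons$significant, tt$p.value < 0.05)
})

test_that("studentized-range quantiles match published tables", {
  published <- tibble::tribble(
    ~r, ~df, ~q95,
    2, 5, 3.64,
    3, 10, 3.88,
    4, 20, 3.96,
    2, Inf, 2.77,
    3, Inf, 3.31,
    10, Inf, 4.47
  )
  got <- qtukey(0.95, published$r, published$df)
  expect_equal(got, published$q95, tolerance = 0.005)
})

test_that("SNK isolates a single displaced group and protects inner spans", {
  set.seed(37)
  tab <- tibble::tibble(
    grp = rep(c("a", "b", "c", "d"), each = 30),
    y = rnorm(120, sd = 1) + rep(c(0, 0, 0, 3), each = 30)
  )
  snk <- snk_posthoc(tab, "y", "grp")
  cmp <- snk$comparisons
  hit <- cmp$group_lo == "d" | cmp$group_hi == "d"
  expect_true(all(cmp$significant[hit]))
  expect_equal(sum(cmp$significant), 3)

  # protection: a non-significant span blocks all nested comparisons,
  # even one whose raw difference would exceed its own critical value
  means <- snk$means$group
  inner <- cmp[!hit, ]
  expect_true(all(!inner$significant[!inner$tested]))
  expect_error(snk_posthoc(tibble::tibble(grp = "a", y = 1), "y", "grp"),
               class = "probescore_validation_error")

  # omnibus gate
  set.seed(38)
  flat <- tibble::tibble(grp = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
  expect_error(snk_posthoc(flat, "y", "grp"), "omnibus",
               class = "probescore_validation_error")
  expect_s3_class(snk_posthoc(flat, "y", "grp", force = TRUE), "snk_result")
})

test_that("the protection rule blocks inner pairs inside a flat span", {
  # three tight groups + one far group: span(a..c) is non-significant, so
  # the a-b, b-c, a-c comparisons inside it must be declared ns untested
  # only when their enclosing span fails; construct a case where the 3-span
  # fails but an inner 2-span difference is numerically large relative to
  # its own critical value by using tiny within-group variance elsewhere.
  set.seed(41)
  tab <- tibble::tibble(
    grp = rep(c("a", "b", "c"), times = c(20, 20, 20)),
    y = rnorm(60, 0, 4)
  )
  # force exact group means (0, 0.5, 1); with sd ~4 the 3-span critical
  # difference is ~3, so the widest span cannot reach significance
  tab$y <- with(tab, ave(y, grp, FUN = function(v) v - mean(v)) +
                  c(a = 0, b = 0.5, c = 1)[grp])
  snk <- snk_posthoc(tab, "y", "grp", force = TRUE)
  cmp <- snk$comparisons
  expect_false(cmp$significant[cmp$span == 3])
  expect_true(all(!cmp$significant[cmp$span == 2]))
  expect_true(all(!cmp$tested[cmp$span == 2]))
})
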