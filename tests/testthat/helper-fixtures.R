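# Small fixtures built in code, shared across test files.

tiny_probe_matrix <- function() {
  probe_matrix(tibble::tibble(
    probe_id = paste0("P", 1:6),
    cluster_id = rep(c("TC1", "TC2"), each = 3),
    s1 = c(100, 120, 80, 400, 420, 380),
    s2 = c(110, 115, 90, 390, 430, 370),
    s3 = c(95, 125, 85, 410, 400, 395),
    s4 = c(105, 118, 78, 405, 415, 385)
  ))
}

# 5 male + 4 female treated/control pairs at one age
nine_pair_design <- function(age = "adolescent_PND43") {
  default_study_design(ages = age, pairs_per_sex = c(M = 5, F = 4))
}

# balanced 2x2 cohort with known cell means (deterministic when sd = 0)
cohort_groups <- function(n = 9, means = c(100, 100, 140, 100), sd = 15) {
  g <- tidyr::expand_grid(sex = c("M", "F"), treatment = c("ethanol", "control"))
  g$n <- n
  g$mean <- means
  g$sd <- sd
  g
}
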