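#' Novel-object-recognition discrimination index
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`, bounded in [-1, 1];
#' 0 means no discrimination, negative values indicate failure to recognize
#' the novel object.
#'
#' @param t_novel,t_familiar Interaction times (seconds), vectorized.
#' @return Discrimination index in [-1, 1].
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  total <- t_novel + t_familiar
  if (any(total <= 0)) {
    abort("undefined discrimination index: total interaction time must be > 0",
          class = "probescore_validation_error")
  }
  (t_novel - t_familiar) / total
}

#' Apply the minimum-training-investigation exclusion for NOR
#'
#' Animals are retained only if they investigated the objects for more than
#' `min_training_s` seconds during training; a training time exactly at the
#' boundary is excluded. Excluded ids are logged on the result.
#'
#' @param table A per-animal tibble.
#' @param min_training_s Retention threshold in seconds (default 10).
#' @param training_col Column holding training investigation time.
#' @return The filtered tibble; excluded rows are attached as attribute
#'   `"exclusion_log"` (see [exclusion_log()]).
#' @export
apply_nor_exclusion <- function(table, min_training_s = 10,
                                training_col = "training_time") {
  table <- tibble::as_tibble(table)
  if (!training_col %in% names(table)) {
    abort(paste0("missing training-time column '", training_col, "'"),
          class = "probescore_format_error")
  }
  keep <- table[[training_col]] > min_training_s
  out <- table[keep, ]
  attr(out, "exclusion_log") <- table[!keep, ]
  out
}

#' @rdname apply_nor_exclusion
#' @param x A table returned by [apply_nor_exclusion()].
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusion_log") %||% tibble::tibble()
}

#' Loss-of-righting-reflex duration
#'
#' Recovery time minus onset time, in seconds.
#'
#' @param onset_s,recovery_s Times in seconds, vectorized.
#' @return Durations in seconds.
#' @export
lorr_duration <- function(onset_s, recovery_s) {
  if (any(recovery_s < onset_s)) {
    abort("recovery before onset", class = "probescore_validation_error")
  }
  recovery_s - onset_s
}

#' Light-dark box percentage metrics
#'
#' Percent time spent in the light and percent distance traveled in the
#' light compartment.
#'
#' @param time_light,time_total Times (seconds).
#' @param dist_light,dist_total Distances (cm).
#' @return Tibble with `pct_time_light`, `pct_distance_light`.
#' @export
lightdark_metrics <- function(time_light, time_total, dist_light, dist_total) {
  if (any(time_total <= 0) || any(dist_total <= 0)) {
    abort("totals must be > 0", class = "probescore_validation_error")
  }
  if (any(time_light > time_total) || any(dist_light > dist_total)) {
    abort("part exceeds total", class = "probescore_validation_error")
  }
  tibble::tibble(pct_time_light = 100 * time_light / time_total,
                 pct_distance_light = 100 * dist_light / dist_total)
}

#' Factorial ANOVA with Type-III sums of squares
#'
#' Fully crossed two- or three-factor ANOVA with sum-to-zero contrasts and
#' Type-III sums of squares, reporting every main effect and interaction.
#'
#' @param data A per-animal tibble.
#' @param response Response column name.
#' @param factors Character vector of 2 or 3 factor column names.
#' @return An `anova_result` tibble: `term`, `sumsq`, `df`, `statistic` (F),
#'   `p.value`; the error mean square and df are attached as attributes
#'   `"mse"` and `"df_error"` for post hoc use.
#' @export
anova_factorial <- function(data, response, factors) {
  data <- tibble::as_tibble(data)
  if (!length(factors) %in% c(2, 3)) {
    abort("factors must name 2 or 3 columns")
  }
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "probescore_format_error")
  }
  df <- data[, c(response, factors)]
  for (f in factors) df[[f]] <- factor(df[[f]])
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- lm(fml, data = df, contrasts = contr)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("aliased term(s): ", paste(bad, collapse = ", ")),
          class = "probescore_validation_error")
  }
  df_error <- fit$df.residual
  if (var(df[[response]]) == 0) {
    terms <- attr(stats::terms(fml), "term.labels")
    out <- tibble::tibble(term = terms, sumsq = 0, df = NA_integer_,
                          statistic = 0, p.value = 1)
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
    out <- tibble::tibble(term = rownames(a)[keep],
                          sumsq = a[keep, "Sum Sq"],
                          df = a[keep, "Df"],
                          statistic = a[keep, "F value"],
                          p.value = a[keep, "Pr(>F)"])
  }
  class(out) <- c("anova_result", class(tibble::tibble()))
  attr(out, "mse") <- sum(fit$residuals^2) / df_error
  attr(out, "df_error") <- df_error
  attr(out, "fit") <- fit
  out
}

snk_mark_block <- function(comp, lo, hi, value) {
  idx <- comp$i >= lo & comp$j <= hi & !(comp$i == lo & comp$j == hi)
  comp$blocked[idx] <- comp$blocked[idx] | value
  comp
}

#' Student-Newman-Keuls stepwise post hoc comparisons
#'
#' Group means are ordered; a comparison spanning `r` ordered means uses the
#' studentized-range critical difference `q(alpha, r, df_error) *
#' sqrt(MSE / n_h)` with `n_h` the harmonic mean cell size. The stepwise
#' protection rule is applied: when a span is not significant, every
#' comparison nested inside it is declared non-significant without testing.
#' Quantiles come from the studentized-range distribution function
#' ([stats::qtukey()]), so any error df is supported.
#'
#' @param data A per-animal tibble.
#' @param response Response column name.
#' @param group Grouping column name (a factor or factor combination).
#' @param alpha Familywise level per step (default 0.05).
#' @param mse,df_error Error mean square and df from an omnibus model;
#'   computed from the one-way fit on `group` when `NULL`.
#' @param force Skip the significant-omnibus gate.
#' @return An `snk_result`: `means` tibble (ordered), `comparisons` tibble
#'   (`group_lo`, `group_hi`, `span`, `diff`, `critical`, `tested`,
#'   `significant`), plus `alpha`, `mse`, `df_error`.
#' @export
snk_posthoc <- function(data, response, group, alpha = 0.05, mse = NULL,
                        df_error = NULL, force = FALSE) {
  data <- tibble::as_tibble(data)
  g <- factor(data[[group]])
  y <- data[[response]]
  if (nlevels(g) < 2) {
    abort("need at least two groups", class = "probescore_validation_error")
  }
  fit <- lm(y ~ g)
  if (is.null(mse)) {
    mse <- sum(fit$residuals^2) / fit$df.residual
    df_error <- fit$df.residual
  }
  if (is.null(df_error)) abort("df_error must accompany mse")
  if (!force) {
    om <- stats::anova(fit)
    if (om[["Pr(>F)"]][1] > alpha) {
      abort(paste0("omnibus test not significant (p = ",
                   signif(om[["Pr(>F)"]][1], 3),
                   "); use force = TRUE to proceed"),
            class = "probescore_validation_error")
    }
  }
  means <- tibble::tibble(group = levels(g),
                          n = as.integer(table(g)),
                          mean = as.numeric(tapply(y, g, mean)))
  means <- dplyr::arrange(means, .data$mean)
  k <- nrow(means)
  n_h <- k / sum(1 / means$n)
  se <- sqrt(mse / n_h)
  comp <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(span = .data$j - .data$i + 1,
                  diff = means$mean[.data$j] - means$mean[.data$i],
                  critical = qtukey(1 - alpha, .data$span, df_error) * se,
                  blocked = FALSE)
  comp <- dplyr::arrange(comp, dplyr::desc(.data$span))
  comp$significant <- NA
  for (r in seq_len(nrow(comp))) {
    if (comp$blocked[r]) {
      comp$significant[r] <- FALSE
      next
    }
    sig <- abs(comp$diff[r]) >= comp$critical[r]
    comp$significant[r] <- sig
    if (!sig) comp <- snk_mark_block(comp, comp$i[r], comp$j[r], TRUE)
  }
  comparisons <- tibble::tibble(group_lo = means$group[comp$i],
                                group_hi = means$group[comp$j],
                                span = comp$span, diff = comp$diff,
                                critical = comp$critical,
                                tested = !comp$blocked,
                                significant = comp$significant)
  structure(list(means = means, comparisons = comparisons, alpha = alpha,
                 mse = mse, df_error = df_error, n_harmonic = n_h),
            class = "snk_result")
}

#' @export
print.snk_result <- function(x, ...) {
  cat("SNK post hoc (alpha =", x$alpha, ", df_error =", x$df_error, ")\n")
  print(x$means)
  print(x$comparisons)
  invisible(x)
}

#' Tidy SNK comparisons
#'
#' @param x An `snk_result`.
#' @param ... Unused.
#' @return The pairwise comparisons tibble.
#' @export
tidy.snk_result <- function(x, ...) x$comparisons
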