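#' Construct and validate a probe-level intensity table
#'
#' A probe matrix is a wide tibble with identifier columns `probe_id` and
#' `cluster_id` (the transcript cluster a probe interrogates) followed by one
#' numeric column per sample, holding linear-scale fluorescence intensities.
#' It is the unit consumed by the probe-level S-score and by cluster
#' summarization.
#'
#' Invariants enforced: every probe maps to exactly one cluster, probe and
#' sample identifiers are unique, and all intensities are finite and
#' non-negative. Probe order within a cluster is preserved as given.
#'
#' @param x A data frame with columns `probe_id`, `cluster_id` and one numeric
#'   column per sample.
#' @return A validated `probe_matrix` tibble.
#' @examples
#' pm <- probe_matrix(tibble::tibble(
#'   probe_id = c("P1", "P2", "P3"),
#'   cluster_id = c("TC1", "TC1", "TC2"),
#'   chipA = c(100, 200, 50), chipB = c(110, 190, 55)
#' ))
#' probe_samples(pm)
#' @export
probe_matrix <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("probe_id", "cluster_id")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("probe matrix is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "probescore_format_error")
  }
  samples <- setdiff(names(x), req)
  if (length(samples) == 0) {
    abort("probe matrix has no sample columns", class = "probescore_format_error")
  }
  if (anyDuplicated(samples)) {
    abort("sample IDs must be unique", class = "probescore_format_error")
  }
  if (anyDuplicated(x$probe_id)) {
    dup <- unique(x$probe_id[duplicated(x$probe_id)])
    abort(paste0("duplicate probe_id: ", paste(head(dup, 5), collapse = ", ")),
          class = "probescore_format_error")
  }
  if (any(is.na(x$cluster_id) | x$cluster_id == "")) {
    bad <- x$probe_id[is.na(x$cluster_id) | x$cluster_id == ""]
    abort(paste0("probe(s) without cluster mapping: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "probescore_format_error")
  }
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(paste0("sample column '", s, "' is not numeric"),
            class = "probescore_format_error")
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(paste0("negative or non-finite intensity at probe '",
                   x$probe_id[bad[1]], "', sample '", s, "'"),
            class = "probescore_validation_error")
    }
  }
  x <- x[, c(req, samples)]
  class(x) <- c("probe_matrix", class(tibble::tibble()))
  x
}

#' @rdname probe_matrix
#' @param pm A `probe_matrix`.
#' @export
probe_samples <- function(pm) {
  setdiff(names(pm), c("probe_id", "cluster_id"))
}

#' Extract the intensity block of a probe matrix as a numeric matrix
#'
#' @param pm A `probe_matrix`.
#' @return Numeric matrix, rows named by `probe_id`, columns by sample.
#' @keywords internal
#' @export
probe_intensity_matrix <- function(pm) {
  m <- as.matrix(as.data.frame(pm[probe_samples(pm)]))
  rownames(m) <- pm$probe_id
  m
}

#' Read a probe intensity matrix and its probe-to-cluster map
#'
#' The matrix file is tab-separated with a header `probe_id<TAB>sample...`;
#' the map file is tab-separated with columns `probe_id` and `cluster_id`.
#' Intensities are linear-scale; any log transform is internal to consumers.
#'
#' @param path Path to the intensity TSV.
#' @param map_path Path to the probe-to-cluster map TSV.
#' @return A validated [probe_matrix()].
#' @export
read_probe_matrix <- function(path, map_path) {
  mat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"probe_id" %in% names(mat)) {
    abort("intensity file must have a 'probe_id' column",
          class = "probescore_format_error")
  }
  for (s in setdiff(names(mat), "probe_id")) {
    # base strtod parsing: bit-exact round trip of %.17g output
    mat[[s]] <- as.numeric(mat[[s]])
  }
  map <- readr::read_tsv(map_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("probe_id", "cluster_id") %in% names(map))) {
    abort("map file must have columns probe_id, cluster_id",
          class = "probescore_format_error")
  }
  if (anyDuplicated(map$probe_id)) {
    abort("map file assigns a probe to more than one cluster",
          class = "probescore_format_error")
  }
  unmapped <- setdiff(mat$probe_id, map$probe_id)
  if (length(unmapped) > 0) {
    abort(paste0("probe(s) without cluster mapping: ",
                 paste(head(unmapped, 5), collapse = ", ")),
          class = "probescore_format_error")
  }
  out <- dplyr::left_join(mat, map[c("probe_id", "cluster_id")], by = "probe_id")
  probe_matrix(out[, c("probe_id", "cluster_id", setdiff(names(mat), "probe_id"))])
}

#' Write a probe matrix to an intensity TSV and a map TSV
#'
#' Round-trips bit-exactly through [read_probe_matrix()]: UTF-8, "." decimal
#' point, full-precision numbers.
#'
#' @param pm A `probe_matrix`.
#' @inheritParams read_probe_matrix
#' @return `pm`, invisibly.
#' @export
write_probe_matrix <- function(pm, path, map_path) {
  pm <- probe_matrix(pm)
  out <- pm[c("probe_id", probe_samples(pm))]
  # 17 significant digits guarantee a bit-exact double round trip
  for (s in probe_samples(pm)) out[[s]] <- sprintf("%.17g", out[[s]])
  readr::write_tsv(out, path)
  readr::write_tsv(pm[c("probe_id", "cluster_id")], map_path)
  invisible(pm)
}

age_levels <- c("adolescent_PND43", "adult_PND66")
sex_levels <- c("M", "F")
treatment_levels <- c("ethanol", "control")

#' Construct and validate a sample design table
#'
#' One row per array/sample: `sample_id`, `age_group`
#' (`adolescent_PND43`/`adult_PND66`), `sex` (`M`/`F`), `treatment`
#' (`ethanol`/`control`) and an optional `pair_id` linking exactly one
#' ethanol-treated sample to one control sample of the same sex and age, the
#' unit over which pairwise S-scores are formed.
#'
#' @param x A data frame with the columns above (`pair_id` optional).
#' @return A validated `design_table` tibble (with a `pair_id` column, `NA`
#'   where unpaired).
#' @export
design_table <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("sample_id", "age_group", "sex", "treatment")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "probescore_format_error")
  }
  if (!"pair_id" %in% names(x)) x$pair_id <- NA_character_
  x$pair_id <- as.character(x$pair_id)
  x$pair_id[!is.na(x$pair_id) & x$pair_id == ""] <- NA_character_
  if (anyDuplicated(x$sample_id)) {
    abort("duplicate sample_id in design", class = "probescore_validation_error")
  }
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(x[[col]]), levels)
    if (length(bad) > 0) {
      abort(paste0("unknown ", col, " level(s): ", paste(bad, collapse = ", "),
                   " (allowed: ", paste(levels, collapse = ", "), ")"),
            class = "probescore_validation_error")
    }
  }
  check_levels("age_group", age_levels)
  check_levels("sex", sex_levels)
  check_levels("treatment", treatment_levels)
  paired <- x[!is.na(x$pair_id), ]
  if (nrow(paired) > 0) {
    for (pid in unique(paired$pair_id)) {
      p <- paired[paired$pair_id == pid, ]
      if (nrow(p) != 2 ||
          !identical(sort(p$treatment), c("control", "ethanol")) ||
          length(unique(p$sex)) != 1 ||
          length(unique(p$age_group)) != 1) {
        abort(paste0("pair_id '", pid, "' must link exactly one ethanol-treated ",
                     "and one control sample of the same sex and age"),
              class = "probescore_validation_error")
      }
    }
  }
  x <- x[, c(req, "pair_id")]
  class(x) <- c("design_table", class(tibble::tibble()))
  x
}

#' Read or write a design table CSV
#'
#' CSV with header `sample_id,age_group,sex,treatment,pair_id`.
#'
#' @param path Path to the CSV file.
#' @return A validated [design_table()].
#' @export
read_design <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  design_table(x)
}

#' @rdname read_design
#' @param design A `design_table`.
#' @export
write_design <- function(design, path) {
  design <- design_table(design)
  readr::write_csv(design, path, na = "")
  invisible(design)
}

#' Pairs defined in a design table
#'
#' @param design A `design_table`.
#' @param age Optional age group to restrict to.
#' @return A tibble with one row per pair: `pair_id`, `age_group`, `sex`,
#'   `treated_id`, `control_id`.
#' @export
design_pairs <- function(design, age = NULL) {
  design <- design_table(design)
  d <- design[!is.na(design$pair_id), ]
  if (!is.null(age)) d <- d[d$age_group %in% age, ]
  if (nrow(d) == 0) {
    return(tibble::tibble(pair_id = character(), age_group = character(),
                          sex = character(), treated_id = character(),
                          control_id = character()))
  }
  d |>
    dplyr::group_by(.data$pair_id, .data$age_group, .data$sex) |>
    dplyr::summarise(
      treated_id = .data$sample_id[.data$treatment == "ethanol"],
      control_id = .data$sample_id[.data$treatment == "control"],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$pair_id)
}

#' Construct and validate a gene-set collection
#'
#' A carrier for gene-set memberships (for example Gene Ontology categories)
#' used in over-representation testing: one row per set with a unique
#' `set_id`, a free-text `set_name`, and a list-column `members` of
#' cluster/gene identifiers (deduplicated, non-empty).
#'
#' @param x A data frame with columns `set_id`, `set_name`, `members`
#'   (list of character vectors).
#' @return A validated `gene_set_collection` tibble.
#' @export
gene_set_collection <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("set_id", "set_name", "members")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene set collection missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "probescore_format_error")
  }
  if (anyDuplicated(x$set_id)) {
    abort("set_id must be unique", class = "probescore_validation_error")
  }
  x$members <- lapply(x$members, function(m) unique(as.character(m)))
  if (any(lengths(x$members) == 0)) {
    abort("gene sets must have at least one member",
          class = "probescore_validation_error")
  }
  x <- x[, req]
  class(x) <- c("gene_set_collection", class(tibble::tibble()))
  x
}

#' Read or write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed on read.
#'
#' @param path Path to the GMT file.
#' @return A validated [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(paste0("GMT line ", short[1], " has fewer than 3 fields"),
          class = "probescore_format_error")
  }
  gene_set_collection(tibble::tibble(
    set_id = vapply(fields, `[[`, "", 1),
    set_name = vapply(fields, `[[`, "", 2),
    members = lapply(fields, function(f) f[-(1:2)])
  ))
}

#' @rdname read_gmt
#' @param sets A `gene_set_collection`.
#' @export
write_gmt <- function(sets, path) {
  sets <- gene_set_collection(sets)
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$set_name[i], sets$members[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(sets)
}
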