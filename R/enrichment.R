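#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (thin wrapper over
#' `p.adjust(method = "BH")` with input validation; order-invariant).
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]", class = "probescore_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided over-representation of a query list within each gene set,
#' against a stated universe (by convention all clusters on the array).
#' Sets are intersected with the universe before testing; with `k` query
#' hits in a set of size `K`, query size `n` and universe size `N`, the
#' p-value is the upper hypergeometric tail `P[X >= k]`. Benjamini-Hochberg
#' adjustment is applied across all tested sets.
#'
#' @param query Character vector of significant cluster/gene ids
#'   (must be a subset of `universe`).
#' @param sets A [gene_set_collection()].
#' @param universe Character vector of all testable ids.
#' @return An `enrichment_result` tibble: `set_id`, `set_name`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, sorted by `p`.
#' @export
overrepresentation <- function(query, sets, universe) {
  sets <- gene_set_collection(sets)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    abort(paste0("query ids not in universe: ",
                 paste(head(stray, 10), collapse = ", ")),
          class = "probescore_validation_error")
  }
  n <- length(query)
  big_n <- length(universe)
  members <- lapply(sets$members, intersect, universe)
  big_k <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), integer(1))
  p <- phyper(k - 1, big_k, big_n - big_k, n, lower.tail = FALSE)
  out <- tibble::tibble(set_id = sets$set_id, set_name = sets$set_name,
                        k = k, K = big_k, n = n, N = big_n,
                        p = p, q = bh_adjust(p))
  out <- dplyr::arrange(out, .data$p, .data$set_id)
  class(out) <- c("enrichment_result", class(tibble::tibble()))
  out
}
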