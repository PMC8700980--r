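# Hypergeometric gene-set over-representation with BH correction. This is the
# pipeline's single deliberate methodological replacement: external annotation
# web services are swapped for the standard upper-tail hypergeometric test
# against user-supplied gene sets.

#' Hypergeometric over-representation test
#'
#' For each term: with universe size N, term size K (after intersection with
#' the universe), query size n and overlap k, the p-value is the upper tail
#' `P(X >= k)` of Hypergeometric(N, K, n). BH correction across terms; results
#' sorted by p.
#'
#' @param query character vector of genes (non-empty, subset of universe).
#' @param universe character vector of background genes.
#' @param collection named list of gene sets (GMT-style).
#' @return data.frame: term, k, K, n, N, pvalue, fdr.
#' @export
hypergeom_enrich <- function(query, universe, collection) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) rc_stop("hypergeom_enrich: empty query")
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    rc_stop("hypergeom_enrich: query gene(s) outside the universe: %s",
            paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(unique(collection[[term]]), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$pvalue)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  rc_log("hypergeom_enrich: %d terms, query %d of %d genes", nrow(out), n, N)
  out
}
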