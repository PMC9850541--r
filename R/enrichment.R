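# Hypergeometric over-representation of a query gene list against a GMT
# collection, with Benjamini-Hochberg correction and fold enrichment.

#' Hypergeometric gene-set over-representation analysis
#'
#' For each term: with `N` background genes, `K` of which belong to the
#' term, and a query of `n` background genes overlapping the term in `k`,
#' the p-value is the upper-tail hypergeometric probability `P(X >= k)`.
#' Fold enrichment is `(k/n) / (K/N)`. The query is intersected with the
#' background before testing; p-values are BH-adjusted across all terms in
#' the collection.
#'
#' @param query character vector of gene ids (e.g. significant DE genes)
#' @param collection a `GeneSetCollection`
#' @param background character vector of all tested genes (typically every
#'   gene surviving preprocessing)
#' @return `EnrichmentTable` data.frame: term, k, K, n, N, fold_enrichment,
#'   p, p_adj, sorted by fold enrichment (decreasing)
#' @export
hypergeom_enrich <- function(query, collection, background) {
  background <- unique(toupper(background))
  query <- intersect(unique(toupper(query)), background)
  if (!length(query))
    stop("query is empty after intersection with the background")
  n <- length(query); N <- length(background)
  rows <- lapply(collection, function(s) {
    term_genes <- intersect(toupper(s$genes), background)
    K <- length(term_genes)
    k <- length(intersect(query, term_genes))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K > 0 && n > 0) (k / n) / (K / N) else 0
    data.frame(term = s$name, k = k, K = K, n = n, N = N,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- adjust_pvalues(out$p, method = "bh")
  out <- out[order(-out$fold_enrichment, out$p), , drop = FALSE]
  class(out) <- c("EnrichmentTable", class(out))
  out
}
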