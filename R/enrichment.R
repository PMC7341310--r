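# Over-representation analysis of a gene list against gene sets by the
# upper-tail hypergeometric test (equivalently one-sided Fisher's exact),
# BH-adjusted across sets. Runs entirely locally against user-supplied GMT
# sets; any cross-species ortholog mapping is the caller's responsibility.

#' Gene-set over-representation test
#'
#' For each set, with universe size `N`, set size `K`, query size `n` and
#' overlap `k`, the p-value is the hypergeometric upper tail
#' `P(X >= k)`. Query genes outside the universe are dropped (with a
#' message), as are set members outside the universe; sets smaller than
#' `min_set_size` after filtering are skipped.
#'
#' @param query Character vector of gene ids of interest.
#' @param gene_sets Tibble from [read_gmt()] (`set_id`, list-column
#'   `genes`) or a named list of character vectors.
#' @param universe Character vector of all testable gene ids.
#' @param min_set_size Minimum effective set size to test.
#' @return A tibble sorted by `padj`: `set_id`, `k`, `n`, `K`, `N`, `p`,
#'   `padj`.
#' @export
enrich_sets <- function(query, gene_sets, universe, min_set_size = 3) {
  if (length(universe) == 0L) abort("universe is empty.")
  if (length(query) == 0L) abort("query gene list is empty.")
  universe <- unique(universe)
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble(set_id = names(gene_sets), genes = unname(gene_sets))
  }
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    rlang::inform(sprintf("dropping %d query gene(s) not in the universe.", length(dropped)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) abort("no query gene is in the universe.")
  members <- map(gene_sets$genes, intersect, universe)
  n_dropped_members <- sum(lengths(gene_sets$genes)) - sum(lengths(members))
  if (n_dropped_members > 0) {
    rlang::inform(sprintf("dropped %d set member(s) not in the universe.", n_dropped_members))
  }
  K <- lengths(members)
  keep <- K >= min_set_size
  if (!any(keep)) abort("no gene set passes min_set_size after universe filtering.")
  members <- members[keep]
  N <- length(universe); n <- length(query)
  k <- map_int(members, function(g) length(intersect(g, query)))
  K <- K[keep]
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(set_id = gene_sets$set_id[keep], k = k, n = n, K = K, N = N,
         p = p, padj = bh_adjust(p)) |>
    arrange(.data$padj, .data$p, .data$set_id)
}
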