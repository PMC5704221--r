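#' Hypergeometric over-representation analysis against a gene-set library
#'
#' Local, deterministic replacement for web-based enrichment services: for
#' each library set the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `n = |query|` genes are sampled without
#' replacement from a universe of `N` genes containing `K` set members,
#' followed by Benjamini-Hochberg adjustment across the library.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param library Named list of gene sets (e.g. from [read_gmt()]); each set
#'   is intersected with the universe before testing.
#' @param universe Character vector of background genes.
#' @return Data frame `set_name`, `overlap` (k), `set_size` (K),
#'   `query_size` (n), `universe_size` (N), `pvalue`, `bh_adjusted`, sorted
#'   by p-value then set name.
#' @export
hypergeom_enrich <- function(query, library, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop(sprintf("query genes outside the universe: %s",
                 paste(utils::head(sort_c(outside), 5), collapse = ", ")),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  K <- vapply(library, function(s) length(intersect(unique(s), universe)), integer(1))
  k <- vapply(library, function(s) length(intersect(unique(s), query)), integer(1))
  pv <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pv <- pmin(pv, 1)
  out <- data.frame(set_name = names(library), overlap = k, set_size = K,
                    query_size = n, universe_size = N, pvalue = pv,
                    bh_adjusted = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$set_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
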