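#' Rank regulators by number of distinct target genes
#'
#' The hub-regulator score used alongside PageRank: a TF's score is the
#' number of distinct genes it regulates (its out-degree in the GRN).
#'
#' @param x A [grn()] object.
#' @param k Maximum number of regulators to return (default 20).
#' @return Data frame `tf_name`, `score`, ordered by decreasing score with
#'   ties broken lexicographically by TF name; attributes `method` and `k`.
#' @export
rank_regulators_by_outdegree <- function(x, k = 20) {
  stopifnot(inherits(x, "grn"))
  tfs <- x$nodes$name[x$nodes$is_tf]
  deg <- vapply(tfs, function(t) length(unique(x$edges$gene[x$edges$tf == t])),
                integer(1))
  ranking(data.frame(tf_name = tfs, score = as.numeric(deg),
                     stringsAsFactors = FALSE), "outdegree", k)
}

ranking <- function(df, method, k) {
  ord <- order(-df$score, df$tf_name, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  attr(df, "method") <- method
  attr(df, "k") <- k
  class(df) <- c("regulator_ranking", "data.frame")
  df
}

#' PageRank scores of GRN nodes
#'
#' Power iteration with damping, uniform teleport and uniform redistribution
#' of dangling-node mass.  By default the edges are reversed (gene -> TF) so
#' that rank mass flows from regulated genes to their regulators and the
#' ranking highlights hub TFs rather than heavily-regulated genes; set
#' `reverse = FALSE` for standard orientation.
#'
#' @param x A non-empty [grn()] object.
#' @param damping Damping factor d (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Maximum iterations (default 200).
#' @param reverse Run on the reversed edge set (default `TRUE`).
#' @return Named numeric vector of scores summing to 1, one per node, with
#'   attributes `converged` (logical), `iterations` and `residual`.  A
#'   warning is raised if `max_iter` is reached before `tol`.
#' @export
pagerank_scores <- function(x, damping = 0.85, tol = 1e-10, max_iter = 200,
                            reverse = TRUE) {
  stopifnot(inherits(x, "grn"))
  n <- nrow(x$nodes)
  if (n == 0) stop("PageRank of an empty network is undefined", call. = FALSE)
  nm <- x$nodes$name
  src <- match(if (reverse) x$edges$gene else x$edges$tf, nm)
  dst <- match(if (reverse) x$edges$tf else x$edges$gene, nm)
  outdeg <- tabulate(src, nbins = n)
  dangling <- outdeg == 0
  M <- Matrix::sparseMatrix(i = dst, j = src,
                            x = 1 / outdeg[src], dims = c(n, n))
  pi_v <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new <- (1 - damping) / n +
      damping * (as.numeric(M %*% pi_v) + sum(pi_v[dangling]) / n)
    resid <- sum(abs(new - pi_v))
    pi_v <- new
    if (resid < tol || iter >= max_iter) break
  }
  converged <- resid < tol
  if (!converged) {
    warning(sprintf("PageRank did not converge in %d iterations (L1 residual %.3g)",
                    max_iter, resid))
  }
  structure(stats::setNames(pi_v, nm), converged = converged,
            iterations = iter, residual = resid)
}

#' Rank regulators by PageRank
#'
#' @inheritParams pagerank_scores
#' @param k Maximum number of regulators to return (default 20).
#' @return Data frame `tf_name`, `score` restricted to TF-role nodes,
#'   ordered by decreasing score, ties broken lexicographically; attributes
#'   `method` and `k`.
#' @export
rank_regulators_by_pagerank <- function(x, k = 20, damping = 0.85, tol = 1e-10,
                                        max_iter = 200, reverse = TRUE) {
  scores <- pagerank_scores(x, damping, tol, max_iter, reverse)
  tfs <- x$nodes$name[x$nodes$is_tf]
  ranking(data.frame(tf_name = tfs, score = as.numeric(scores[tfs]),
                     stringsAsFactors = FALSE), "pagerank", k)
}

#' @export
print.regulator_ranking <- function(x, ...) {
  cat(sprintf("Top %d regulators by %s:\n", nrow(x), attr(x, "method")))
  print.data.frame(x, ...)
  invisible(x)
}

grn_element_set <- function(x, element) {
  switch(element,
         genes = x$nodes$name[x$nodes$is_gene],
         tfs = x$nodes$name[x$nodes$is_tf],
         receptors = x$nodes$name[x$nodes$is_receptor])
}

#' Multi-network set intersections (UpSet-style membership table)
#'
#' For a named collection of GRNs, tabulates every non-empty presence
#' pattern of the chosen element type across the networks, together with
#' per-network "unique" counts (elements present in exactly one network).
#'
#' @param grns Named list of [grn()] objects (>= 2).
#' @param element Which node sets to intersect: `"genes"` (regulated genes),
#'   `"tfs"` or `"receptors"`.
#' @return An object of class `"network_intersection"`: list with
#'   `membership` (logical element x network matrix), `table` (data frame
#'   `signature` — `&`-joined network names —, `degree`, `count`,
#'   `members`), and `unique` (named integer vector per network).
#' @export
intersect_networks <- function(grns, element = c("genes", "tfs", "receptors")) {
  element <- match.arg(element)
  stopifnot(length(grns) >= 2, !is.null(names(grns)), all(nzchar(names(grns))))
  sets <- lapply(grns, grn_element_set, element = element)
  all_el <- sort_c(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_el %in% s,
                       logical(length(all_el)))
  if (length(all_el) == 1) membership <- matrix(membership, nrow = 1,
                                                dimnames = list(all_el, names(sets)))
  else rownames(membership) <- all_el
  sig <- apply(membership, 1, function(r) paste(colnames(membership)[r], collapse = "&"))
  sp <- split(all_el, sig)
  tab <- data.frame(signature = names(sp),
                    degree = lengths(strsplit(names(sp), "&", fixed = TRUE)),
                    count = lengths(sp),
                    members = vapply(sp, function(g) paste(sort_c(g), collapse = ","),
                                     character(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$signature, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  uniq <- vapply(names(sets), function(nm) {
    sum(membership[, nm] & rowSums(membership) == 1)
  }, integer(1))
  structure(list(membership = membership, table = tab, unique = uniq,
                 element = element),
            class = "network_intersection")
}

#' @export
print.network_intersection <- function(x, ...) {
  cat(sprintf("Intersection of %d networks over %s (%d elements)\n",
              ncol(x$membership), x$element, nrow(x$membership)))
  print.data.frame(x$table[, c("signature", "degree", "count")], ...)
  invisible(x)
}

#' Receptor regulatory subnetwork of a GRN
#'
#' The induced subnetwork containing every receptor-flagged node that
#' receives at least one edge, all its incoming edges, and their source
#' TFs — nothing else.  Idempotent.
#'
#' @param x A [grn()] object.
#' @return A [grn()] object (empty when no receptor is regulated).
#' @export
receptor_subnetwork <- function(x) {
  stopifnot(inherits(x, "grn"))
  receptors <- grn_receptor_names(x)
  keep <- x$edges$gene %in% receptors
  grn(x$edges[keep, , drop = FALSE], receptors)
}

#' Differential network between two GRNs
#'
#' Exact set differences between two conditions' networks.  Edge identity is
#' the `(TF, gene)` pair; evidence is ignored.  A receptor counts as "lost"
#' when it is regulated (receives >= 1 edge) in `a` but is not a regulated
#' node in `b`; its number of distinct regulators in `a` is reported.
#'
#' @param a,b [grn()] objects (condition A and condition B).
#' @return An object of class `"grn_diff"`: list with `edges_lost`,
#'   `edges_gained` (data frames `tf`, `gene`), `nodes_lost`,
#'   `nodes_gained` (character), `receptors_lost` (data frame `receptor`,
#'   `n_regulators_a`).
#' @export
diff_network <- function(a, b) {
  stopifnot(inherits(a, "grn"), inherits(b, "grn"))
  ka <- edge_keys(a); kb <- edge_keys(b)
  edges_lost <- a$edges[!(ka %in% kb), c("tf", "gene"), drop = FALSE]
  edges_gained <- b$edges[!(kb %in% ka), c("tf", "gene"), drop = FALSE]
  rownames(edges_lost) <- rownames(edges_gained) <- NULL
  rec_a <- a$nodes$name[a$nodes$is_receptor & a$nodes$is_gene]
  lost <- rec_a[!(rec_a %in% b$edges$gene)]
  receptors_lost <- data.frame(
    receptor = lost,
    n_regulators_a = vapply(lost, function(r) {
      length(unique(a$edges$tf[a$edges$gene == r]))
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(receptors_lost) <- NULL
  structure(list(edges_lost = edges_lost, edges_gained = edges_gained,
                 nodes_lost = setdiff(a$nodes$name, b$nodes$name),
                 nodes_gained = setdiff(b$nodes$name, a$nodes$name),
                 receptors_lost = receptors_lost),
            class = "grn_diff")
}

#' @export
print.grn_diff <- function(x, ...) {
  cat(sprintf("GRN diff: %d edges lost, %d gained; %d nodes lost, %d gained; %d receptors lost\n",
              nrow(x$edges_lost), nrow(x$edges_gained),
              length(x$nodes_lost), length(x$nodes_gained),
              nrow(x$receptors_lost)))
  if (nrow(x$receptors_lost) > 0) print.data.frame(x$receptors_lost)
  invisible(x)
}

#' Differential receptor regulatory network
#'
#' The receptor subnetwork of condition A restricted to edges absent from
#' condition B: the receptor wiring that condition B has lost.
#'
#' @param a,b [grn()] objects.
#' @return A [grn()] object.
#' @export
diff_receptor_network <- function(a, b) {
  rs <- receptor_subnetwork(a)
  keep <- !(edge_keys(rs) %in% edge_keys(b))
  grn(rs$edges[keep, , drop = FALSE], grn_receptor_names(rs))
}
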