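#' Construct a gene regulatory network object
#'
#' A GRN is a directed TF -> gene graph.  Edges carry their binding evidence
#' (which peaks and motif occurrences support them); nodes carry roles: a
#' node is a TF if it sources at least one edge, a (regulated) gene if it
#' receives at least one edge, and is flagged as a receptor when its name is
#' on the supplied receptor list.  One name may hold several roles.
#'
#' @param edges Data frame with columns `tf`, `gene`, `n_peaks` (integer,
#'   distinct supporting peaks), `best_pvalue` (numeric, minimum motif-hit
#'   p-value), `evidence` (character; semicolon-joined
#'   `"peak_id|motif_id|strand|offset|pvalue"` entries).  Zero rows give an
#'   empty network.
#' @param receptors Character vector of receptor symbols; only names present
#'   in the network are flagged.
#' @param isolated Optional names of nodes that carry no edge (kept in the
#'   node table with no TF/gene role).
#' @return An object of class `"grn"`: list with `nodes` (data frame `name`,
#'   `is_tf`, `is_gene`, `is_receptor`) and `edges` (sorted by `(tf, gene)`).
#' @export
grn <- function(edges = NULL, receptors = character(), isolated = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(tf = character(), gene = character(),
                        n_peaks = integer(), best_pvalue = numeric(),
                        evidence = character(), stringsAsFactors = FALSE)
  }
  req <- c("tf", "gene", "n_peaks", "best_pvalue", "evidence")
  if (!all(req %in% names(edges))) {
    stop(sprintf("edges must have columns: %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  edges <- edges[, req, drop = FALSE]
  if (anyDuplicated(paste(edges$tf, edges$gene, sep = "\r"))) {
    stop("duplicate (tf, gene) edges", call. = FALSE)
  }
  if (nrow(edges) > 0 && !all(nzchar(edges$evidence))) {
    stop("every edge needs non-empty evidence", call. = FALSE)
  }
  edges <- edges[order(edges$tf, edges$gene, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  nm <- sort_c(unique(c(edges$tf, edges$gene, isolated)))
  nodes <- data.frame(name = nm,
                      is_tf = nm %in% edges$tf,
                      is_gene = nm %in% edges$gene,
                      is_receptor = nm %in% receptors,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("GRN: %d nodes (%d TFs, %d regulated genes, %d receptors), %d edges\n",
              s$n_nodes, s$n_tfs, s$n_genes, s$n_receptors, s$n_edges))
  invisible(x)
}

#' Summarise a GRN by node role and edge count
#'
#' @param x A [grn()] object.
#' @return A one-row data frame: `n_nodes`, `n_tfs`, `n_genes` (regulated
#'   genes), `n_receptors`, `n_edges` (distinct TF-gene pairs),
#'   `n_evidence` (TF-peak-gene support triples, the alternative reading of
#'   "regulatory pairs"), `n_self_edges` (TFs regulating their own gene).
#' @export
network_summary <- function(x) {
  stopifnot(inherits(x, "grn"))
  n_ev <- if (nrow(x$edges) == 0) 0L else {
    ev <- strsplit(x$edges$evidence, ";", fixed = TRUE)
    sum(vapply(seq_along(ev), function(i) {
      length(unique(vapply(strsplit(ev[[i]], "|", fixed = TRUE), `[`, character(1), 1)))
    }, integer(1)))
  }
  data.frame(n_nodes = nrow(x$nodes),
             n_tfs = sum(x$nodes$is_tf),
             n_genes = sum(x$nodes$is_gene),
             n_receptors = sum(x$nodes$is_receptor),
             n_edges = nrow(x$edges),
             n_evidence = n_ev,
             n_self_edges = sum(x$edges$tf == x$edges$gene))
}

#' Edge identity keys of a GRN
#' @param x A [grn()] object.
#' @return Character vector `"tf\tgene"` per edge (evidence is not part of
#'   edge identity).
#' @keywords internal
edge_keys <- function(x) paste(x$edges$tf, x$edges$gene, sep = "\t")

grn_receptor_names <- function(x) x$nodes$name[x$nodes$is_receptor]

#' Write a GRN to a TSV edge list
#'
#' Columns: `TF`, `gene`, `n_peaks`, `best_pvalue`, `evidence` (semicolon
#' joined `peak_id|motif_id|strand|offset|pvalue`), sorted lexicographically
#' by (TF, gene) for byte-stable output.  Receptor flags are preserved in a
#' `# receptors:` header line.  [read_network()] inverts this exactly.
#'
#' @param x A [grn()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path) {
  stopifnot(inherits(x, "grn"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# receptors: %s", paste(grn_receptor_names(x), collapse = ",")), con)
  iso <- x$nodes$name[!x$nodes$is_tf & !x$nodes$is_gene]
  if (length(iso) > 0) {
    writeLines(sprintf("# isolated: %s", paste(iso, collapse = ",")), con)
  }
  writeLines("TF\tgene\tn_peaks\tbest_pvalue\tevidence", con)
  if (nrow(x$edges) > 0) {
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s",
                       x$edges$tf, x$edges$gene, x$edges$n_peaks,
                       fmt_num(x$edges$best_pvalue), x$edges$evidence), con)
  }
  invisible(path)
}

#' Read a GRN from a TSV edge list written by [write_network()]
#'
#' @param path Path to the network TSV.
#' @return A [grn()] object identical (nodes, edges, evidence) to the one
#'   written.
#' @export
read_network <- function(path) {
  lines <- read_nonempty_lines(path)
  parse_comment <- function(tag) {
    at <- grep(paste0("^# ", tag, ":"), lines)
    if (length(at) == 0) return(character())
    val <- trimws(sub(paste0("^# ", tag, ":"), "", lines[at[1]]))
    if (!nzchar(val)) return(character())
    strsplit(val, ",", fixed = TRUE)[[1]]
  }
  receptors <- parse_comment("receptors")
  isolated <- parse_comment("isolated")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0 || body[1] != "TF\tgene\tn_peaks\tbest_pvalue\tevidence") {
    stop(sprintf("%s: missing network header line", path), call. = FALSE)
  }
  body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(grn(NULL, receptors, isolated))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) != 5)
  if (length(bad) > 0) stop(sprintf("%s: malformed edge line %d", path, bad[1]), call. = FALSE)
  edges <- data.frame(tf = vapply(f, `[`, character(1), 1),
                      gene = vapply(f, `[`, character(1), 2),
                      n_peaks = as.integer(vapply(f, `[`, character(1), 3)),
                      best_pvalue = as.numeric(vapply(f, `[`, character(1), 4)),
                      evidence = vapply(f, `[`, character(1), 5),
                      stringsAsFactors = FALSE)
  grn(edges, receptors, isolated)
}
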