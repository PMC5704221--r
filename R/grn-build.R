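#' Build a gene regulatory network from assignments and motif hits
#'
#' Joins peak-to-gene assignments with motif occurrences: an edge
#' `TF -> gene` is created whenever some peak is assigned to the gene and
#' carries a hit of one of the TF's motifs.  All supporting hits are kept as
#' edge evidence; a dimer motif attributed to several TFs yields one edge
#' per TF, sharing the evidence.  The result is independent of the input
#' row order.
#'
#' @param assignments Data frame from [assign_peaks_to_genes()].
#' @param hits Data frame from [scan_all()].
#' @param motif_to_tfs Named list mapping motif id to TF symbols (see
#'   [motif_tf_map()]).
#' @param receptors Character vector of receptor symbols to flag in the
#'   network.
#' @param peak_ids Optional character vector of all valid peak ids; when
#'   supplied, hits referencing unknown peaks are rejected with an error
#'   listing the offenders.  Hits in known peaks that simply have no gene
#'   assignment contribute nothing.
#' @return A [grn()] object.
#' @export
build_grn <- function(assignments, hits, motif_to_tfs, receptors = character(),
                      peak_ids = NULL) {
  if (!is.null(peak_ids)) {
    unknown <- sort_c(unique(hits$peak_id[!hits$peak_id %in% peak_ids]))
    if (length(unknown) > 0) {
      stop(sprintf("hits reference unknown peak_ids: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  unknown_motifs <- sort_c(unique(hits$motif_id[!hits$motif_id %in% names(motif_to_tfs)]))
  if (length(unknown_motifs) > 0) {
    stop(sprintf("hits reference motifs with no TF mapping: %s",
                 paste(unknown_motifs, collapse = ", ")), call. = FALSE)
  }
  if (nrow(hits) == 0 || nrow(assignments) == 0) return(grn(NULL, receptors))
  m <- merge(hits, assignments[, c("peak_id", "gene_id")], by = "peak_id")
  if (nrow(m) == 0) return(grn(NULL, receptors))
  tf_per_row <- motif_to_tfs[m$motif_id]
  reps <- lengths(tf_per_row)
  m <- m[rep(seq_len(nrow(m)), reps), , drop = FALSE]
  m$tf <- unlist(tf_per_row, use.names = FALSE)
  ev <- sprintf("%s|%s|%s|%d|%s", m$peak_id, m$motif_id, m$strand,
                m$offset, fmt_num(m$pvalue))
  key <- paste(m$tf, m$gene_id, sep = "\t")
  sp <- split(seq_len(nrow(m)), key)
  keys <- names(sp)
  tf_gene <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    tf = vapply(tf_gene, `[`, character(1), 1),
    gene = vapply(tf_gene, `[`, character(1), 2),
    n_peaks = vapply(sp, function(i) length(unique(m$peak_id[i])), integer(1)),
    best_pvalue = vapply(sp, function(i) min(m$pvalue[i]), numeric(1)),
    evidence = vapply(sp, function(i) paste(sort_c(unique(ev[i])), collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE)
  grn(edges, receptors)
}
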