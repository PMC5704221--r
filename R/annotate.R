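#' Anchor position of a peak
#'
#' The single-base position a peak is reduced to for gene assignment: the
#' summit (`start + summit_offset`) when the peak file provides one, else
#' the interval midpoint `floor((start + end - 1) / 2)`.
#'
#' @param peaks Data frame from [read_peaks()] (vectorised).
#' @return Integer vector of 0-based positions.
#' @examples
#' peak_position(data.frame(start = 100, end = 200, summit_offset = NA))  # 149
#' @export
peak_position <- function(peaks) {
  mid <- (peaks$start + peaks$end - 1L) %/% 2L
  ifelse(is.na(peaks$summit_offset), mid, peaks$start + peaks$summit_offset)
}

#' Assign peaks to genes by TSS proximity
#'
#' Emits an assignment `(peak, gene)` whenever the gene's transcription
#' start site lies within `window` bp of the peak position on the same
#' chromosome (closed interval: a distance of exactly `window` is kept).  A
#' peak may map to zero, one or several genes and a gene to several peaks;
#' no nearest-gene restriction is applied.
#'
#' @param peaks Data frame from [read_peaks()].
#' @param genes Data frame from [read_gene_annotation()].
#' @param window Maximum |TSS - peak position| in bp (default 2000, i.e. the
#'   conventional +/- 2 kb promoter-proximal window).
#' @return Data frame `peak_id`, `gene_id`, `distance` (signed, TSS minus
#'   peak position in genome coordinates), sorted by `(peak_id, gene_id)`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 2000) {
  stopifnot(window >= 0)
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(empty)
  pos <- peak_position(peaks)
  # 1-based closed coordinates for IRanges; peak anchor expanded by window,
  # intersected with TSS points
  pr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(pmax(pos + 1L - window, 1L),
                                                pos + 1L + window))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tss + 1L, width = 1L))
  # disjoint chromosome sets are a valid empty result, not a warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pr, gr, ignore.strand = TRUE))
  if (length(ov) == 0) return(empty)
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  out <- data.frame(peak_id = peaks$peak_id[pi],
                    gene_id = genes$gene_id[gi],
                    distance = genes$tss[gi] - pos[pi],
                    stringsAsFactors = FALSE)
  out <- out[order(out$peak_id, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
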