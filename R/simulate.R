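#' Configuration for the synthetic study generator
#'
#' Defines a fully self-contained toy study: a random genome, genes with
#' promoter-proximal accessibility peaks, a motif library, TF binding sites
#' planted into the peaks (the ground-truth regulatory edges), a second
#' "tumor-infiltrated" condition in which the peaks upstream of chosen
#' receptor genes are removed, and a grouped expression matrix in which
#' those receptors are down-modulated.
#'
#' @param seed Integer seed; fixes every random draw (byte-identical output
#'   trees on reruns).
#' @param n_chromosomes,chrom_length Number of chromosomes and their length
#'   in bp (defaults 2 x 120000).
#' @param n_genes Number of annotated genes (default 30); receptor genes are
#'   drawn from these.
#' @param n_tfs Number of TFs with planted binding sites (default 8).
#' @param n_decoy_tfs Number of decoy TFs whose motifs are in the library
#'   but never planted, so edge precision is measurable (default 4).
#' @param n_receptors Number of receptor genes (default 5), named
#'   `R1..Rk`.
#' @param n_peaks_per_gene Accessibility peaks per gene (default 1).
#' @param peak_width Peak width in bp (default 200).
#' @param planting_rate Probability that a designated TF -> gene edge
#'   receives a planted site (default 1).
#' @param motif_width Motif width in bp (default 9).  With the default
#'   point-mass motifs and a scan threshold of 1e-4 the odd width is chosen
#'   so only the exact consensus clears the threshold: the one-mismatch
#'   upper tail is (1 + 27) / 4^9 = 1.07e-4, just above it, so chance edges
#'   stay rare and edge precision is a meaningful readout.
#' @param motif_information_content_min Minimum per-column information
#'   content in bits (default 2, i.e. point-mass consensus columns).
#' @param background Base composition of the i.i.d. background genome
#'   (default uniform), which makes the analytic false-positive calibration
#'   exact.
#' @param shutdown_receptors Receptor symbols whose peaks (and hence all
#'   planted upstream sites) are deleted in condition B (default `"R1"`).
#' @param regulators_per_gene Integer vector to sample each gene's number of
#'   designated regulators from (default `2:4`).
#' @param expression_lfc Log2 fold-change by which shutdown receptors are
#'   down-shifted in the condition-B expression group (default 2).
#' @param expression_sd Log2-scale noise standard deviation (default 0.25).
#' @param samples_per_group Samples per expression group (default 5).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2, chrom_length = 120000,
                              n_genes = 30, n_tfs = 8, n_decoy_tfs = 4,
                              n_receptors = 5, n_peaks_per_gene = 1,
                              peak_width = 200, planting_rate = 1,
                              motif_width = 9,
                              motif_information_content_min = 2,
                              background = rep(0.25, 4),
                              shutdown_receptors = "R1",
                              regulators_per_gene = 2:4,
                              expression_lfc = 2, expression_sd = 0.25,
                              samples_per_group = 5) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              n_tfs = as.integer(n_tfs), n_decoy_tfs = as.integer(n_decoy_tfs),
              n_receptors = as.integer(n_receptors),
              n_peaks_per_gene = as.integer(n_peaks_per_gene),
              peak_width = as.integer(peak_width), planting_rate = planting_rate,
              motif_width = as.integer(motif_width),
              motif_information_content_min = motif_information_content_min,
              background = as.numeric(background),
              shutdown_receptors = shutdown_receptors,
              regulators_per_gene = as.integer(regulators_per_gene),
              expression_lfc = expression_lfc, expression_sd = expression_sd,
              samples_per_group = as.integer(samples_per_group))
  counts <- c(cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes, cfg$n_tfs,
              cfg$n_receptors, cfg$n_peaks_per_gene, cfg$peak_width,
              cfg$motif_width, cfg$samples_per_group)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (cfg$n_decoy_tfs < 0) stop("n_decoy_tfs must be >= 0", call. = FALSE)
  if (!(cfg$planting_rate > 0 && cfg$planting_rate <= 1)) {
    stop("planting_rate must be in (0, 1]", call. = FALSE)
  }
  if (length(cfg$background) != 4 || any(cfg$background <= 0) ||
      abs(sum(cfg$background) - 1) > 1e-6) {
    stop("background must be 4 positive frequencies summing to 1", call. = FALSE)
  }
  if (cfg$n_receptors > cfg$n_genes) stop("n_receptors > n_genes", call. = FALSE)
  if (cfg$motif_width >= cfg$peak_width) {
    stop("motif_width must be smaller than peak_width", call. = FALSE)
  }
  receptor_names <- paste0("R", seq_len(cfg$n_receptors))
  if (!all(cfg$shutdown_receptors %in% receptor_names)) {
    stop(sprintf("shutdown_receptors must be among %s",
                 paste(receptor_names, collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Dominant-base probability whose column information content (uniform
# background) meets ic_min bits; ic_min = 2 gives a point-mass column.
ic_dominant_prob <- function(ic_min) {
  if (ic_min >= 2) return(1)
  ic <- function(p) {
    q <- (1 - p) / 3
    probs <- c(p, q, q, q)
    2 + sum(ifelse(probs > 0, probs * log2(probs), 0))
  }
  stats::uniroot(function(p) ic(p) - ic_min, c(0.2500001, 1 - 1e-12),
                 tol = 1e-12)$root
}

#' Expected number of background motif hits
#'
#' Closed-form expectation for scanning i.i.d. background sequence on both
#' strands at p-value threshold `alpha`: `2 * (L - w + 1) * alpha` summed
#' over the scanned sequence lengths.
#'
#' @param lengths Integer vector of scanned sequence lengths (bp).
#' @param alpha P-value threshold in (0, 1), or 0 for the boundary case.
#' @param w Motif width; every length must be >= w.
#' @return Expected hit count (numeric scalar).
#' @export
expected_background_hits <- function(lengths, alpha, w) {
  stopifnot(alpha >= 0, alpha < 1, all(lengths >= w))
  sum(2 * (lengths - w + 1) * alpha)
}

#' Simulate a grouped expression matrix with down-modulated genes
#'
#' Log-normal model: each gene has a baseline log2 mean; listed genes have
#' their group-B mean shifted down by `lfc`; values are `2^rnorm(mean, sd)`.
#'
#' @param gene_symbols Character vector of genes (rows).
#' @param down_genes Genes down-shifted in group B.
#' @param n_per_group Samples per group (default 5).
#' @param lfc Log2 fold-change of the shift (default 2).
#' @param sd Log2-scale noise sd (default 0.25).
#' @param group_names Two group labels (default `c("blood", "tumor")`).
#' @param base_mean_range Range the baseline log2 means are drawn from.
#' @return An [expression_matrix()] with samples `<group>_1..n`.
#' @export
simulate_expression <- function(gene_symbols, down_genes = character(),
                                n_per_group = 5, lfc = 2, sd = 0.25,
                                group_names = c("blood", "tumor"),
                                base_mean_range = c(4, 8)) {
  stopifnot(length(group_names) == 2, n_per_group >= 2)
  ng <- length(gene_symbols)
  base <- stats::runif(ng, base_mean_range[1], base_mean_range[2])
  mean_b <- base - ifelse(gene_symbols %in% down_genes, lfc, 0)
  n <- n_per_group
  vals <- cbind(
    matrix(2^stats::rnorm(ng * n, mean = rep(base, times = n), sd = sd), ng, n),
    matrix(2^stats::rnorm(ng * n, mean = rep(mean_b, times = n), sd = sd), ng, n))
  samples <- c(paste0(group_names[1], "_", seq_len(n)),
               paste0(group_names[2], "_", seq_len(n)))
  dimnames(vals) <- list(gene_symbols, samples)
  expression_matrix(vals, stats::setNames(rep(group_names, each = n), samples))
}

#' Generate the full synthetic study
#'
#' Writes a self-contained dataset with known ground truth into `outdir`:
#' `genome.fa` (i.i.d. background with planted motif sites), `genes.bed`,
#' `motifs.meme` (planted + decoy motifs), `peaks_A.narrowPeak`,
#' `peaks_B.narrowPeak` (condition A minus the shutdown receptors' peaks),
#' `receptors.txt`, `genesets.gmt` (one set per planted TF = its planted
#' targets), `expression.tsv` + `labels.tsv` (two groups; shutdown
#' receptors down-shifted in the second), and `truth.json`.
#'
#' Reruns with the same configuration produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, an object of class `"ground_truth"`: list with
#'   `planted_edges` (data frame `tf`, `gene`), `planted_sites` (data frame
#'   `peak_id`, `motif_id`, `offset`, `strand`, `chrom`, `genome_start`),
#'   `condition_B_deleted_edges`, `decoy_tfs`, `shutdown_receptors`, and
#'   `files` (named paths).
#' @export
simulate_study <- function(config = simulation_config(), outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  ## gene layout: evenly spaced slots so no peak of one gene can fall within
  ## the assignment window of another gene's TSS
  margin <- 3000L
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  spacing <- (config$chrom_length - 2L * margin) %/% per_chrom
  if (spacing < 4200L + config$peak_width) {
    stop("chrom_length too small for the requested gene density", call. = FALSE)
  }
  receptor_names <- paste0("R", seq_len(config$n_receptors))
  other_names <- sprintf("G%03d", seq_len(config$n_genes - config$n_receptors))
  symbols <- sample(c(receptor_names, other_names))
  genes <- data.frame(gene_id = symbols, symbol = symbols,
                      chrom = character(config$n_genes),
                      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                      start = integer(config$n_genes), end = integer(config$n_genes),
                      tss = integer(config$n_genes), stringsAsFactors = FALSE)
  for (g in seq_len(config$n_genes)) {
    ci <- ((g - 1L) %/% per_chrom) + 1L
    slot <- ((g - 1L) %% per_chrom)
    pos <- margin + slot * spacing + sample.int(500L, 1L)
    len <- sample(800:2000, 1L)
    genes$chrom[g] <- chroms[ci]
    if (genes$strand[g] == "+") {
      genes$start[g] <- pos; genes$end[g] <- pos + len
    } else {
      genes$start[g] <- pos + 1L - len; genes$end[g] <- pos + 1L
    }
    genes$tss[g] <- pos
  }

  ## motif library: distinct consensus sequences, dominant-base columns
  n_motifs <- config$n_tfs + config$n_decoy_tfs
  tf_names <- c(sprintf("TF%02d", seq_len(config$n_tfs)),
                sprintf("DTF%02d", seq_len(config$n_decoy_tfs))[seq_len(config$n_decoy_tfs)])
  p_dom <- ic_dominant_prob(config$motif_information_content_min)
  consensus <- character(0)
  motifs <- vector("list", n_motifs)
  for (m in seq_len(n_motifs)) {
    for (attempt in seq_len(1000L)) {
      cons <- paste(sample(DNA_BASES, config$motif_width, replace = TRUE,
                           prob = config$background), collapse = "")
      if (!(cons %in% consensus) && !(revcomp(cons) %in% consensus)) break
      if (attempt == 1000L) stop("could not draw distinct motif consensi", call. = FALSE)
    }
    consensus <- c(consensus, cons)
    prob <- matrix((1 - p_dom) / 3, nrow = config$motif_width, ncol = 4)
    dom <- match(strsplit(cons, "")[[1]], DNA_BASES)
    prob[cbind(seq_len(config$motif_width), dom)] <- p_dom
    motifs[[m]] <- pwm(sprintf("M%02d", m), tf_names[m], prob)
  }
  names(motifs) <- vapply(motifs, function(m) m$motif_id, character(1))
  planted_tf <- tf_names[seq_len(config$n_tfs)]
  decoy_tf <- setdiff(tf_names, planted_tf)

  ## designated edges and peaks
  peaks <- data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), summit_offset = integer(),
                      gene = character(), stringsAsFactors = FALSE)
  pk <- 0L
  for (g in seq_len(config$n_genes)) {
    for (j in seq_len(config$n_peaks_per_gene)) {
      pk <- pk + 1L
      half <- config$peak_width %/% 2L
      center <- genes$tss[g] + sample.int(2L * (1500L - half) + 1L, 1L) - (1500L - half) - 1L
      start <- center - half
      peaks <- rbind(peaks, data.frame(
        chrom = genes$chrom[g], start = start, end = start + config$peak_width,
        peak_id = sprintf("peak%04d", pk), summit_offset = half,
        gene = genes$gene_id[g], stringsAsFactors = FALSE))
    }
  }

  edges <- list(); sites <- list()
  site_occupancy <- list()  # peak_id -> integer offsets occupied
  for (g in seq_len(config$n_genes)) {
    rp <- config$regulators_per_gene
    k <- if (length(rp) == 1) rp else sample(rp, 1L)
    k <- min(k, config$n_tfs)
    regs <- sample(planted_tf, k)
    gene_peaks <- which(peaks$gene == genes$gene_id[g])
    for (tf in regs) {
      if (stats::runif(1) > config$planting_rate) next
      p <- if (length(gene_peaks) == 1) gene_peaks else sample(gene_peaks, 1L)
      pid <- peaks$peak_id[p]
      occ <- site_occupancy[[pid]] %||% integer(0)
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        off <- sample.int(config$peak_width - config$motif_width + 1L, 1L) - 1L
        if (!any(abs(occ - off) < config$motif_width)) { placed <- TRUE; break }
      }
      if (!placed) {
        stop(sprintf("could not place a non-overlapping site in %s after 1000 attempts", pid),
             call. = FALSE)
      }
      site_occupancy[[pid]] <- c(occ, off)
      strand <- sample(c("+", "-"), 1L)
      mid <- names(motifs)[match(tf, tf_names)]
      edges[[length(edges) + 1L]] <- data.frame(tf = tf, gene = genes$gene_id[g],
                                                stringsAsFactors = FALSE)
      sites[[length(sites) + 1L]] <- data.frame(
        peak_id = pid, motif_id = mid, offset = off, strand = strand,
        chrom = peaks$chrom[p], genome_start = peaks$start[p] + off,
        stringsAsFactors = FALSE)
    }
  }
  planted_edges <- unique(do.call(rbind, edges))
  planted_edges <- planted_edges[order(planted_edges$tf, planted_edges$gene,
                                       method = "radix"), , drop = FALSE]
  rownames(planted_edges) <- NULL
  planted_sites <- do.call(rbind, sites)
  rownames(planted_sites) <- NULL

  ## genome: i.i.d. background, then overwrite the planted sites
  genome_chars <- lapply(chroms, function(ch) {
    sample(DNA_BASES, config$chrom_length, replace = TRUE, prob = config$background)
  })
  names(genome_chars) <- chroms
  cons_by_motif <- stats::setNames(consensus, names(motifs))
  for (s in seq_len(nrow(planted_sites))) {
    cons <- cons_by_motif[[planted_sites$motif_id[s]]]
    if (planted_sites$strand[s] == "-") cons <- revcomp(cons)
    at <- planted_sites$genome_start[s] + seq_len(config$motif_width)  # 1-based
    genome_chars[[planted_sites$chrom[s]]][at] <- strsplit(cons, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms

  ## condition B: drop the shutdown receptors' peaks
  deleted_genes <- config$shutdown_receptors
  peaks_b <- peaks[!(peaks$gene %in% deleted_genes), , drop = FALSE]
  del <- planted_edges$gene %in% deleted_genes
  deleted_edges <- planted_edges[del, , drop = FALSE]
  rownames(deleted_edges) <- NULL

  ## expression: shutdown receptors down-modulated in group B
  expr <- simulate_expression(sort_c(genes$gene_id), deleted_genes,
                              n_per_group = config$samples_per_group,
                              lfc = config$expression_lfc,
                              sd = config$expression_sd)

  ## write everything
  paths <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.bed"),
             motifs = file.path(outdir, "motifs.meme"),
             peaks_A = file.path(outdir, "peaks_A.narrowPeak"),
             peaks_B = file.path(outdir, "peaks_B.narrowPeak"),
             receptors = file.path(outdir, "receptors.txt"),
             gmt = file.path(outdir, "genesets.gmt"),
             expression = file.path(outdir, "expression.tsv"),
             labels = file.path(outdir, "labels.tsv"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(genome, paths["genome"], width = 80)
  bed <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start, genes$end,
                 genes$gene_id, genes$strand)
  writeLines(bed, con <- file(paths["genes"], "wb")); close(con)
  write_meme_motifs(motifs, paths["motifs"], background = config$background)
  write_peaks(peaks[, c("chrom", "start", "end", "peak_id", "summit_offset")],
              paths["peaks_A"])
  write_peaks(peaks_b[, c("chrom", "start", "end", "peak_id", "summit_offset")],
              paths["peaks_B"])
  writeLines(receptor_names, con <- file(paths["receptors"], "wb")); close(con)
  target_sets <- lapply(stats::setNames(planted_tf, paste0("targets_", planted_tf)),
                        function(tf) sort_c(planted_edges$gene[planted_edges$tf == tf]))
  target_sets <- target_sets[lengths(target_sets) > 0]
  write_gmt(target_sets, paths["gmt"])
  write_expression(expr, paths["expression"], paths["labels"])

  truth <- structure(list(planted_edges = planted_edges,
                          planted_sites = planted_sites,
                          condition_B_deleted_edges = deleted_edges,
                          decoy_tfs = decoy_tf,
                          shutdown_receptors = config$shutdown_receptors,
                          files = paths),
                     class = "ground_truth")
  jsonlite::write_json(list(planted_edges = planted_edges,
                            planted_sites = planted_sites,
                            condition_B_deleted_edges = deleted_edges,
                            decoy_tfs = as.list(decoy_tf),
                            shutdown_receptors = as.list(config$shutdown_receptors)),
                       paths["truth"], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted edges (%d deleted in condition B), %d sites, %d decoy TFs\n",
              nrow(x$planted_edges), nrow(x$condition_B_deleted_edges),
              nrow(x$planted_sites), length(x$decoy_tfs)))
  invisible(x)
}
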