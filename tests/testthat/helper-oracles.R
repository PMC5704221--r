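# Independent brute-force oracles used to validate the production code
# paths.  These deliberately use the most direct formulation possible.

# all-pairs peak-to-gene assignment
bf_assign <- function(peaks, genes, window = 2000) {
  pos <- peak_position(peaks)
  out <- list()
  for (p in seq_len(nrow(peaks))) {
    for (g in seq_len(nrow(genes))) {
      if (peaks$chrom[p] == genes$chrom[g] &&
          abs(genes$tss[g] - pos[p]) <= window) {
        out[[length(out) + 1]] <- data.frame(peak_id = peaks$peak_id[p],
                                             gene_id = genes$gene_id[g],
                                             distance = genes$tss[g] - pos[p],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$peak_id, res$gene_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive enumeration of all 4^w words: integer total scores and their
# background probabilities
bf_enumerate_scores <- function(s_int, background) {
  w <- nrow(s_int)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- integer(nrow(words))
  pr <- rep(1, nrow(words))
  for (i in seq_len(w)) {
    tot <- tot + s_int[i, words[, i]]
    pr <- pr * background[words[, i]]
  }
  list(tot = tot, pr = pr)
}

bf_tail_pvalue <- function(enum, t) sum(enum$pr[enum$tot >= t])

# dense linear-system PageRank: solve (I - d*A) pi = (1-d)/n * 1 where
# column i of A spreads node i's mass (uniformly over n for dangling nodes)
dense_pagerank <- function(node_names, src, dst, damping = 0.85) {
  n <- length(node_names)
  A <- matrix(0, n, n)
  outdeg <- tabulate(src, nbins = n)
  for (e in seq_along(src)) A[dst[e], src[e]] <- A[dst[e], src[e]] + 1 / outdeg[src[e]]
  for (i in which(outdeg == 0)) A[, i] <- 1 / n
  pi_v <- solve(diag(n) - damping * A, rep((1 - damping) / n, n))
  stats::setNames(pi_v, node_names)
}

# combinatorial hypergeometric upper tail
bf_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random test objects -------------------------------------------------------

random_pwm <- function(w, id = "M1", tfs = "TF1") {
  m <- matrix(stats::rgamma(w * 4, 0.6) + 1e-6, nrow = w)
  pwm(id, tfs, m / rowSums(m))
}

point_pwm <- function(consensus, id = "PM", tfs = "TFPM") {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, nrow = length(idx), ncol = 4)
  m[cbind(seq_along(idx), idx)] <- 1
  pwm(id, tfs, m)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

fake_evidence <- function(n = 1) {
  paste(sprintf("pk%d|M%d|+|%d|0.0001", seq_len(n), seq_len(n), seq_len(n)),
        collapse = ";")
}

random_grn <- function(n_tfs, n_genes, n_edges, receptors = character(),
                       allow_overlap_names = FALSE) {
  tfs <- paste0("T", seq_len(n_tfs))
  genes <- paste0("g", seq_len(n_genes))
  if (allow_overlap_names) genes[1] <- tfs[1]  # a node with both roles
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- pairs[pick, , drop = FALSE]
  edges$n_peaks <- sample(1:3, nrow(edges), replace = TRUE)
  edges$best_pvalue <- stats::runif(nrow(edges), 1e-8, 1e-4)
  edges$evidence <- replicate(nrow(edges), fake_evidence(sample(1:2, 1)))
  grn(edges, receptors)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000,
                         width_range = c(50, 400)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  summit <- ifelse(stats::runif(n) < 0.5, NA_integer_,
                   vapply(width, function(w) sample.int(w, 1) - 1L, integer(1)))
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + width, peak_id = sprintf("pk%04d", seq_len(n)),
             summit_offset = summit, stringsAsFactors = FALSE)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(500:2000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             symbol = sprintf("g%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             strand = strand, start = start, end = start + len,
             tss = ifelse(strand == "+", start, start + len - 1L),
             stringsAsFactors = FALSE)
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  stats::setNames(as.character(tools::md5sum(file.path(dir, files))), files)
}
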