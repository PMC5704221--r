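small_sim <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chromosomes = 1, chrom_length = 60000,
                    n_genes = 12, n_tfs = 4, n_decoy_tfs = 2, n_receptors = 3,
                    ...)
}

test_that("simulate_study is byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_sim(seed = 99), d1)
  simulate_study(small_sim(seed = 99), d2)
  m1 <- md5_tree(d1); m2 <- md5_tree(d2)
  expect_identical(names(m1), names(m2))
  expect_identical(unname(m1), unname(m2))
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_study(small_sim(seed = 100), d3)
  expect_false(identical(unname(m1), unname(md5_tree(d3))))
})

test_that("planted sites re-read from the written FASTA match the consensus", {
  d <- withr::local_tempdir()
  truth <- simulate_study(small_sim(seed = 5), d)
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  motifs <- read_meme_motifs(file.path(d, "motifs.meme"))
  for (s in seq_len(nrow(truth$planted_sites))) {
    site <- truth$planted_sites[s, ]
    m <- motifs[[site$motif_id]]
    seq_s <- as.character(Biostrings::subseq(genome[[site$chrom]],
                                             site$genome_start + 1,
                                             site$genome_start + pwm_width(m)))
    expected <- pwm_consensus(m)
    if (site$strand == "-") {
      seq_s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_s)))
    }
    expect_identical(seq_s, expected)
  }
})

test_that("ground truth is internally consistent and matches the config", {
  d <- withr::local_tempdir()
  cfg <- small_sim(seed = 6, shutdown_receptors = c("R1", "R2"))
  truth <- simulate_study(cfg, d)
  pk <- paste(truth$planted_edges$tf, truth$planted_edges$gene)
  dk <- paste(truth$condition_B_deleted_edges$tf, truth$condition_B_deleted_edges$gene)
  expect_true(all(dk %in% pk))
  expect_true(all(truth$condition_B_deleted_edges$gene %in% cfg$shutdown_receptors))
  # with planting_rate = 1 every gene has at least one planted regulator
  expect_setequal(unique(truth$planted_edges$gene),
                  read_gene_annotation(file.path(d, "genes.bed"))$gene_id)
  # truth.json round-trips the edge sets
  js <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_setequal(paste(js$planted_edges$tf, js$planted_edges$gene), pk)
})

test_that("condition B differs from A exactly at the shutdown receptors' peaks", {
  d <- withr::local_tempdir()
  cfg <- small_sim(seed = 7)
  truth <- simulate_study(cfg, d)
  a <- readLines(file.path(d, "peaks_A.narrowPeak"))
  b <- readLines(file.path(d, "peaks_B.narrowPeak"))
  # kept peaks are byte-identical and in the same order
  expect_identical(b, a[a %in% b])
  removed <- setdiff(a, b)
  expect_gt(length(removed), 0)
  removed_ids <- vapply(strsplit(removed, "\t"), `[`, character(1), 4)
  # removed peaks are precisely the ones assigned to the shutdown receptors
  peaks_a <- read_peaks(file.path(d, "peaks_A.narrowPeak"), "narrowPeak")
  genes <- read_gene_annotation(file.path(d, "genes.bed"))
  asg <- assign_peaks_to_genes(peaks_a, genes, window = 2000)
  shutdown_peaks <- asg$peak_id[asg$gene_id %in% cfg$shutdown_receptors]
  expect_setequal(removed_ids, shutdown_peaks)
  # the deleted edges' planted sites all live in removed peaks
  deleted <- truth$condition_B_deleted_edges
  expect_true(all(deleted$gene %in% cfg$shutdown_receptors))
})

test_that("expected_background_hits follows the closed form", {
  expect_equal(expected_background_hits(1000, 1e-3, 1), 2)
  expect_equal(expected_background_hits(1000, 0, 5), 0)
  expect_equal(expected_background_hits(1e6, 1e-4, 10), 2 * (1e6 - 9) * 1e-4)
  # sums over multiple scanned sequences
  expect_equal(expected_background_hits(c(100, 200), 0.01, 10),
               2 * (91 + 191) * 0.01)
  expect_error(expected_background_hits(5, 0.1, 10))
})

test_that("simulated expression down-shifts the listed genes by the lfc", {
  set.seed(42)
  expr <- simulate_expression(paste0("g", 1:200), down_genes = c("g1", "g2"),
                              n_per_group = 50, lfc = 2, sd = 0.25)
  lg <- log2(expr$values)
  blood <- expr$groups == "blood"
  shift <- rowMeans(lg[, blood]) - rowMeans(lg[, !blood])
  expect_equal(unname(shift[c("g1", "g2")]), c(2, 2), tolerance = 0.2)
  expect_lt(max(abs(shift[-(1:2)])), 0.5)
  expect_true(all(expr$values > 0))
})
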