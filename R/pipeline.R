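#' Pipeline configuration
#'
#' Collects every input path and tunable parameter for an end-to-end run:
#' peak-to-gene window, motif p-value threshold, PageRank settings and the
#' number of top regulators to report.
#'
#' @param genome Path to the genome FASTA.
#' @param genes Path to the BED6 gene annotation.
#' @param peaks Named character vector of condition name -> peak file path
#'   (narrowPeak), e.g. `c(A = "peaks_A.narrowPeak", B = "peaks_B.narrowPeak")`.
#' @param motifs Path to the MEME-format motif library.
#' @param receptors Optional path to the receptor gene list.
#' @param gmt Optional path to a GMT gene-set library (for enrichment of the
#'   lost-edge target genes).
#' @param expression,labels Optional paths to the expression matrix and its
#'   group labels.
#' @param group_a,group_b Expression group labels to compare (defaults
#'   `"blood"` and `"tumor"`).
#' @param window Peak-to-gene TSS window in bp (default 2000).
#' @param scan A [scan_config()] (default: alpha 1e-4, pseudocount 0.01,
#'   uniform background).
#' @param k Top regulators to report (default 20).
#' @param damping,pagerank_reverse PageRank parameters (defaults 0.85,
#'   reversed edges).
#' @param expr_threshold Modulated-gene p-value threshold (default 0.01).
#' @param outdir Output directory for all result files.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(genome, genes, peaks, motifs, receptors = NULL,
                            gmt = NULL, expression = NULL, labels = NULL,
                            group_a = "blood", group_b = "tumor",
                            window = 2000, scan = scan_config(), k = 20,
                            damping = 0.85, pagerank_reverse = TRUE,
                            expr_threshold = 0.01, outdir) {
  stopifnot(length(peaks) >= 1, !is.null(names(peaks)), all(nzchar(names(peaks))))
  stopifnot(inherits(scan, "scan_config"), window >= 0, k >= 1)
  cfg <- structure(list(genome = genome, genes = genes, peaks = peaks,
                        motifs = motifs, receptors = receptors, gmt = gmt,
                        expression = expression, labels = labels,
                        group_a = group_a, group_b = group_b,
                        window = window, scan = scan, k = k,
                        damping = damping, pagerank_reverse = pagerank_reverse,
                        expr_threshold = expr_threshold, outdir = outdir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  paths <- c(genome = cfg$genome, genes = cfg$genes, motifs = cfg$motifs,
             cfg$peaks, receptors = cfg$receptors, gmt = cfg$gmt,
             expression = cfg$expression, labels = cfg$labels)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("pipeline input file(s) not found: %s",
                 paste(sprintf("%s (%s)", names(missing), missing), collapse = "; ")),
         call. = FALSE)
  }
  invisible(cfg)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the network-construction pipeline for one condition
#'
#' Reads the inputs, assigns peaks to genes, scans the peak sequences with
#' the motif library, builds the GRN, ranks regulators by out-degree and by
#' PageRank, and extracts the receptor subnetwork.  All intermediate tables
#' are written as TSV under `outdir`; output is deterministic given the
#' inputs (logging goes to stderr only).
#'
#' @param config A [pipeline_config()].
#' @param condition Name of the condition (must match a name of
#'   `config$peaks`).
#' @return List with `peaks`, `assignments`, `hits`, `grn`,
#'   `ranking_outdegree`, `ranking_pagerank`, `receptor_grn`, `summary`.
#' @export
run_condition <- function(config, condition) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  if (!condition %in% names(config$peaks)) {
    stop(sprintf("unknown condition '%s' (have: %s)", condition,
                 paste(names(config$peaks), collapse = ", ")), call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::readDNAStringSet(config$genome)
  genes <- read_gene_annotation(config$genes)
  motifs <- read_meme_motifs(config$motifs)
  receptors <- if (is.null(config$receptors)) character() else
    read_gene_list(config$receptors)
  peaks <- read_peaks(config$peaks[[condition]], "narrowPeak")
  log_stage("annotate", "condition %s: %d peaks, %d genes", condition,
            nrow(peaks), nrow(genes))
  assignments <- assign_peaks_to_genes(peaks, genes, config$window)
  write_tsv_file(assignments,
                 file.path(config$outdir, sprintf("assignments_%s.tsv", condition)))
  log_stage("scan", "condition %s: %d assignments; scanning %d motifs",
            condition, nrow(assignments), length(motifs))
  hits <- scan_all(peaks, genome, motifs, config$scan)
  tfmap <- motif_tf_map(motifs)
  hits_out <- data.frame(motif_id = hits$motif_id,
                         tf_names = vapply(tfmap[hits$motif_id], paste,
                                           character(1), collapse = ";"),
                         peak_id = hits$peak_id, offset = hits$offset,
                         strand = hits$strand, score_bits = hits$score,
                         pvalue = hits$pvalue, stringsAsFactors = FALSE)
  write_tsv_file(hits_out, file.path(config$outdir, sprintf("hits_%s.tsv", condition)))
  log_stage("build", "condition %s: %d motif hits", condition, nrow(hits))
  net <- build_grn(assignments, hits, tfmap, receptors, peak_ids = peaks$peak_id)
  write_network(net, file.path(config$outdir, sprintf("grn_%s.tsv", condition)))
  rk_out <- rank_regulators_by_outdegree(net, config$k)
  rk_pr <- if (nrow(net$nodes) > 0) {
    rank_regulators_by_pagerank(net, config$k, damping = config$damping,
                                reverse = config$pagerank_reverse)
  } else rk_out
  write_tsv_file(as.data.frame(rk_out),
                 file.path(config$outdir, sprintf("ranking_%s_outdegree.tsv", condition)))
  write_tsv_file(as.data.frame(rk_pr),
                 file.path(config$outdir, sprintf("ranking_%s_pagerank.tsv", condition)))
  rec_net <- receptor_subnetwork(net)
  write_network(rec_net,
                file.path(config$outdir, sprintf("receptor_subnetwork_%s.tsv", condition)))
  summ <- network_summary(net)
  write_tsv_file(summ, file.path(config$outdir, sprintf("summary_%s.tsv", condition)))
  log_stage("done", "condition %s: %d edges, %d nodes", condition,
            summ$n_edges, summ$n_nodes)
  list(peaks = peaks, assignments = assignments, hits = hits, grn = net,
       ranking_outdegree = rk_out, ranking_pagerank = rk_pr,
       receptor_grn = rec_net, summary = summ)
}

#' Run and compare two conditions end-to-end
#'
#' Runs [run_condition()] for conditions `a` and `b`, computes the
#' differential network and the differential receptor network, tests the
#' target genes of the lost edges for gene-set over-representation (when a
#' GMT library is configured), and screens the expression matrix for
#' modulated genes (when configured).  A `manifest.json` with all parameter
#' values and input checksums is written; rerunning with identical inputs
#' reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()] with at least two conditions.
#' @param a,b Condition names (default the first two of `config$peaks`).
#' @return List with `a`, `b` (per-condition results), `diff`,
#'   `diff_receptor_grn`, `enrichment` (or `NULL`), `modulated` (or
#'   `NULL`).
#' @export
run_comparison <- function(config, a = names(config$peaks)[1],
                           b = names(config$peaks)[2]) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  res_a <- run_condition(config, a)
  res_b <- run_condition(config, b)
  dn <- diff_network(res_a$grn, res_b$grn)
  write_tsv_file(dn$edges_lost, file.path(config$outdir, "diff_edges_lost.tsv"))
  write_tsv_file(dn$edges_gained, file.path(config$outdir, "diff_edges_gained.tsv"))
  write_tsv_file(dn$receptors_lost, file.path(config$outdir, "diff_receptors_lost.tsv"))
  drn <- diff_receptor_network(res_a$grn, res_b$grn)
  write_network(drn, file.path(config$outdir, "diff_receptor_network.tsv"))
  enrichment <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    universe <- res_a$grn$nodes$name[res_a$grn$nodes$is_gene]
    query <- intersect(unique(dn$edges_lost$gene), universe)
    if (length(query) > 0) {
      enrichment <- hypergeom_enrich(query, sets, universe)
      write_tsv_file(enrichment, file.path(config$outdir, "enrichment_lost_targets.tsv"))
    } else {
      log_stage("enrich", "no lost-edge target genes; skipping enrichment")
    }
  }
  modulated <- NULL
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression, config$labels)
    modulated <- modulated_genes(expr, config$group_a, config$group_b,
                                 threshold = config$expr_threshold)
    write_tsv_file(modulated$table, file.path(config$outdir, "modulated_genes.tsv"))
  }
  manifest <- list(
    parameters = list(window = config$window, alpha = config$scan$alpha,
                      pseudocount = config$scan$pseudocount,
                      background = as.numeric(config$scan$background),
                      granularity = config$scan$granularity, k = config$k,
                      damping = config$damping,
                      pagerank_reverse = config$pagerank_reverse,
                      expr_threshold = config$expr_threshold,
                      conditions = c(a, b)),
    inputs = {
      files <- stats::na.omit(c(
        genome = config$genome, genes = config$genes, motifs = config$motifs,
        config$peaks, receptors = config$receptors %||% NA_character_,
        gmt = config$gmt %||% NA_character_,
        expression = config$expression %||% NA_character_,
        labels = config$labels %||% NA_character_))
      # key by role, not by path, so manifests are location-independent
      as.list(stats::setNames(unname(tools::md5sum(unname(files))), names(files)))
    })
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(a = res_a, b = res_b, diff = dn, diff_receptor_grn = drn,
       enrichment = enrichment, modulated = modulated)
}

#' One-command synthetic study: simulate, run, compare
#'
#' Generates the synthetic dataset under `<outdir>/data`, then runs the full
#' two-condition comparison under `<outdir>/results`.  With a fixed
#' configuration the entire output tree is byte-identical across reruns.
#'
#' @param sim A [simulation_config()].
#' @param outdir Output directory.
#' @param window,k,expr_threshold Pipeline parameters (defaults 2000, 20,
#'   0.01).
#' @param scan A [scan_config()]; its background defaults to the
#'   simulation's base composition.
#' @return List with `truth` (the [simulate_study()] ground truth),
#'   `comparison` (the [run_comparison()] result) and `config` (the
#'   [pipeline_config()] used).
#' @export
run_synthetic_study <- function(sim = simulation_config(), outdir,
                                window = 2000, k = 20, expr_threshold = 0.01,
                                scan = NULL) {
  truth <- simulate_study(sim, file.path(outdir, "data"))
  f <- truth$files
  if (is.null(scan)) scan <- scan_config(background = sim$background)
  cfg <- pipeline_config(genome = f[["genome"]], genes = f[["genes"]],
                         peaks = c(A = unname(f["peaks_A"]), B = unname(f["peaks_B"])),
                         motifs = f[["motifs"]], receptors = f[["receptors"]],
                         gmt = f[["gmt"]], expression = f[["expression"]],
                         labels = f[["labels"]], window = window, scan = scan,
                         k = k, expr_threshold = expr_threshold,
                         outdir = file.path(outdir, "results"))
  comparison <- run_comparison(cfg, "A", "B")
  list(truth = truth, comparison = comparison, config = cfg)
}
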