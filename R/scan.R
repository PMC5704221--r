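#' Motif scan configuration
#'
#' @param alpha Motif-hit p-value threshold; occurrences with
#'   `p-value <= alpha` are reported (default `1e-4`, the conventional
#'   FIMO-style cutoff).
#' @param pseudocount Pseudocount fraction `eps` used to regularise PWM
#'   probabilities towards the background (default `0.01`).
#' @param background Length-4 vector of background base frequencies
#'   (A,C,G,T), all positive, summing to 1 (default uniform).  The same
#'   vector defines the log-odds denominator and the null model for
#'   p-values (0-order background).
#' @param granularity Score discretisation step in bits for the exact
#'   p-value dynamic programme (default `0.001`).  Observed scores are
#'   rounded down onto the grid, so reported p-values are never
#'   underestimated.
#' @param max_grid Maximum number of grid cells the dynamic programme may
#'   allocate (default `1e7`); exceeding it raises an error advising a
#'   larger granularity.
#' @return An object of class `"scan_config"`.
#' @export
scan_config <- function(alpha = 1e-4, pseudocount = 0.01,
                        background = rep(0.25, 4), granularity = 0.001,
                        max_grid = 1e7) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive frequencies summing to 1", call. = FALSE)
  }
  background <- background / sum(background)
  if (granularity <= 0) stop("granularity must be positive", call. = FALSE)
  structure(list(alpha = alpha, pseudocount = pseudocount,
                 background = stats::setNames(background, DNA_BASES),
                 granularity = granularity, max_grid = max_grid),
            class = "scan_config")
}

#' Regularise a PWM with a background-weighted pseudocount
#'
#' Each probability becomes `(p + eps * b) / (1 + eps)` where `b` is the
#' background frequency of the base, so all entries are strictly positive
#' when `eps > 0` and rows still sum to 1.
#'
#' @param x A [pwm()] object.
#' @param config A [scan_config()].
#' @return The regularised [pwm()].
#' @export
regularize_pwm <- function(x, config = scan_config()) {
  stopifnot(inherits(x, "pwm"))
  eps <- config$pseudocount
  prob <- sweep(x$prob * 1, 2, eps * config$background, `+`) / (1 + eps)
  pwm(x$motif_id, x$tf_names, prob)
}

#' Log-odds score matrix of a regularised PWM
#'
#' @param x A [pwm()] object (regularise first so no entry is zero).
#' @param config A [scan_config()].
#' @return `w x 4` matrix of `log2(p / b)` scores in bits.
#' @export
pwm_log_odds <- function(x, config = scan_config()) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$prob <= 0)) {
    stop("log-odds requires strictly positive probabilities; apply regularize_pwm()",
         call. = FALSE)
  }
  log2(sweep(x$prob, 2, config$background, `/`))
}

#' Exact null score distribution of a PWM score matrix
#'
#' Computes, by position-wise convolution on an integer score grid, the
#' exact distribution of the total log-odds score of a random sequence drawn
#' i.i.d. from the background.  This is the FIMO-style null used to convert
#' motif scores into p-values.
#'
#' @param score_matrix `w x 4` log-odds matrix in bits (from
#'   [pwm_log_odds()]).
#' @param background Length-4 background frequencies.
#' @param granularity Grid step in bits.
#' @param max_grid Maximum grid cells allowed.
#' @return An object of class `"score_dist"` with elements `granularity`,
#'   `int_matrix` (the floor-discretised integer score matrix), `scores`
#'   (sorted achievable integer totals), `prob` (their probabilities,
#'   summing to 1 within `1e-9`), `pvalue` (upper-tail probability
#'   `P(S >= s)` per achievable score) and `min_int`/`max_int`.
#' @export
score_distribution <- function(score_matrix, background = rep(0.25, 4),
                               granularity = 0.001, max_grid = 1e7) {
  stopifnot(is.matrix(score_matrix), ncol(score_matrix) == 4)
  if (any(!is.finite(score_matrix))) {
    stop("score matrix has non-finite entries; regularise the PWM first", call. = FALSE)
  }
  s_int <- matrix(as.integer(floor(score_matrix / granularity)),
                  nrow = nrow(score_matrix))
  mins <- apply(s_int, 1, min)
  maxs <- apply(s_int, 1, max)
  total_cells <- sum(maxs - mins) + 1
  if (total_cells > max_grid) {
    stop(sprintf(paste0("score grid needs %.3g cells (cap %.3g); ",
                        "increase granularity"), total_cells, max_grid),
         call. = FALSE)
  }
  # sparse convolution over achievable sums; never more entries than the
  # dense grid, and typically far fewer for informative motifs
  scores <- 0
  prob <- 1
  for (i in seq_len(nrow(s_int))) {
    cand <- rep(scores, times = 4) + rep(s_int[i, ], each = length(scores))
    w8 <- rep(prob, times = 4) * rep(background, each = length(prob))
    agg <- rowsum(w8, cand)
    scores <- as.numeric(rownames(agg))
    prob <- as.numeric(agg)
  }
  pv <- pmin(rev(cumsum(rev(prob))), 1)
  structure(list(granularity = granularity, int_matrix = s_int,
                 scores = scores, prob = prob, pvalue = pv,
                 min_int = sum(mins), max_int = sum(maxs)),
            class = "score_dist")
}

#' P-value of a motif score under the exact null distribution
#'
#' @param dist A [score_distribution()] object.
#' @param score Numeric vector of scores in bits (rounded down onto the
#'   grid, a conservative choice) or, with `integer_score = TRUE`, already
#'   discretised integer totals.
#' @param integer_score Whether `score` is already on the integer grid.
#' @return Upper-tail probability `P(S >= score)` per input score.
#' @export
score_pvalue <- function(dist, score, integer_score = FALSE) {
  t_int <- if (integer_score) score else floor(score / dist$granularity)
  # first achievable score >= t_int
  j <- findInterval(t_int - 1, dist$scores) + 1
  out <- numeric(length(j))
  inside <- j <= length(dist$scores)
  out[inside] <- dist$pvalue[j[inside]]
  # a score above the maximum achievable has zero upper-tail mass
  out[!inside] <- 0
  out
}

# Precompute everything needed to scan with one motif: regularised PWM,
# continuous and integer score matrices for both strands, and the null
# distribution shared by the two strands.
motif_scorer <- function(x, config = scan_config()) {
  reg <- regularize_pwm(x, config)
  S <- pwm_log_odds(reg, config)
  dist <- score_distribution(S, config$background, config$granularity,
                             config$max_grid)
  w <- nrow(S)
  list(motif_id = x$motif_id, tf_names = x$tf_names, width = w,
       S = S, S_int = dist$int_matrix,
       # minus strand: score the reverse complement of the window, i.e. the
       # row-reversed, base-complemented matrix applied at the same offset
       S_rc = S[w:1, 4:1, drop = FALSE],
       S_int_rc = dist$int_matrix[w:1, 4:1, drop = FALSE],
       dist = dist)
}

scan_codes_one_strand <- function(codes0, bad, S_bits, S_int, n_off) {
  w <- nrow(S_int)
  tot_int <- integer(n_off)
  tot_bits <- numeric(n_off)
  for (i in seq_len(w)) {
    idx <- codes0[i:(i + n_off - 1)]
    tot_int <- tot_int + S_int[i, idx]
    tot_bits <- tot_bits + S_bits[i, idx]
  }
  tot_int[bad] <- NA_integer_
  tot_bits[bad] <- NA_real_
  list(int = tot_int, bits = tot_bits)
}

empty_hits <- function() {
  data.frame(motif_id = character(), peak_id = character(),
             offset = integer(), strand = character(),
             score = numeric(), pvalue = numeric(), stringsAsFactors = FALSE)
}

#' Scan one sequence with one PWM on both strands
#'
#' Every window of motif width on the forward and reverse strand is scored
#' with the regularised log-odds matrix; an occurrence is reported when its
#' exact background p-value is at or below `config$alpha`.  Windows
#' containing `N` (or any non-ACGT character) are skipped.  Offsets are
#' 0-based positions of the window's leftmost base on the forward strand,
#' for both strands.
#'
#' @param sequence DNA string over A,C,G,T,N.
#' @param x A [pwm()] object.
#' @param config A [scan_config()].
#' @param peak_id Identifier recorded in the hits (default `"seq"`).
#' @param scorer Optional precomputed [motif_scorer()] (internal reuse).
#' @return Data frame of hits: `motif_id`, `peak_id`, `offset`, `strand`,
#'   `score` (bits), `pvalue`, sorted by `(offset, strand)`.
#' @export
scan_peak <- function(sequence, x, config = scan_config(), peak_id = "seq",
                      scorer = NULL) {
  if (is.null(scorer)) scorer <- motif_scorer(x, config)
  w <- scorer$width
  codes <- encode_dna(sequence)
  L <- length(codes)
  if (L < w) return(empty_hits())
  n_off <- L - w + 1L
  isna <- is.na(codes)
  if (any(isna)) {
    cs <- c(0L, cumsum(isna))
    bad <- (cs[(w + 1):(L + 1)] - cs[1:n_off]) > 0L
  } else {
    bad <- logical(n_off)
  }
  codes0 <- codes
  codes0[isna] <- 1L
  fwd <- scan_codes_one_strand(codes0, bad, scorer$S, scorer$S_int, n_off)
  rvs <- scan_codes_one_strand(codes0, bad, scorer$S_rc, scorer$S_int_rc, n_off)
  res <- list()
  for (str in c("+", "-")) {
    sc <- if (str == "+") fwd else rvs
    ok <- !is.na(sc$int)
    if (!any(ok)) next
    pv <- score_pvalue(scorer$dist, sc$int[ok], integer_score = TRUE)
    keep <- pv <= config$alpha
    if (!any(keep)) next
    res[[str]] <- data.frame(motif_id = scorer$motif_id, peak_id = peak_id,
                             offset = (which(ok)[keep]) - 1L, strand = str,
                             score = sc$bits[ok][keep], pvalue = pv[keep],
                             stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_hits())
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan all peaks of a genome with a motif library
#'
#' Extracts each peak's sequence from the genome and runs [scan_peak()] for
#' every motif.  Output order is deterministic: peak file order, then motif
#' order.
#'
#' @param peaks Data frame from [read_peaks()].
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param motifs List of [pwm()] objects (e.g. from [read_meme_motifs()]).
#' @param config A [scan_config()].
#' @return Data frame of hits as in [scan_peak()].
#' @export
scan_all <- function(peaks, genome, motifs, config = scan_config()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    stop(sprintf("peak chromosomes absent from genome: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  over <- peaks$end > lens[peaks$chrom]
  if (any(over)) {
    stop(sprintf("peak '%s' extends past the end of %s",
                 peaks$peak_id[over][1], peaks$chrom[over][1]), call. = FALSE)
  }
  scorers <- lapply(motifs, motif_scorer, config = config)
  chrom_str <- stats::setNames(as.character(genome), names(genome))
  out <- vector("list", nrow(peaks) * length(scorers))
  k <- 0L
  for (p in seq_len(nrow(peaks))) {
    seq_p <- substring(chrom_str[[peaks$chrom[p]]], peaks$start[p] + 1L,
                       peaks$end[p])
    for (m in seq_along(scorers)) {
      k <- k + 1L
      out[[k]] <- scan_peak(seq_p, NULL, config, peak_id = peaks$peak_id[p],
                            scorer = scorers[[m]])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_hits()
  rownames(res) <- NULL
  res
}
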