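#' Construct a position weight matrix object
#'
#' A PWM holds per-position base probabilities over the alphabet A,C,G,T for
#' one DNA-binding motif, together with the transcription factor name(s) the
#' motif is attributed to (a dimer motif such as `TFA::TFB` carries both).
#'
#' @param motif_id Motif identifier.
#' @param tf_names Character vector (length >= 1) of TF symbols.
#' @param prob Numeric `w x 4` matrix of probabilities; each row must sum to
#'   1 within `1e-6` (rows are renormalised to sum exactly 1).
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(motif_id, tf_names, prob) {
  stopifnot(is.character(motif_id), length(motif_id) == 1)
  stopifnot(is.character(tf_names), length(tf_names) >= 1)
  prob <- as.matrix(prob)
  if (ncol(prob) != 4 || nrow(prob) < 1) {
    stop("PWM probability matrix must be w x 4 with w >= 1", call. = FALSE)
  }
  if (any(prob < 0)) stop("PWM probabilities must be non-negative", call. = FALSE)
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-6)) {
    stop(sprintf("PWM '%s': row %d sums to %.6f, not 1",
                 motif_id, which(abs(rs - 1) > 1e-6)[1], rs[abs(rs - 1) > 1e-6][1]),
         call. = FALSE)
  }
  prob <- prob / rs
  colnames(prob) <- DNA_BASES
  rownames(prob) <- NULL
  structure(list(motif_id = motif_id, tf_names = tf_names, prob = prob),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (TFs: %s), width %d\n",
              x$motif_id, paste(x$tf_names, collapse = ", "), nrow(x$prob)))
  print(round(x$prob, 3))
  invisible(x)
}

#' Width of a PWM
#' @param x A [pwm()] object.
#' @return Integer motif width.
#' @export
pwm_width <- function(x) nrow(x$prob)

#' Consensus sequence of a PWM
#' @param x A [pwm()] object.
#' @return The most probable base at each position, as a string (ties broken
#'   in favour of the alphabetically first base).
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$prob, 1, which.max)], collapse = "")
}

# TF symbols from a MEME motif name: prefer the alternate name when present,
# strip a database-style suffix after the first "_" (e.g. "STAT1_HUMAN" ->
# "STAT1"), and split heterodimer names on "::" so each partner receives the
# motif's hits.
motif_name_to_tfs <- function(primary, alternate = NA_character_) {
  nm <- if (!is.na(alternate) && nzchar(alternate)) alternate else primary
  nm <- sub("_.*$", "", nm)
  tfs <- strsplit(nm, "::", fixed = TRUE)[[1]]
  tfs[nzchar(tfs)]
}

#' Read a motif library in MEME minimal motif format
#'
#' Parses the MEME suite's minimal text format: a `MEME version` line, an
#' `ALPHABET= ACGT` line, optional background frequencies, and one or more
#' `MOTIF` blocks each followed by a `letter-probability matrix:` header and
#' `w` rows of 4 probabilities.
#'
#' @param path Path to the `.meme` file.
#' @return A list of [pwm()] objects.  The file-level background frequencies,
#'   when present, are attached as attribute `"background"`.
#' @details The motif's alternate name (or, failing that, its primary id) is
#'   taken as the TF symbol; `"::"`-joined dimer names are split into
#'   multiple TFs and an underscore-delimited database suffix is stripped.
#'   A matrix row whose sum deviates from 1 by more than `1e-3` is rejected;
#'   rows within tolerance are renormalised.  Alphabets other than ACGT are
#'   rejected.
#' @export
read_meme_motifs <- function(path) {
  lines <- read_nonempty_lines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop(sprintf("%s: missing 'MEME version' header", path), call. = FALSE)
  }
  alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha_line) >= 1) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT") {
      stop(sprintf("%s: unsupported alphabet '%s' (only ACGT)", path, alpha),
           call. = FALSE)
    }
  }
  background <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    if (length(toks) == 8) {
      bg <- as.numeric(toks[c(2, 4, 6, 8)])
      if (!any(is.na(bg))) background <- stats::setNames(bg, DNA_BASES)
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) {
    stop(sprintf("%s: no MOTIF blocks found", path), call. = FALSE)
  }
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    at <- motif_at[k]
    toks <- strsplit(trimws(lines[at]), "\\s+")[[1]]
    if (length(toks) < 2) stop_io(path, at, "MOTIF line has no identifier")
    motif_id <- toks[2]
    alternate <- if (length(toks) >= 3) toks[3] else NA_character_
    block_end <- if (k < length(motif_at)) motif_at[k + 1] - 1 else length(lines)
    hdr_rel <- grep("^letter-probability matrix", lines[at:block_end])
    if (length(hdr_rel) == 0) {
      stop_io(path, at, sprintf("motif '%s' has no letter-probability matrix", motif_id))
    }
    hdr <- at + hdr_rel[1] - 1
    wm <- regmatches(lines[hdr], regexpr("w=\\s*[0-9]+", lines[hdr]))
    if (length(wm) == 0) stop_io(path, hdr, "matrix header does not state w=")
    w <- as.integer(sub("w=\\s*", "", wm))
    if (w < 1) stop_io(path, hdr, "motif width must be >= 1")
    if (hdr + w > length(lines)) stop_io(path, hdr, "truncated probability matrix")
    mat <- matrix(NA_real_, nrow = w, ncol = 4)
    for (i in seq_len(w)) {
      row <- suppressWarnings(as.numeric(strsplit(trimws(lines[hdr + i]), "\\s+")[[1]]))
      if (length(row) != 4 || any(is.na(row))) {
        stop_io(path, hdr + i, "expected 4 numeric probabilities")
      }
      if (any(row < 0)) stop_io(path, hdr + i, "negative probability")
      if (abs(sum(row) - 1) > 1e-3) {
        stop_io(path, hdr + i, sprintf("row sums to %.6f (tolerance 1e-3)", sum(row)))
      }
      mat[i, ] <- row / sum(row)
    }
    motifs[[k]] <- pwm(motif_id, motif_name_to_tfs(motif_id, alternate), mat)
  }
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate motif id '%s'", path, ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  names(motifs) <- ids
  attr(motifs, "background") <- background
  motifs
}

#' Write a motif library in MEME minimal motif format
#'
#' @param motifs List of [pwm()] objects.
#' @param path Output path.
#' @param background Optional length-4 background frequency vector (A,C,G,T).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", ""), con)
  if (!is.null(background)) {
    writeLines(c("Background letter frequencies",
                 sprintf("A %.6f C %.6f G %.6f T %.6f",
                         background[1], background[2], background[3], background[4]),
                 ""), con)
  }
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id, paste(m$tf_names, collapse = "::")), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", nrow(m$prob)), con)
    writeLines(apply(m$prob, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Motif-to-TF mapping from a motif library
#'
#' @param motifs List of [pwm()] objects.
#' @return Named list mapping each motif id to its character vector of TF
#'   symbols.
#' @export
motif_tf_map <- function(motifs) {
  stats::setNames(lapply(motifs, function(m) m$tf_names),
                  vapply(motifs, function(m) m$motif_id, character(1)))
}
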