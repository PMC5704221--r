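#' Read a gene annotation from a BED6 file
#'
#' Each line gives one gene: chrom, start, end, name, score, strand, with
#' 0-based half-open coordinates.  The transcription start site (TSS) is
#' derived from the strand: `start` for `+` genes and `end - 1` for `-`
#' genes.
#'
#' @param path Path to the BED6 file.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `start`, `end`, `tss`.  BED6 carries a single name, used as both
#'   `gene_id` and `symbol`.
#' @export
read_gene_annotation <- function(path) {
  lines <- read_nonempty_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") & !startsWith(lines, "track"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- length(keep)
  out <- data.frame(gene_id = character(n), symbol = character(n),
                    chrom = character(n), strand = character(n),
                    start = integer(n), end = integer(n), tss = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ln <- keep[i]
    f <- fields[[i]]
    if (length(f) < 6) stop_io(path, ln, sprintf("expected 6 BED fields, found %d", length(f)))
    start <- as_int_or_stop(f[2], path, ln, "start")
    end <- as_int_or_stop(f[3], path, ln, "end")
    if (start < 0) stop_io(path, ln, "negative start")
    if (start >= end) stop_io(path, ln, sprintf("start %d not less than end %d", start, end))
    if (!f[6] %in% c("+", "-")) stop_io(path, ln, sprintf("invalid strand '%s'", f[6]))
    out$gene_id[i] <- f[4]; out$symbol[i] <- f[4]
    out$chrom[i] <- f[1]; out$strand[i] <- f[6]
    out$start[i] <- start; out$end[i] <- end
    out$tss[i] <- if (f[6] == "+") start else end - 1L
  }
  if (anyDuplicated(out$gene_id)) {
    stop_io(path, keep[which(duplicated(out$gene_id))[1]],
            sprintf("duplicate gene_id '%s'", out$gene_id[duplicated(out$gene_id)][1]))
  }
  out
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#' Symbols are case-sensitive and must match the annotation's symbols.
#'
#' @param path Path to the file.
#' @return Character vector of unique symbols, in file order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(read_nonempty_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop(sprintf("%s: no gene symbols", path), call. = FALSE)
  unique(lines)
}

#' Read a gene-set library in GMT format
#'
#' Each tab-separated line is: set name, description, then member genes.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character vectors (unique members per set);
#'   descriptions attached as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- read_nonempty_lines(path)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  sets <- vector("list", length(keep))
  nms <- character(length(keep)); desc <- character(length(keep))
  for (i in seq_along(keep)) {
    f <- fields[[i]]
    if (length(f) < 3) stop_io(path, keep[i], "GMT line needs set name, description and >= 1 gene")
    nms[i] <- f[1]; desc[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
  }
  if (anyDuplicated(nms)) {
    stop_io(path, keep[which(duplicated(nms))[1]],
            sprintf("duplicate set name '%s'", nms[duplicated(nms)][1]))
  }
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(desc, nms)
  sets
}

#' Write a gene-set library in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  desc <- if (is.null(description)) stats::setNames(rep(".", length(sets)), names(sets)) else description
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% ".", sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an expression matrix with sample group labels
#'
#' The matrix file is TSV with a header row of sample ids and gene symbols in
#' the first column; values must be non-negative.  The labels file is a
#' two-column TSV (sample id, group name) covering every sample.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @return An object of class `"expression_matrix"`: a list with `values`
#'   (numeric matrix, genes x samples) and `groups` (named character vector,
#'   sample id -> group).
#' @export
read_expression <- function(path, labels_path) {
  lines <- read_nonempty_lines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) < 2) stop(sprintf("%s: fewer than 2 samples", path), call. = FALSE)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(genes)) {
    stop(sprintf("%s: duplicate gene symbol '%s'", path, genes[duplicated(genes)][1]),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (length(v) != length(samples) || any(is.na(v))) {
      stop_io(path, i + 1L, "row does not have one numeric value per sample")
    }
    vals[i, ] <- v
  }
  if (any(vals < 0)) stop(sprintf("%s: negative expression values", path), call. = FALSE)
  lab_lines <- read_nonempty_lines(labels_path)
  lab <- strsplit(lab_lines[nzchar(trimws(lab_lines))], "\t", fixed = TRUE)
  if (any(vapply(lab, length, integer(1)) < 2)) {
    stop(sprintf("%s: labels file needs two columns (sample, group)", labels_path),
         call. = FALSE)
  }
  groups <- stats::setNames(vapply(lab, `[`, character(1), 2),
                            vapply(lab, `[`, character(1), 1))
  expression_matrix(vals, groups)
}

#' Construct an expression matrix object
#' @param values Non-negative numeric matrix, genes (rows) x samples (cols).
#' @param groups Named character vector mapping every sample id to a group.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0) {
    stop(sprintf("samples without a group label: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  groups <- groups[colnames(values)]
  if (length(unique(groups)) < 2) stop("need >= 2 sample groups", call. = FALSE)
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix and its group labels
#' @param expr An [expression_matrix()] object.
#' @param path Output path for the matrix TSV (first column `gene`).
#' @param labels_path Output path for the two-column labels TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, labels_path) {
  con <- file(path, open = "wb")
  writeLines(paste(c("gene", colnames(expr$values)), collapse = "\t"), con)
  rows <- apply(expr$values, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(expr$values), rows, sep = "\t"), con)
  close(con)
  con <- file(labels_path, open = "wb")
  writeLines(paste(names(expr$groups), expr$groups, sep = "\t"), con)
  close(con)
  invisible(path)
}
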