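# Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (C collation) ordering so written files are byte-stable
# across machines regardless of LC_COLLATE.
order_c <- function(...) order(..., method = "radix")

sort_c <- function(x) x[order(x, method = "radix")]

# Full-precision decimal rendering of a double; round-trips through
# as.numeric() exactly.
fmt_num <- function(x) sprintf("%.17g", x)

stop_io <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); any other character
# (including N) becomes NA.  Case-insensitive.
encode_dna <- function(seq) {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  codes <- utf8ToInt(seq)
  if (any(codes > 127L)) stop("non-ASCII character in DNA sequence", call. = FALSE)
  lut[codes]
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop(sprintf("%s: file is empty", path), call. = FALSE)
  }
  lines
}

as_int_or_stop <- function(x, path, line, what) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v))) stop_io(path, line, sprintf("%s is not an integer: '%s'", what, x))
  v
}

write_tsv_file <- function(df, path) {
  # deterministic, unquoted TSV with header; numeric columns at full precision
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}
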