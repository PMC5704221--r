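#' Read accessibility peaks from a BED3 or narrowPeak file
#'
#' Parses peak intervals from an ATAC-seq/DNase-seq peak file.  All
#' coordinates are 0-based half-open, as in BED.  For narrowPeak input the
#' tenth column (summit offset from the peak start) is kept; a value of -1
#' means "no summit" and is stored as `NA`.
#'
#' @param path Path to the peak file.
#' @param dialect Either `"bed3"` (>= 3 tab-separated columns; column 4, when
#'   present, is used as the peak id) or `"narrowPeak"` (>= 10 columns).
#' @return A data frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `summit_offset` (integer, `NA` when absent), one row per peak, in file
#'   order.  Peaks without a name get the id `"<chrom>:<start>-<end>"`.
#' @details Malformed coordinates (`start >= end`, negative values) and
#'   duplicate peak ids are rejected with an error naming the offending line.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t400\t650\tpk2"), f)
#' read_peaks(f, "bed3")
#' @export
read_peaks <- function(path, dialect = c("bed3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  lines <- read_nonempty_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") & !startsWith(lines, "track")
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  min_cols <- if (dialect == "bed3") 3L else 10L
  n <- length(idx)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  peak_id <- character(n); summit <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ln <- idx[i]
    f <- fields[[i]]
    if (length(f) < min_cols) {
      stop_io(path, ln, sprintf("expected >= %d tab-separated fields, found %d",
                                min_cols, length(f)))
    }
    chrom[i] <- f[1]
    start[i] <- as_int_or_stop(f[2], path, ln, "start")
    end[i]   <- as_int_or_stop(f[3], path, ln, "end")
    if (start[i] < 0) stop_io(path, ln, sprintf("negative start %d", start[i]))
    if (start[i] >= end[i]) {
      stop_io(path, ln, sprintf("start %d is not less than end %d", start[i], end[i]))
    }
    peak_id[i] <- if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") {
      f[4]
    } else {
      sprintf("%s:%d-%d", chrom[i], start[i], end[i])
    }
    if (dialect == "narrowPeak") {
      s <- as_int_or_stop(f[10], path, ln, "summit offset")
      if (s != -1L) {
        if (s < 0 || s >= end[i] - start[i]) {
          stop_io(path, ln, sprintf("summit offset %d outside peak of width %d",
                                    s, end[i] - start[i]))
        }
        summit[i] <- s
      }
    }
  }
  dup <- duplicated(peak_id)
  if (any(dup)) {
    stop_io(path, idx[which(dup)[1]],
            sprintf("duplicate peak_id '%s'", peak_id[which(dup)[1]]))
  }
  data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
             summit_offset = summit, stringsAsFactors = FALSE)
}

#' Write peaks as a narrowPeak file
#'
#' Inverse of [read_peaks()] for the narrowPeak dialect.  Score/signal/p/q
#' columns are written as placeholder values (0, 0, -1, -1); a missing summit
#' is written as -1.
#'
#' @param peaks Data frame as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t0\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id, summit)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
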