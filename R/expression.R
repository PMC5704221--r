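#' Differentially modulated genes between two sample groups
#'
#' Per-gene two-group test on (optionally log-transformed) expression,
#' selecting genes below a p-value threshold — the screen behind a
#' "significantly modulated genes" heatmap.  The default test is Welch's
#' two-sided t-test on `log2(x + 1)` values; a Mann-Whitney alternative is
#' available.  Genes with zero variance in both groups cannot be tested:
#' their p-value is set to 1 and they are flagged.
#'
#' @param expr An [expression_matrix()] object.
#' @param group_a,group_b Group labels to compare; each must have >= 2
#'   samples.
#' @param threshold Selection threshold on the raw p-value (default 0.01).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return An object of class `"modulated_genes"`: list with `table` (data
#'   frame `gene`, `mean_a`, `mean_b`, `statistic`, `pvalue`, `selected`,
#'   `degenerate`) and `zmatrix` (selected genes x all samples of the two
#'   groups, each row z-scored to mean 0 / sd 1 for heatmap export).
#' @export
modulated_genes <- function(expr, group_a, group_b, threshold = 0.01,
                            transform = c("log2p1", "none"),
                            test = c("welch", "wilcoxon")) {
  stopifnot(inherits(expr, "expression_matrix"))
  transform <- match.arg(transform)
  test <- match.arg(test)
  ia <- which(expr$groups == group_a)
  ib <- which(expr$groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  x <- expr$values[, c(ia, ib), drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  a_cols <- seq_along(ia)
  b_cols <- length(ia) + seq_along(ib)
  ng <- nrow(x)
  stat <- pv <- rep(NA_real_, ng)
  degen <- logical(ng)
  for (i in seq_len(ng)) {
    va <- x[i, a_cols]; vb <- x[i, b_cols]
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      degen[i] <- TRUE
      stat[i] <- 0
      pv[i] <- 1
    } else if (test == "welch") {
      tt <- stats::t.test(va, vb, var.equal = FALSE)
      stat[i] <- unname(tt$statistic)
      pv[i] <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
      stat[i] <- unname(wt$statistic)
      pv[i] <- wt$p.value
    }
  }
  selected <- pv < threshold
  tab <- data.frame(gene = rownames(x),
                    mean_a = rowMeans(x[, a_cols, drop = FALSE]),
                    mean_b = rowMeans(x[, b_cols, drop = FALSE]),
                    statistic = stat, pvalue = pv,
                    selected = selected, degenerate = degen,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  zm <- x[selected, , drop = FALSE]
  if (nrow(zm) > 0) {
    mu <- rowMeans(zm)
    sd <- apply(zm, 1, stats::sd)
    ok <- sd > 0
    zm[ok, ] <- (zm[ok, , drop = FALSE] - mu[ok]) / sd[ok]
    zm[!ok, ] <- 0
  }
  structure(list(table = tab, zmatrix = zm,
                 group_a = group_a, group_b = group_b,
                 threshold = threshold, transform = transform, test = test),
            class = "modulated_genes")
}

#' @export
print.modulated_genes <- function(x, ...) {
  cat(sprintf("modulated_genes: %d / %d genes with p < %g (%s on %s vs %s)\n",
              sum(x$table$selected), nrow(x$table), x$threshold, x$test,
              x$group_a, x$group_b))
  invisible(x)
}
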