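test_that("hypergeometric p-values match combinatorial enumeration", {
  # N=10, K=5, n=4, k=4: p = C(5,4) C(5,0) / C(10,4)
  uni <- paste0("u", 1:10)
  set5 <- uni[1:5]
  query <- uni[1:4]
  res <- hypergeom_enrich(query, list(s = set5), uni)
  expect_equal(res$pvalue, choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(res$overlap, 4L)
  # small grid against the brute-force tail
  set.seed(61)
  for (trial in 1:25) {
    N <- sample(5:20, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    uni <- paste0("g", 1:N)
    lib <- list(s = sample(uni, K))
    q <- sample(uni, n)
    k <- length(intersect(lib$s, q))
    expect_equal(hypergeom_enrich(q, lib, uni)$pvalue,
                 bf_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("hypergeometric boundary cases behave", {
  uni <- paste0("g", 1:12)
  lib <- list(a = uni[1:4], b = uni[5:12])
  # query = universe draws everything: k = K and p = 1
  res <- hypergeom_enrich(uni, lib, uni)
  expect_equal(res$pvalue, c(1, 1))
  expect_equal(res$overlap[res$set_name == "a"], 4L)
  # k = 0 tail completeness: P(X >= 0) = 1
  res0 <- hypergeom_enrich(uni[5:6], list(a = uni[1:4]), uni)
  expect_lte(res0$pvalue, 1)
  expect_equal(hypergeom_enrich(uni[1], list(whole = uni), uni)$pvalue, 1)
  # set members outside the universe are dropped before testing
  res2 <- hypergeom_enrich(uni[1:2], list(a = c(uni[1:4], "alien")), uni)
  expect_equal(res2$set_size, 4L)
  expect_error(hypergeom_enrich(character(), lib, uni), "empty query")
  expect_error(hypergeom_enrich(uni[1], lib, character()), "empty universe")
  expect_error(hypergeom_enrich("alien", lib, uni), "outside the universe")
})

test_that("BH adjustment is monotone over the p-value-sorted results", {
  set.seed(62)
  uni <- paste0("g", 1:50)
  lib <- lapply(stats::setNames(1:12, paste0("s", 1:12)),
                function(i) sample(uni, sample(3:20, 1)))
  res <- hypergeom_enrich(sample(uni, 15), lib, uni)
  expect_true(all(diff(res$pvalue) >= 0))
  expect_true(all(diff(res$bh_adjusted) >= 0))
  expect_true(all(res$bh_adjusted >= res$pvalue))
  expect_equal(res$bh_adjusted, stats::p.adjust(res$pvalue, "BH"))
})

null_expr <- function(ng, n_per_group = 5) {
  simulate_expression(paste0("g", seq_len(ng)), character(),
                      n_per_group = n_per_group, sd = 0.25)
}

test_that("identical group distributions are never selected", {
  vals <- matrix(rep(c(3, 5, 8, 2, 6), 2), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:10)))
  # group B holds a permutation of the same values
  vals[1, 6:10] <- vals[1, c(3, 1, 5, 2, 4)]
  expr <- expression_matrix(vals, stats::setNames(rep(c("a", "b"), each = 5),
                                                  colnames(vals)))
  m <- modulated_genes(expr, "a", "b")
  expect_false(m$table$selected)
  expect_equal(m$table$statistic, 0)
})

test_that("constant genes are flagged degenerate with p = 1", {
  vals <- rbind(g1 = rep(5, 10), g2 = c(rnorm(5, 100, 5), rnorm(5, 2, 0.5)))
  colnames(vals) <- paste0("s", 1:10)
  vals <- pmax(vals, 0)
  expr <- expression_matrix(vals, stats::setNames(rep(c("a", "b"), each = 5),
                                                  colnames(vals)))
  m <- modulated_genes(expr, "a", "b")
  expect_true(m$table$degenerate[1])
  expect_equal(m$table$pvalue[1], 1)
  expect_false(m$table$selected[1])
  expect_true(m$table$selected[2])
})

test_that("down-shifted receptors are selected and z-rows are standardised", {
  set.seed(63)
  expr <- simulate_expression(paste0("g", 1:300), down_genes = paste0("g", 1:5),
                              n_per_group = 5, lfc = 2, sd = 0.25)
  m <- modulated_genes(expr, "blood", "tumor", threshold = 0.01)
  expect_true(all(m$table$selected[m$table$gene %in% paste0("g", 1:5)]))
  expect_true(all(m$table$selected == (m$table$pvalue < 0.01)))
  expect_gt(nrow(m$zmatrix), 0)
  expect_equal(unname(rowMeans(m$zmatrix)), rep(0, nrow(m$zmatrix)), tolerance = 1e-6)
  expect_equal(unname(apply(m$zmatrix, 1, stats::sd)), rep(1, nrow(m$zmatrix)),
               tolerance = 1e-6)
  # the wilcoxon alternative runs and also flags strong shifts
  mw <- modulated_genes(expr, "blood", "tumor", test = "wilcoxon", threshold = 0.05)
  expect_true(all(mw$table$selected[mw$table$gene %in% paste0("g", 1:5)]))
})

test_that("the type-I error of the screen is near the nominal threshold", {
  set.seed(64)
  expr <- null_expr(2000)
  m <- modulated_genes(expr, "blood", "tumor", threshold = 0.01)
  frac <- mean(m$table$selected)
  se <- sqrt(0.01 * 0.99 / 2000)
  expect_lt(abs(frac - 0.01), 4 * se)
})
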