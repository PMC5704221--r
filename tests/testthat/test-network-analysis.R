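edges_df <- function(tfs, genes) {
  data.frame(tf = tfs, gene = genes, n_peaks = 1L, best_pvalue = 1e-5,
             evidence = "p|M|+|0|1e-05", stringsAsFactors = FALSE)
}

test_that("out-degree ranking counts distinct targets with lexicographic ties", {
  g <- grn(edges_df(c("T1", "T1", "T2"), c("g1", "g2", "g1")))
  r <- rank_regulators_by_outdegree(g)
  expect_equal(r$tf_name, c("T1", "T2"))
  expect_equal(r$score, c(2, 1))
  # all-tied scores fall back to lexicographic order
  g2 <- grn(edges_df(c("Tc", "Ta", "Tb"), c("g1", "g2", "g3")))
  expect_equal(rank_regulators_by_outdegree(g2)$tf_name, c("Ta", "Tb", "Tc"))
  # k truncates
  expect_equal(nrow(rank_regulators_by_outdegree(g2, k = 2)), 2L)
})

test_that("out-degree ranking matches a brute-force degree census", {
  set.seed(51)
  for (trial in 1:10) {
    g <- random_grn(8, 20, 40)
    r <- rank_regulators_by_outdegree(g, k = 100)
    census <- table(unique(g$edges)[, c("tf", "gene")]$tf)
    expect_equal(nrow(r), length(census))
    for (i in seq_len(nrow(r))) {
      expect_equal(r$score[i], as.numeric(census[[r$tf_name[i]]]))
    }
    expect_true(all(diff(r$score) <= 0))
  }
})

test_that("PageRank on an edgeless network is the uniform teleport fixed point", {
  g <- grn(NULL, isolated = paste0("n", 1:7))
  s <- pagerank_scores(g)
  expect_equal(unname(as.numeric(s)), rep(1 / 7, 7))
  expect_true(attr(s, "converged"))
})

test_that("PageRank matches a dense linear solve, with dangling nodes", {
  set.seed(52)
  for (trial in 1:8) {
    g <- random_grn(10, 15, sample(10:40, 1), allow_overlap_names = TRUE)
    for (reverse in c(TRUE, FALSE)) {
      s <- pagerank_scores(g, reverse = reverse)
      expect_equal(sum(s), 1, tolerance = 1e-9)
      nm <- g$nodes$name
      src <- match(if (reverse) g$edges$gene else g$edges$tf, nm)
      dst <- match(if (reverse) g$edges$tf else g$edges$gene, nm)
      oracle <- dense_pagerank(nm, src, dst, damping = 0.85)
      expect_lt(max(abs(as.numeric(s) - unname(oracle[names(s)]))), 1e-8)
    }
  }
})

test_that("PageRank ranking restricts to TFs and mirrors the score order", {
  set.seed(53)
  g <- random_grn(6, 12, 25)
  r <- rank_regulators_by_pagerank(g, k = 100)
  expect_setequal(r$tf_name, g$nodes$name[g$nodes$is_tf])
  expect_true(all(diff(r$score) <= 0))
  s <- pagerank_scores(g)
  expect_equal(r$score, unname(as.numeric(s[r$tf_name])))
})

test_that("network intersections tabulate presence patterns and uniques", {
  ga <- grn(edges_df("T", c("a", "b")))
  gb <- grn(edges_df("T", c("b", "c")))
  ix <- intersect_networks(list(A = ga, B = gb), element = "genes")
  expect_equal(unname(ix$unique), c(1L, 1L))
  both <- ix$table[ix$table$signature == "A&B", ]
  expect_equal(both$members, "b")
  # identical networks put everything in the full intersection
  ix2 <- intersect_networks(list(X = ga, Y = ga), element = "genes")
  expect_equal(ix2$table$signature, "X&Y")
  expect_equal(ix2$table$count, 2L)
  expect_equal(unname(ix2$unique), c(0L, 0L))
})

test_that("signature counts equal per-element pattern enumeration", {
  set.seed(54)
  for (trial in 1:5) {
    gs <- list(A = random_grn(6, 15, 25), B = random_grn(6, 15, 25),
               C = random_grn(6, 15, 25))
    for (el in c("genes", "tfs")) {
      ix <- intersect_networks(gs, element = el)
      sets <- lapply(gs, function(g) {
        if (el == "genes") g$nodes$name[g$nodes$is_gene] else g$nodes$name[g$nodes$is_tf]
      })
      elements <- unique(unlist(sets))
      sig_of <- vapply(elements, function(e) {
        paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
              collapse = "&")
      }, character(1))
      bf <- table(sig_of)
      expect_equal(nrow(ix$table), length(bf))
      for (i in seq_len(nrow(ix$table))) {
        expect_equal(ix$table$count[i], as.integer(bf[[ix$table$signature[i]]]))
      }
    }
  }
})

test_that("receptor subnetworks keep only regulated receptors and their TFs", {
  g <- grn(edges_df(c("T1", "T2", "T3"), c("r", "r", "g")), receptors = "r")
  sub <- receptor_subnetwork(g)
  expect_equal(sub$edges$tf, c("T1", "T2"))
  expect_equal(unique(sub$edges$gene), "r")
  expect_false("T3" %in% sub$nodes$name)
  # idempotence
  expect_identical(receptor_subnetwork(sub), sub)
  # no regulated receptors -> empty network
  g2 <- grn(edges_df("T1", "g1"), receptors = "r")
  expect_equal(nrow(receptor_subnetwork(g2)$edges), 0L)
})

test_that("diff_network computes exact set differences and lost receptors", {
  a <- grn(edges_df(c("T1", "T1"), c("g1", "r")), receptors = "r")
  b <- grn(edges_df("T1", "g1"), receptors = "r")
  d <- diff_network(a, b)
  expect_equal(d$edges_lost$gene, "r")
  expect_equal(nrow(d$edges_gained), 0L)
  expect_equal(d$receptors_lost$receptor, "r")
  expect_equal(d$receptors_lost$n_regulators_a, 1L)
  expect_equal(d$nodes_lost, "r")
  # identity comparison is empty
  d0 <- diff_network(a, a)
  expect_equal(nrow(d0$edges_lost) + nrow(d0$edges_gained) +
                 length(d0$nodes_lost) + length(d0$nodes_gained) +
                 nrow(d0$receptors_lost), 0L)
})

test_that("diff_network is anti-symmetric under swapping the conditions", {
  set.seed(55)
  for (trial in 1:5) {
    a <- random_grn(6, 15, 30, receptors = c("g1", "g2", "g3"))
    b <- random_grn(6, 15, 30, receptors = c("g1", "g2", "g3"))
    d_ab <- diff_network(a, b)
    d_ba <- diff_network(b, a)
    expect_identical(d_ab$edges_lost, d_ba$edges_gained)
    expect_identical(d_ab$edges_gained, d_ba$edges_lost)
    expect_identical(d_ab$nodes_lost, d_ba$nodes_gained)
  }
})

test_that("a receptor still regulated in B is not counted as lost", {
  a <- grn(edges_df(c("T1", "T2"), c("r", "r")), receptors = "r")
  b <- grn(edges_df("T2", "r"), receptors = "r")
  d <- diff_network(a, b)
  expect_equal(nrow(d$receptors_lost), 0L)
  expect_equal(d$edges_lost$tf, "T1")
})

test_that("diff_receptor_network is the lost receptor wiring of condition A", {
  a <- grn(edges_df(c("T1", "T2", "T3"), c("r1", "r1", "g")),
           receptors = c("r1", "r2"))
  b <- grn(edges_df("T2", "r1"), receptors = c("r1", "r2"))
  d <- diff_receptor_network(a, b)
  expect_equal(d$edges$tf, "T1")
  expect_equal(d$edges$gene, "r1")
  # comparing a network against itself leaves nothing
  expect_equal(nrow(diff_receptor_network(a, a)$edges), 0L)
})
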