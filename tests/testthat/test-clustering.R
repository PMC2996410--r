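test_that("euclidean_distances equals sqrt of the Hamming count", {
  m <- rbind(t1 = c(1, 0, 0), t2 = c(0, 1, 0), t3 = c(1, 0, 0))
  colnames(m) <- c("g1", "g2", "g3")
  D <- euclidean_distances(m)
  expect_equal(D["t1", "t2"], sqrt(2))
  expect_equal(D["t1", "t3"], 0)
  expect_error(euclidean_distances(m[1, , drop = FALSE]), "at least 2")

  set.seed(81)
  for (k in 1:10) {
    b <- random_binary_matrix(6, 20)
    D <- euclidean_distances(b)
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(D[i, j], sqrt(oracle_hamming(b[i, ], b[j, ])),
                   tolerance = 0)
  }
})

test_that("euclidean_distances satisfies the metric axioms", {
  set.seed(82)
  for (k in 1:10) {
    m <- matrix(rnorm(7 * 5), 7, 5,
                dimnames = list(sprintf("t%d", 1:7), NULL))
    D <- euclidean_distances(m)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 7))
    for (i in 1:7) for (j in 1:7) for (l in 1:7)
      expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-12)
  }
})

test_that("agglomerative_cluster handles forced and unambiguous merges", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  for (lk in c("single", "complete", "average", "ward")) {
    d <- agglomerative_cluster(D2, lk)
    expect_equal(d$height, 3)
  }
  D3 <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- agglomerative_cluster(D3, "complete")
  expect_equal(d$height, c(1, 5))
  expect_equal(pkg_merge_steps(d)[[1]]$union, "A\rB")
  bad <- D3; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(agglomerative_cluster(bad, "complete"), "NA/NaN")
  bad2 <- D3; bad2[1, 2] <- bad2[2, 1] <- -1
  expect_error(agglomerative_cluster(bad2, "complete"), "non-negative")
})

test_that("merge sequences match the naive oracle for all linkages", {
  set.seed(83)
  for (k in 1:20) {
    D <- random_euclidean_dist(sample(3:8, 1))
    for (lk in c("single", "complete", "average", "ward")) {
      d <- agglomerative_cluster(D, lk)
      got <- pkg_merge_steps(d)
      want <- oracle_agglomerate(D, lk)
      for (s in seq_along(want)) {
        expect_identical(got[[s]]$union, want[[s]]$union)
        expect_identical(got[[s]]$children, want[[s]]$children)
        expect_equal(got[[s]]$height, want[[s]]$height, tolerance = 1e-9)
      }
    }
  }
})

test_that("clustering agrees with stats::hclust on tie-free matrices", {
  set.seed(84)
  for (k in 1:10) {
    D <- random_euclidean_dist(sample(4:10, 1))
    for (lk in c("single", "complete", "average", "ward")) {
      d <- agglomerative_cluster(D, lk)
      hc <- stats::hclust(stats::as.dist(D),
                          method = if (lk == "ward") "ward.D2" else lk)
      expect_equal(sort(d$height), sort(hc$height), tolerance = 1e-8)
      expect_equal(stats::cophenetic(stats::as.hclust(d)),
                   stats::cophenetic(hc), tolerance = 1e-8)
    }
  }
})

test_that("monotone linkages give monotone heights; order invariance holds", {
  set.seed(85)
  for (k in 1:10) {
    D <- random_euclidean_dist(7)
    for (lk in c("single", "complete", "average")) {
      d <- agglomerative_cluster(D, lk)
      expect_true(all(diff(d$height) >= -1e-12))
    }
    # permuting taxa yields the same merges and heights
    perm <- sample(7)
    Dp <- D[perm, perm]
    for (lk in c("complete", "average")) {
      a <- pkg_merge_steps(agglomerative_cluster(D, lk))
      b <- pkg_merge_steps(agglomerative_cluster(Dp, lk))
      expect_equal(vapply(a, `[[`, character(1), "union"),
                   vapply(b, `[[`, character(1), "union"))
      expect_equal(vapply(a, `[[`, numeric(1), "height"),
                   vapply(b, `[[`, numeric(1), "height"), tolerance = 1e-12)
    }
  }
})

test_that("a duplicated taxon merges first with its twin at height 0", {
  set.seed(86)
  m <- random_binary_matrix(5, 12)
  m <- rbind(m, twin = m["t1", ])
  D <- euclidean_distances(m)
  d <- agglomerative_cluster(D, "complete")
  expect_equal(d$height[1], 0)
  expect_identical(pkg_merge_steps(d)[[1]]$union, "t1\rtwin")
})

test_that("to_newick follows the edge-length convention and round-trips", {
  D2 <- matrix(c(0, 1.414, 1.414, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  d <- agglomerative_cluster(D2, "complete")
  expect_identical(to_newick(d, precision = 3), "(A:1.414,B:1.414);")

  set.seed(87)
  D <- random_euclidean_dist(8)
  d <- agglomerative_cluster(D, "average")
  nwk <- to_newick(d, precision = 6)
  expect_identical(substr(nwk, nchar(nwk), nchar(nwk)), ";")
  n_open <- lengths(regmatches(nwk, gregexpr("(", nwk, fixed = TRUE)))
  n_close <- lengths(regmatches(nwk, gregexpr(")", nwk, fixed = TRUE)))
  expect_equal(n_open, n_close)
  expect_equal(lengths(regmatches(nwk, gregexpr(";", nwk, fixed = TRUE))), 1L)
  # reparse: same leaves, same root-to-tip heights (= max merge height)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(D))
  depths <- ape::node.depth.edgelength(phy)[seq_len(8)]
  expect_equal(unname(depths), rep(max(d$height), 8), tolerance = 1e-5)
  # cophenetic distances survive the round trip (tree path = 2 * height)
  coph_tree <- ape::cophenetic.phylo(phy)[rownames(D), rownames(D)] / 2
  coph_dend <- as.matrix(stats::cophenetic(stats::as.hclust(d)))
  expect_equal(coph_tree, coph_dend[rownames(D), rownames(D)],
               tolerance = 1e-4)
  # reserved characters are quoted
  Dq <- D2; rownames(Dq) <- colnames(Dq) <- c("A x", "B(1)")
  nq <- to_newick(agglomerative_cluster(Dq, "single"), 3)
  expect_true(grepl("'A x'", nq, fixed = TRUE))
})

test_that("compare_clades flags monophyly and computes RF distances", {
  m <- rbind(a1 = c(1, 1, 0, 0), a2 = c(1, 1, 0, 1),
             b1 = c(0, 0, 1, 0), b2 = c(0, 0, 1, 1))
  colnames(m) <- sprintf("g%d", 1:4)
  d <- agglomerative_cluster(euclidean_distances(m), "complete")
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rec <- compare_clades(d, labels)
  expect_true(all(rec$monophyletic))
  expect_equal(rec$n_clades_recovered, 2L)
  # self-comparison: RF 0
  self <- compare_clades(d, labels, reference_tree = to_newick(d))
  expect_equal(self$rf, 0L)
  expect_error(compare_clades(d, labels[-1]), "missing leaf")
})

test_that("RF distance matches an independent bipartition comparison", {
  skip_if_not_installed("phangorn")
  set.seed(88)
  for (k in 1:12) {
    D <- random_euclidean_dist(8)
    d <- agglomerative_cluster(D, "average")
    ref <- ape::rtree(8, tip.label = sample(rownames(D)))
    labels <- setNames(rownames(D), rownames(D))  # every taxon its own clade
    rec <- compare_clades(d, labels, reference_tree = ref)
    want <- phangorn::RF.dist(ape::unroot(ape::as.phylo(stats::as.hclust(d))),
                              ape::unroot(ref))
    expect_equal(rec$rf, want)
  }
})

test_that("perfect clade structure is recovered with clade-level RF 0", {
  tr <- sample_tree(4, 3, seed = 89)
  truth <- evolve_content(tr, gain_loss_params(0.3, 0.3, 250, master_seed = 89))
  d <- agglomerative_cluster(euclidean_distances(truth$matrix), "complete")
  rec <- compare_clades(d, tr$clades, reference_tree = tr)
  expect_true(all(rec$monophyletic))
  expect_equal(rec$rf_clade, 0L)
})
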