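test_that("sample_tree builds valid clade-labelled trees", {
  tr <- sample_tree(1, 2, within_clade_depth = 1, between_clade_depth = 2,
                    seed = 1)
  expect_equal(length(tr$phy$tip.label), 2L)
  expect_equal(tr$phy$Nnode, 1L)

  tr4 <- sample_tree(4, 4, seed = 3)
  expect_equal(length(tr4$phy$tip.label), 16L)
  expect_false(anyDuplicated(tr4$phy$tip.label) > 0)
  expect_equal(length(tr4$clades), 16L)
  expect_equal(sort(unique(unname(tr4$clades))), sprintf("C%02d", 1:4))
  # ultrametric: every leaf at depth between_clade_depth
  depths <- ape::node.depth.edgelength(tr4$phy)[seq_len(16)]
  expect_equal(depths, rep(3.0, 16), tolerance = 1e-9)

  expect_identical(sample_tree(3, 2, seed = 7)$newick,
                   sample_tree(3, 2, seed = 7)$newick)
  expect_false(identical(sample_tree(3, 2, seed = 7)$newick,
                         sample_tree(3, 2, seed = 8)$newick))
  expect_error(sample_tree(0, 4), "positive")
  expect_error(sample_tree(2, 2, within_clade_depth = 3,
                           between_clade_depth = 1), "between_clade_depth")
})

test_that("evolve_content honors degenerate regimes", {
  tr <- sample_tree(2, 2, within_clade_depth = 0.5, between_clade_depth = 1,
                    seed = 2)
  # zero branch lengths: leaf state == root state everywhere
  tr0 <- tr
  tr0$phy$edge.length[] <- 0
  truth0 <- evolve_content(tr0, gain_loss_params(1, 1, 40, master_seed = 5))
  for (f in seq_len(ncol(truth0$matrix)))
    expect_true(all(truth0$matrix[, f] == truth0$matrix[1, f]))
  expect_equal(nrow(truth0$trace), 0L)

  # absorbing gain on long branches: everything present
  trL <- tr
  trL$phy$edge.length[] <- 200
  truthL <- evolve_content(trL, gain_loss_params(1, 0, 30, master_seed = 5))
  expect_true(all(truthL$matrix == 1L))

  expect_error(gain_loss_params(0, 0, 10), "stationary")
  # explicit root probability rescues the rate-free case
  p <- gain_loss_params(0, 0, 10, root_presence_prob = 0.4)
  expect_equal(p$root_presence_prob, 0.4)
})

test_that("event trace replays to the leaf matrix bit-for-bit", {
  for (seed in c(1, 12, 33)) {
    tr <- sample_tree(3, 3, seed = seed)
    truth <- evolve_content(tr, gain_loss_params(0.4, 0.6, 80,
                                                 master_seed = seed))
    expect_identical(replay_trace(tr, truth), truth$matrix)
    expect_true(all(truth$trace$branch %in% seq_len(nrow(tr$phy$edge))))
    expect_true(all(truth$trace$position >= 0))
  }
})

test_that("presence converges to the stationary frequency", {
  tr <- sample_tree(1, 2, within_clade_depth = 8, between_clade_depth = 9,
                    seed = 4)
  gl <- gain_loss_params(0.4, 0.6, 4000, master_seed = 9)
  truth <- evolve_content(tr, gl)
  # distance 8 >> 1/(lambda+mu): both leaves near pi = 0.4
  expect_lt(abs(mean(truth$matrix[1, ]) - 0.4), 0.04)
  expect_lt(abs(mean(truth$matrix[2, ]) - 0.4), 0.04)
})

test_that("content divergence grows with patristic distance", {
  # three distance levels via clade structure; averages over 600 families
  tr <- sample_tree(2, 4, within_clade_depth = 0.8, between_clade_depth = 4,
                    seed = 6)
  truth <- evolve_content(tr, gain_loss_params(0.5, 0.5, 600,
                                               master_seed = 6))
  D <- ape::cophenetic.phylo(tr$phy)
  H <- as.matrix(stats::dist(truth$matrix, method = "manhattan"))
  taxa <- rownames(D)
  pd <- D[upper.tri(D)]
  hd <- H[taxa, taxa][upper.tri(D)]
  lev <- cut(pd, breaks = c(0, 1, 3, Inf))
  means <- tapply(hd, lev, mean)
  expect_true(all(diff(means) > 0))
  # zero patristic distance would force identical rows: check sisters at
  # tiny distance are much closer than cross-clade pairs
  expect_lt(min(hd[pd < 1.7]), min(hd[pd > 6]))
})

test_that("evolve_proteomes respects presence and mutates per the model", {
  tr <- sample_tree(2, 2, within_clade_depth = 0.5, between_clade_depth = 1.5,
                    seed = 8)
  truth <- evolve_content(tr, gain_loss_params(0.6, 0.4, 40, master_seed = 8))
  # no mutation: leaf sequences identical to family roots
  pr0 <- evolve_proteomes(tr, truth, seq_evol_params(0, 50, 60, seed = 1))
  for (tx in names(pr0$proteomes)) {
    fams <- names(pr0$proteomes[[tx]])
    expect_identical(unname(pr0$proteomes[[tx]]), unname(pr0$roots[fams]))
    # presence semantics: exactly the state-1 families appear
    expect_setequal(fams,
                    colnames(truth$matrix)[truth$matrix[tx, ] == 1L])
  }
  # determinism of the full generator stack
  pr1 <- evolve_proteomes(tr, truth, seq_evol_params(0.2, 50, 60, seed = 2))
  pr2 <- evolve_proteomes(tr, truth, seq_evol_params(0.2, 50, 60, seed = 2))
  expect_identical(pr1$proteomes, pr2$proteomes)
})

test_that("per-site divergence matches the closed form", {
  # one branch of length t: P(site differs) = min(1, rate * t), since a
  # substitution always picks one of the 19 other residues
  tr <- sample_tree(1, 2, within_clade_depth = 2, between_clade_depth = 3,
                    seed = 5)
  tr$phy$edge.length <- c(1.5, 0)  # leaf 1 at distance 1.5, leaf 2 at 0
  truth <- evolve_content(tr, gain_loss_params(1, 0, 1,
                                               root_presence_prob = 1,
                                               master_seed = 1))
  truth$matrix[] <- 1L  # force presence so both leaves carry the family
  pr <- evolve_proteomes(tr, truth,
                         seq_evol_params(0.2, 10000, 10000, seed = 3))
  root <- pr$roots[[1]]
  far_tip <- tr$phy$tip.label[tr$phy$edge[tr$phy$edge.length > 0, 2]]
  leaf <- pr$proteomes[[far_tip]][[1]]
  p_exp <- min(1, 0.2 * 1.5)
  obs <- mean(strsplit(leaf, "")[[1]] != strsplit(root, "")[[1]])
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(obs - p_exp), 3 * se)
})
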