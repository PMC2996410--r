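scoring <- scoring_scheme()

test_that("smith_waterman handles identity and degenerate inputs", {
  s <- "MKVLAADWFFGHQR"
  h <- smith_waterman(s, s, scoring)
  idx <- match(strsplit(s, "")[[1]], AA20)
  expect_equal(h$score, sum(diag(scoring$matrix[idx, idx])))
  expect_equal(h$percent_identity, 100)
  expect_equal(h$alignment_columns, nchar(s))
  expect_null(smith_waterman("", s, scoring))
  expect_null(smith_waterman(s, "", scoring))
  expect_error(smith_waterman("MKX1", s, scoring), "illegal residue")
})

test_that("smith_waterman is symmetric in its arguments", {
  set.seed(11)
  for (k in 1:25) {
    a <- random_aa(sample(5:40, 1)); b <- random_aa(sample(5:40, 1))
    ha <- smith_waterman(a, b, scoring)
    hb <- smith_waterman(b, a, scoring)
    if (is.null(ha)) { expect_null(hb); next }
    expect_equal(ha$score, hb$score)
    expect_equal(ha$alignment_columns, hb$alignment_columns)
    expect_equal(ha$identical_columns, hb$identical_columns)
  }
})

test_that("smith_waterman equals the exhaustive enumeration oracle", {
  set.seed(21)
  for (k in 1:60) {
    a <- random_aa(sample(2:8, 1)); b <- random_aa(sample(2:8, 1))
    h <- smith_waterman(a, b, scoring)
    expect_identical(as.integer(if (is.null(h)) 0L else h$score),
                     as.integer(oracle_sw_score(a, b, scoring)))
  }
})

test_that("self-alignment dominates under a diagonal-maximal matrix", {
  set.seed(31)
  for (k in 1:10) {
    a <- random_aa(30); b <- random_aa(30)
    sa <- smith_waterman(a, a, scoring)$score
    h <- smith_waterman(a, b, scoring)
    expect_gte(sa, if (is.null(h)) 0L else h$score)
  }
})

test_that("evalue follows the Karlin-Altschul closed form", {
  e1 <- evalue(50, 100, 200, scoring)
  # independent evaluation of the formula
  expect_equal(e1, 0.041 * 100 * 200 * exp(-0.267 * 50), tolerance = 1e-15)
  expect_equal(evalue(50, 100, 400, scoring), 2 * e1, tolerance = 1e-12)
  ev <- evalue(seq(0, 300, by = 10), 100, 100, scoring)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue(-1, 10, 10, scoring), "score")
  expect_error(evalue(5, 0, 10, scoring), "length")
})

test_that("best_hit finds the exact copy and breaks ties predictably", {
  set.seed(41)
  q <- random_aa(60)
  targets <- c(z_decoy = random_aa(60), copy = q, other = random_aa(60))
  bh <- best_hit(q, targets, scoring)
  expect_equal(bh$subject, "copy")
  # equal-score tie: lexicographically smaller id wins
  ties <- c(b_t = q, a_t = q)
  expect_equal(best_hit(q, ties, scoring)$subject, "a_t")
  expect_error(best_hit(q, character(0), scoring), "empty")
  # brute-force agreement over individual alignments
  for (k in 1:5) {
    tg <- setNames(replicate(6, random_aa(40)), sprintf("p%d", 1:6))
    qq <- random_aa(40)
    bh <- best_hit(qq, tg, scoring)
    scores <- vapply(tg, function(s) {
      h <- smith_waterman(qq, s, scoring)
      if (is.null(h)) 0L else h$score
    }, integer(1))
    expect_equal(bh$score, max(scores))
  }
})

test_that("reciprocal_best_hits recovers copies and applies strict filters", {
  set.seed(51)
  pa <- setNames(replicate(5, random_aa(90)), sprintf("f%d", 1:5))
  rbh <- reciprocal_best_hits(pa, pa, scoring)
  expect_equal(nrow(rbh), 5L)
  expect_identical(rbh$protein_a, rbh$protein_b)
  expect_equal(rbh$percent_identity, rep(100, 5))

  # boundary: a 70-column perfect alignment is excluded, 71 included
  s70 <- random_aa(70); s71 <- random_aa(71)
  expect_equal(nrow(reciprocal_best_hits(c(x = s70), c(y = s70), scoring)), 0L)
  got <- reciprocal_best_hits(c(x = s71), c(y = s71), scoring)
  expect_equal(nrow(got), 1L)
  expect_equal(got$alignment_columns, 71L)
  # the same pair passes once the threshold is lowered
  expect_equal(nrow(reciprocal_best_hits(c(x = s70), c(y = s70), scoring,
                                         min_alignment_columns = 69)), 1L)
})

test_that("filters are monotone on simulated proteomes", {
  tr <- sample_tree(2, 1, within_clade_depth = 0.2, between_clade_depth = 1,
                    seed = 14)
  truth <- evolve_content(tr, gain_loss_params(0.8, 0.2, 30, master_seed = 14))
  pr <- suppressWarnings(
    evolve_proteomes(tr, truth, seq_evol_params(0.08, 80, 120, seed = 14)))
  pa <- pr$proteomes[[1]]; pb <- pr$proteomes[[2]]
  strict <- reciprocal_best_hits(pa, pb, scoring, 70, 20)
  loose_cols <- reciprocal_best_hits(pa, pb, scoring, 40, 20)
  loose_id <- reciprocal_best_hits(pa, pb, scoring, 70, 5)
  key <- function(x) paste(x$protein_a, x$protein_b)
  expect_true(all(key(strict) %in% key(loose_cols)))
  expect_true(all(key(strict) %in% key(loose_id)))
})

test_that("BBH pairs at low divergence match family provenance", {
  tr <- sample_tree(2, 1, within_clade_depth = 0.2, between_clade_depth = 0.6,
                    seed = 15)
  truth <- evolve_content(tr, gain_loss_params(0.8, 0.2, 60, master_seed = 15))
  pr <- suppressWarnings(
    evolve_proteomes(tr, truth, seq_evol_params(0.05, 85, 130, seed = 15)))
  pa <- pr$proteomes[[1]]; pb <- pr$proteomes[[2]]
  shared <- intersect(names(pa), names(pb))
  rbh <- reciprocal_best_hits(pa, pb, scoring)
  hit_share <- mean(shared %in% rbh$protein_a[rbh$protein_a == rbh$protein_b])
  expect_gte(hit_share, 0.95)
})

test_that("homolog groups are the BBH graph's connected components", {
  empty <- build_homolog_groups(
    data.frame(taxon_a = character(0), protein_a = character(0),
               taxon_b = character(0), protein_b = character(0)))
  expect_equal(nrow(empty), 0L)

  chain <- data.frame(taxon_a = c("T1", "T2"), protein_a = c("a", "b"),
                      taxon_b = c("T2", "T3"), protein_b = c("b", "c"),
                      stringsAsFactors = FALSE)
  g <- build_homolog_groups(chain)
  expect_equal(length(unique(g$group_id)), 1L)
  expect_equal(nrow(g), 3L)

  set.seed(61)
  for (k in 1:10) {
    nv <- sample(6:30, 1)
    taxa <- sprintf("T%d", sample(1:4, nv, replace = TRUE))
    prots <- sprintf("p%02d", seq_len(nv))
    ne <- sample(3:20, 1)
    ij <- cbind(sample(nv, ne, TRUE), sample(nv, ne, TRUE))
    ij <- ij[taxa[ij[, 1]] != taxa[ij[, 2]], , drop = FALSE]
    if (nrow(ij) == 0) next
    pairs <- data.frame(taxon_a = taxa[ij[, 1]], protein_a = prots[ij[, 1]],
                        taxon_b = taxa[ij[, 2]], protein_b = prots[ij[, 2]],
                        stringsAsFactors = FALSE)
    got <- build_homolog_groups(pairs, min_taxa_span = 1L)
    verts <- unique(c(paste(pairs$taxon_a, pairs$protein_a),
                      paste(pairs$taxon_b, pairs$protein_b)))
    want <- oracle_components(verts, paste(pairs$taxon_a, pairs$protein_a),
                              paste(pairs$taxon_b, pairs$protein_b))
    got_parts <- lapply(split(paste(got$taxon, got$protein), got$group_id),
                        sort)
    want_parts <- lapply(want, sort)
    expect_equal(
      sort(unname(vapply(got_parts, paste, character(1), collapse = ";"))),
      sort(unname(vapply(want_parts, paste, character(1), collapse = ";"))))
    # partition covers exactly the incident proteins, disjointly
    expect_equal(sort(unname(unlist(got_parts))), sort(verts))
  }
})
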