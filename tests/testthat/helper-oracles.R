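# Independent oracles used to validate the package's core computations.
# Each is deliberately written by a different route than the implementation
# it checks (enumeration instead of dynamic programming, direct member-pair
# scans instead of Lance-Williams updates, etc.).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Exhaustive local-alignment enumeration: depth-first search over every
# alignment path (diagonal / gap-in-a / gap-in-b moves, affine gap costs),
# from every start cell, keeping the running maximum. The admissible bound
# `score + remaining_diagonals * max(S)` prunes branches that cannot beat
# the incumbent; pruning never changes the maximum.
oracle_sw_score <- function(seq_a, seq_b, scoring) {
  a <- match(strsplit(seq_a, "", fixed = TRUE)[[1]], AA20)
  b <- match(strsplit(seq_b, "", fixed = TRUE)[[1]], AA20)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  S <- scoring$matrix
  go <- scoring$gap_open + scoring$gap_extend
  ge <- scoring$gap_extend
  maxs <- max(S)
  best <- 0L
  dfs <- function(i, j, score, state) {
    if (score > best) best <<- score
    rem <- min(n - i, m - j)
    if (rem > 0L && score + rem * maxs > best)
      dfs(i + 1L, j + 1L, score + S[a[i + 1L], b[j + 1L]], 0L)
    if (j < m && score + min(n - i, m - j - 1L) * maxs > best)
      dfs(i, j + 1L, score - (if (state == 1L) ge else go), 1L)
    if (i < n && score + min(n - i - 1L, m - j) * maxs > best)
      dfs(i + 1L, j, score - (if (state == 2L) ge else go), 2L)
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m))
    dfs(i0, j0, S[a[i0], b[j0]], 0L)
  max(best, 0L)
}

# column-by-column Hamming scan (independent of stats::dist)
oracle_hamming <- function(x, y) {
  stopifnot(length(x) == length(y))
  cnt <- 0L
  for (k in seq_along(x)) if (x[k] != y[k]) cnt <- cnt + 1L
  cnt
}

# Naive quadratic agglomeration sharing the package's tie-break contract
# (pair with lexicographically smallest sorted member tuple merges first).
# single/complete/average distances are recomputed from the ORIGINAL
# matrix by scanning member pairs; ward follows its squared-distance
# recursion on a naively maintained cluster-distance matrix.
oracle_agglomerate <- function(D, linkage) {
  labels <- rownames(D)
  n <- nrow(D)
  clusters <- lapply(labels, identity)
  Wd <- D  # only used by ward
  sizes <- rep(1L, n)
  steps <- list()
  for (st in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- Inf; bi <- 0L; bj <- 0L; bkey <- NULL
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      d <- if (linkage == "ward") Wd[i, j] else {
        vals <- as.vector(D[clusters[[i]], clusters[[j]], drop = FALSE])
        switch(linkage,
               single = min(vals), complete = max(vals),
               average = mean(vals))
      }
      if (d > best) next
      key <- paste(sort(c(clusters[[i]], clusters[[j]])), collapse = "\r")
      if (d < best || key < bkey) { best <- d; bi <- i; bj <- j; bkey <- key }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    steps[[st]] <- list(
      union = paste(merged, collapse = "\r"),
      children = sort(c(paste(sort(clusters[[bi]]), collapse = "\r"),
                        paste(sort(clusters[[bj]]), collapse = "\r"))),
      height = best)
    if (linkage == "ward") {
      na <- sizes[bi]; nb <- sizes[bj]
      new_row <- vapply(seq_len(k), function(c2) {
        if (c2 %in% c(bi, bj)) return(NA_real_)
        nc <- sizes[c2]
        sqrt(((na + nc) * Wd[bi, c2]^2 + (nb + nc) * Wd[bj, c2]^2 -
                nc * Wd[bi, bj]^2) / (na + nb + nc))
      }, numeric(1))
      keep <- setdiff(seq_len(k), c(bi, bj))
      Wd2 <- matrix(0, k - 1L, k - 1L)
      Wd2[seq_along(keep), seq_along(keep)] <- Wd[keep, keep]
      Wd2[k - 1L, seq_along(keep)] <- Wd2[seq_along(keep), k - 1L] <-
        new_row[keep]
      Wd <- Wd2
      sizes <- c(sizes[keep], na + nb)
      clusters <- c(clusters[keep], list(merged))
    } else {
      keep <- setdiff(seq_len(k), c(bi, bj))
      clusters <- c(clusters[keep], list(merged))
      sizes <- c(sizes[keep], sizes[bi] + sizes[bj])
    }
  }
  steps
}

# the package dendrogram rendered in the oracle's step format
pkg_merge_steps <- function(dend) {
  sets <- list()
  get_set <- function(code)
    if (code < 0L) dend$labels[-code] else sets[[code]]
  steps <- vector("list", nrow(dend$merge))
  for (k in seq_len(nrow(dend$merge))) {
    c1 <- get_set(dend$merge[k, 1L]); c2 <- get_set(dend$merge[k, 2L])
    sets[[k]] <- sort(c(c1, c2))
    steps[[k]] <- list(
      union = paste(sets[[k]], collapse = "\r"),
      children = sort(c(paste(sort(c1), collapse = "\r"),
                        paste(sort(c2), collapse = "\r"))),
      height = dend$height[k])
  }
  steps
}

# transitive-closure reachability (boolean matrix powers)
oracle_components <- function(vertices, edges_from, edges_to) {
  n <- length(vertices)
  A <- diag(TRUE, n)
  rownames(A) <- colnames(A) <- vertices
  for (k in seq_along(edges_from)) {
    A[edges_from[k], edges_to[k]] <- TRUE
    A[edges_to[k], edges_from[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[A[i, ] > 0] <- cid
  }
  split(vertices, comp)
}

# a distance matrix that is exactly Euclidean (from random points), so
# every linkage including ward is well defined and ties have measure zero
random_euclidean_dist <- function(n, p = 4L) {
  pts <- matrix(rnorm(n * p), n, p)
  rownames(pts) <- sprintf("t%02d", seq_len(n))
  as.matrix(dist(pts))
}

random_binary_matrix <- function(n_taxa, n_cols) {
  m <- matrix(sample(0:1, n_taxa * n_cols, replace = TRUE), n_taxa, n_cols,
              dimnames = list(sprintf("t%d", seq_len(n_taxa)),
                              sprintf("g%d", seq_len(n_cols))))
  m
}
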