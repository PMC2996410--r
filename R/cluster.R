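#' Euclidean distance matrix from a phyletic matrix
#'
#' `d(x, y) = sqrt(sum_c (x_c - y_c)^2)`; on binary rows this is the
#' square root of the number of differing columns. No weighting or
#' normalization is applied.
#'
#' @param matrix numeric matrix with at least 2 rows (taxa) and row
#'   names.
#' @return symmetric numeric matrix with zero diagonal and the taxa as
#'   dimnames.
#' @export
euclidean_distances <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 2L)
    stop("need a matrix with at least 2 taxa")
  if (is.null(rownames(matrix))) stop("matrix must have taxon row names")
  as.matrix(stats::dist(matrix, method = "euclidean"))
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Standard agglomeration: repeatedly merge the two clusters at minimal
#' linkage distance, recording the merge height. Cluster-to-cluster
#' distances follow the Lance-Williams updates (`ward` is the
#' squared-distance "ward.D2" form). When several pairs share exactly
#' the minimal distance, the pair whose sorted member-label tuple is
#' lexicographically smallest merges first, so results are reproducible
#' regardless of input order.
#'
#' @param dist symmetric distance matrix (or a `stats::dist`) with
#'   labels; NaN or negative entries are an error.
#' @param linkage one of `"complete"`, `"single"`, `"average"`,
#'   `"ward"`.
#' @return an object of class `phyletic_dendrogram`: list with `merge`
#'   (hclust-style n-1 x 2 matrix, negative entries are leaves),
#'   `height`, `labels` and `linkage`.
#' @export
agglomerative_cluster <- function(dist, linkage = c("complete", "single",
                                                    "average", "ward")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(dist, "dist")) as.matrix(dist) else dist
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("dist must be a square matrix or dist object")
  if (anyNA(D) || any(is.nan(D))) stop("distances contain NA/NaN")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have labels")
  diag(D) <- 0

  active <- seq_len(n)
  members <- lapply(labels, identity)       # sorted member labels
  code <- -seq_len(n)                       # hclust codes
  size <- rep(1L, n)
  W <- D                                    # working linkage distances
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    # minimal linkage distance among active pairs
    best <- Inf; bi <- 0L; bj <- 0L; bkey <- NULL
    for (ii in seq_len(length(active) - 1L)) {
      for (jj in seq((ii + 1L), length(active))) {
        i <- active[ii]; j <- active[jj]
        d <- W[i, j]
        if (d > best) next
        key <- paste(sort(c(members[[i]], members[[j]])), collapse = "\r")
        if (d < best || key < bkey) {
          best <- d; bi <- i; bj <- j; bkey <- key
        }
      }
    }
    height[step] <- best
    # child order: cluster with the lexicographically smaller member
    # tuple on the left, so serialized output is label-deterministic
    ka <- paste(members[[bi]], collapse = "\r")
    kb <- paste(members[[bj]], collapse = "\r")
    merge[step, ] <- if (ka < kb) c(code[bi], code[bj]) else
      c(code[bj], code[bi])
    # merge bj into bi
    ni <- size[bi]; nj <- size[bj]
    for (k in active) {
      if (k == bi || k == bj) next
      W[bi, k] <- W[k, bi] <- lw_update(linkage, W[bi, k], W[bj, k],
                                        W[bi, bj], ni, nj, size[k])
    }
    members[[bi]] <- sort(c(members[[bi]], members[[bj]]))
    size[bi] <- ni + nj
    code[bi] <- step
    active <- active[active != bj]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "phyletic_dendrogram")
}

# Lance-Williams update for the distance from the merged cluster (a u b)
# to cluster c; ward follows the ward.D2 (squared-distance) recursion
lw_update <- function(linkage, dac, dbc, dab, na, nb, nc) {
  switch(linkage,
    single = min(dac, dbc),
    complete = max(dac, dbc),
    average = (na * dac + nb * dbc) / (na + nb),
    ward = sqrt(((na + nc) * dac^2 + (nb + nc) * dbc^2 - nc * dab^2) /
                  (na + nb + nc)))
}

#' @export
print.phyletic_dendrogram <- function(x, ...) {
  cat(sprintf("phyletic_dendrogram: %d leaves, %s linkage, heights %s..%s\n",
              length(x$labels), x$linkage,
              fmt_num(min(x$height), 4), fmt_num(max(x$height), 4)))
  invisible(x)
}

#' @export
as.hclust.phyletic_dendrogram <- function(x, ...) {
  h <- list(merge = x$merge, height = x$height, labels = x$labels,
            order = dendrogram_leaf_order(x), method = x$linkage,
            call = match.call(), dist.method = "euclidean")
  class(h) <- "hclust"
  h
}

# left-to-right leaf order implied by the merge matrix
dendrogram_leaf_order <- function(dend) {
  rec <- function(code) {
    if (code < 0L) return(-code)
    c(rec(dend$merge[code, 1L]), rec(dend$merge[code, 2L]))
  }
  rec(nrow(dend$merge))
}

# leaf-label sets below every internal node (list of sorted char vectors)
dendrogram_node_sets <- function(dend) {
  sets <- vector("list", nrow(dend$merge))
  get <- function(code) {
    if (code < 0L) return(dend$labels[-code])
    sets[[code]]
  }
  for (k in seq_len(nrow(dend$merge)))
    sets[[k]] <- sort(c(get(dend$merge[k, 1L]), get(dend$merge[k, 2L])))
  sets
}

#' Serialize a dendrogram to Newick
#'
#' Each edge length is the parent's merge height minus the child's
#' height, with leaves at height 0 (no halving). Labels containing
#' Newick-reserved characters are single-quoted.
#'
#' @param dendrogram a [agglomerative_cluster()] result.
#' @param precision decimal places for edge lengths.
#' @return a Newick string terminated by `;`.
#' @export
to_newick <- function(dendrogram, precision = 6L) {
  stopifnot(inherits(dendrogram, "phyletic_dendrogram"))
  dend <- dendrogram
  quote_label <- function(l) {
    if (grepl("[][ ,:;()']", l))
      paste0("'", gsub("'", "''", l, fixed = TRUE), "'")
    else l
  }
  rec <- function(code, parent_height) {
    if (code < 0L) {
      paste0(quote_label(dend$labels[-code]), ":",
             fmt_num(parent_height, precision))
    } else {
      h <- dend$height[code]
      kids <- c(rec(dend$merge[code, 1L], h), rec(dend$merge[code, 2L], h))
      out <- paste0("(", paste(kids, collapse = ","), ")")
      if (!is.null(parent_height))
        out <- paste0(out, ":", fmt_num(parent_height - h, precision))
      out
    }
  }
  paste0(rec(nrow(dend$merge), NULL), ";")
}
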