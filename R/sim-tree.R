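#' Sample a clade-structured ultrametric tree
#'
#' Generates a rooted binary ultrametric tree of `n_clades` clades with
#' `leaves_per_clade` leaves each, emulating a sample of taxa drawn from
#' well-separated domains. Within a clade, leaves coalesce by random
#' pairwise joins at heights drawn uniformly below `within_clade_depth`,
#' with the clade root at exactly `within_clade_depth` above the leaves.
#' Clade roots join along a random backbone whose merge heights are
#' spaced evenly between `within_clade_depth` and `between_clade_depth`
#' (the root), so every leaf sits at depth `between_clade_depth` from
#' the root, clades separate cleanly, and the backbone topology itself
#' remains identifiable rather than collapsing into a star.
#'
#' @param n_clades,leaves_per_clade positive integers.
#' @param within_clade_depth,between_clade_depth tree heights in expected
#'   events per gene family per unit branch length; must satisfy
#'   `between_clade_depth > within_clade_depth > 0`.
#' @param seed integer seed; the same seed yields a byte-identical tree.
#' @return an object of class `evol_tree`: a list with `phy` (an
#'   [ape::read.tree()] phylo), `clades` (named character vector mapping
#'   taxon to clade label) and `newick` (the serialized tree).
#' @export
sample_tree <- function(n_clades, leaves_per_clade,
                        within_clade_depth = 0.5,
                        between_clade_depth = 3.0,
                        seed = 1L) {
  n_clades <- as.integer(n_clades)
  leaves_per_clade <- as.integer(leaves_per_clade)
  if (is.na(n_clades) || n_clades < 1L)
    stop("n_clades must be a positive integer")
  if (is.na(leaves_per_clade) || leaves_per_clade < 1L)
    stop("leaves_per_clade must be a positive integer")
  if (n_clades * leaves_per_clade < 2L)
    stop("tree must have at least 2 leaves")
  if (!(between_clade_depth > within_clade_depth && within_clade_depth > 0))
    stop("need between_clade_depth > within_clade_depth > 0")

  build <- function() {
    clade_names <- sprintf("C%02d", seq_len(n_clades))
    # ultrametric subtree per clade by random sequential coalescence
    clade_nodes <- lapply(seq_len(n_clades), function(ci) {
      labs <- sprintf("%s_L%02d", clade_names[ci], seq_len(leaves_per_clade))
      nodes <- lapply(labs, function(l) list(label = l, height = 0))
      k <- length(nodes)
      if (k == 1L) return(nodes[[1L]])
      hs <- if (k == 2L) within_clade_depth else
        c(sort(runif(k - 2L, 0, within_clade_depth)), within_clade_depth)
      for (h in hs) {
        pick <- sample.int(length(nodes), 2L)
        joined <- list(children = nodes[pick], height = h)
        nodes <- c(nodes[-pick], list(joined))
      }
      nodes[[1L]]
    })
    # backbone: joins spread evenly through the deep part of the tree,
    # up to the root at exactly between_clade_depth, so the clade
    # topology stays identifiable (a backbone squeezed against the root
    # would be an unresolvable star)
    nodes <- clade_nodes
    if (n_clades > 1L) {
      hs <- seq(within_clade_depth, between_clade_depth,
                length.out = n_clades)[-1L]
      for (h in hs) {
        pick <- sample.int(length(nodes), 2L)
        joined <- list(children = nodes[pick], height = h)
        nodes <- c(nodes[-pick], list(joined))
      }
    }
    clades <- setNames(
      rep(clade_names, each = leaves_per_clade),
      unlist(lapply(seq_len(n_clades), function(ci)
        sprintf("%s_L%02d", clade_names[ci], seq_len(leaves_per_clade)))))
    list(root = nodes[[1L]], clades = clades)
  }
  built <- with_seed(seed, build())

  newick <- paste0(node_to_newick(built$root, parent_height = NULL,
                                  precision = 6L), ";")
  phy <- ape::read.tree(text = newick)
  structure(list(phy = phy, clades = built$clades, newick = newick),
            class = "evol_tree")
}

# recursive Newick rendering of the internal node representation
node_to_newick <- function(node, parent_height, precision) {
  brlen <- if (is.null(parent_height)) NULL else
    fmt_num(parent_height - node$height, precision)
  if (is.null(node$children)) {
    paste0(node$label, if (!is.null(brlen)) paste0(":", brlen))
  } else {
    kids <- vapply(node$children, node_to_newick, character(1),
                   parent_height = node$height, precision = precision)
    paste0("(", paste(kids, collapse = ","), ")",
           if (!is.null(brlen)) paste0(":", brlen))
  }
}

#' @export
print.evol_tree <- function(x, ...) {
  cat(sprintf("evol_tree: %d leaves, %d clades\n",
              length(x$clades), length(unique(x$clades))))
  invisible(x)
}

# edge table in preorder (parent before child), with per-edge lengths
tree_edges_preorder <- function(tree) {
  phy <- if (inherits(tree, "evol_tree")) tree$phy else tree
  phy <- ape::reorder.phylo(phy, "cladewise")
  data.frame(edge = seq_len(nrow(phy$edge)),
             parent = phy$edge[, 1L], child = phy$edge[, 2L],
             length = phy$edge.length)
}
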