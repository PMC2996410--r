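#' Parameters of the sequence divergence process
#'
#' Sites evolve independently: along a branch of length `t` a site is
#' replaced with probability `min(1, sub_rate * t)` by a residue drawn
#' uniformly from the 19 alternatives (so a substituted site always
#' changes). Root sequences draw their length uniformly from
#' `[root_len_min, root_len_max]` and their residues uniformly from the
#' 20-letter alphabet. No indels are simulated.
#'
#' @param sub_rate per-site substitution probability per unit branch
#'   length, in `[0, 1]` before capping.
#' @param root_len_min,root_len_max root-sequence length bounds (>= 1).
#' @param seed integer seed for the sequence streams (independent of the
#'   gain/loss master seed).
#' @return an object of class `seq_evol_params`.
#' @export
seq_evol_params <- function(sub_rate = 0.1, root_len_min = 80L,
                            root_len_max = 150L, seed = 1L) {
  if (sub_rate < 0) stop("sub_rate must be >= 0")
  root_len_min <- as.integer(root_len_min)
  root_len_max <- as.integer(root_len_max)
  if (root_len_min < 1L || root_len_max < root_len_min)
    stop("need 1 <= root_len_min <= root_len_max")
  structure(list(sub_rate = sub_rate, root_len_min = root_len_min,
                 root_len_max = root_len_max, seed = as.integer(seed)),
            class = "seq_evol_params")
}

#' Evolve synthetic proteomes with known family provenance
#'
#' Draws one root sequence per gene family, mutates it site-independently
#' along every branch (per-family, per-branch derived seeds), and emits
#' for each leaf taxon exactly the sequences of the families present
#' (state 1) at that leaf, keyed by family identifier.
#'
#' @param tree the `evol_tree` the content was evolved on.
#' @param content a [evolve_content()] `content_truth`.
#' @param seq_params a [seq_evol_params()].
#' @return an object of class `proteome_set`: a list with `proteomes`
#'   (named list, one named character vector of sequences per taxon;
#'   element names are family ids), `roots` (named character vector of
#'   family root sequences) and `seq_params`.
#' @export
evolve_proteomes <- function(tree, content, seq_params = seq_evol_params()) {
  stopifnot(inherits(content, "content_truth"),
            inherits(seq_params, "seq_evol_params"))
  phy <- if (inherits(tree, "evol_tree")) tree$phy else tree
  edges <- tree_edges_preorder(phy)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  if (!identical(sort(rownames(content$matrix)), sort(phy$tip.label)))
    stop("content matrix is not consistent with the tree's taxa")
  fams <- colnames(content$matrix)
  nnode <- ntip + phy$Nnode
  roots <- character(length(fams))
  proteomes <- lapply(phy$tip.label, function(t) character(0))
  names(proteomes) <- phy$tip.label
  per_leaf <- lapply(phy$tip.label, function(t) list())
  names(per_leaf) <- phy$tip.label
  for (f in seq_along(fams)) {
    root_seq <- with_seed(derive_seed(seq_params$seed, f, 0L), {
      len <- sample(seq(seq_params$root_len_min, seq_params$root_len_max), 1L)
      paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
    })
    roots[f] <- root_seq
    node_seq <- character(nnode)
    node_seq[root] <- root_seq
    for (e in seq_len(nrow(edges))) {
      s <- node_seq[edges$parent[e]]
      p <- min(1, seq_params$sub_rate * edges$length[e])
      if (p > 0) {
        s <- with_seed(derive_seed(seq_params$seed, f, e),
                       mutate_sequence(s, p))
      }
      node_seq[edges$child[e]] <- s
    }
    present <- which(content$matrix[phy$tip.label, f] == 1L)
    for (li in present)
      per_leaf[[phy$tip.label[li]]][[fams[f]]] <- node_seq[li]
  }
  names(roots) <- fams
  for (tx in phy$tip.label) {
    v <- unlist(per_leaf[[tx]])
    if (is.null(v)) {
      v <- character(0)
      warning("taxon ", tx, " has an empty proteome (all families absent)")
    }
    proteomes[[tx]] <- v
  }
  structure(list(proteomes = proteomes, roots = roots,
                 seq_params = seq_params),
            class = "proteome_set")
}

# substitute each site independently with probability p, drawing
# uniformly from the 19 alternative residues
mutate_sequence <- function(seq, p) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    repl <- vapply(chars[hit], function(ch)
      sample(AA_ALPHABET20[AA_ALPHABET20 != ch], 1L), character(1),
      USE.NAMES = FALSE)
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Build a reference ortholog database from simulator root sequences
#'
#' Turns the family root sequences of a [evolve_proteomes()] run into a
#' category-labelled reference database (one member per group). Functional
#' categories default to the six informational letters (J, A, K, L, B, F)
#' assigned cyclically by family index, which is deterministic and keeps
#' every simulated family inside the informational universe.
#'
#' @param proteome_set a [evolve_proteomes()] result (or a named character
#'   vector of root sequences).
#' @param categories character vector recycled over the families.
#' @return a `reference_db` (see [reference_db()]).
#' @export
reference_from_roots <- function(proteome_set,
                                 categories = c("J", "A", "K", "L", "B", "F")) {
  roots <- if (inherits(proteome_set, "proteome_set")) proteome_set$roots
           else proteome_set
  if (is.null(names(roots))) stop("root sequences must be named by family")
  groups <- data.frame(
    group_id = names(roots),
    category = rep_len(categories, length(roots)),
    stringsAsFactors = FALSE)
  members <- data.frame(
    group_id = names(roots), member_id = "root",
    seq = unname(roots), stringsAsFactors = FALSE)
  reference_db(groups, members)
}
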