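#' Score clade recovery of a dendrogram
#'
#' A labelled clade is monophyletic iff some edge of the dendrogram
#' separates exactly its taxa from all others. When a reference tree is
#' supplied, the Robinson-Foulds distance (size of the symmetric
#' difference of the two trees' non-trivial unrooted bipartitions) is
#' computed on the full taxon set, and additionally at the clade level:
#' every bipartition in which each clade lies wholly on one side induces
#' a split of the clade labels, and the two trees' induced clade-split
#' sets are compared (`rf_clade` is `NA` unless all clades are
#' monophyletic in both trees).
#'
#' @param dendrogram a [agglomerative_cluster()] result.
#' @param clade_labels named character vector mapping every leaf taxon
#'   to its clade label; a missing leaf is an error.
#' @param reference_tree optional reference topology: an `evol_tree`, an
#'   ape `phylo`, a Newick string, or a path to a Newick file.
#' @return an object of class `clade_recovery`: list with `monophyletic`
#'   (named logical per clade), `n_clades_recovered`, and when a
#'   reference is given `rf`, `shared_bipartitions`,
#'   `unique_bipartitions` (per tree), `rf_clade`.
#' @export
compare_clades <- function(dendrogram, clade_labels, reference_tree = NULL) {
  stopifnot(inherits(dendrogram, "phyletic_dendrogram"))
  taxa <- dendrogram$labels
  missing <- setdiff(taxa, names(clade_labels))
  if (length(missing))
    stop("clade_labels missing leaf taxa: ", paste(missing, collapse = ", "))
  clade_labels <- clade_labels[taxa]
  sets <- dendrogram_node_sets(dendrogram)
  all_sorted <- sort(taxa)
  clades <- sort(unique(clade_labels))
  mono <- vapply(clades, function(cl) {
    want <- sort(taxa[clade_labels == cl])
    compl <- setdiff(all_sorted, want)
    any(vapply(sets, function(s)
      identical(s, want) || identical(s, compl), logical(1)))
  }, logical(1))
  out <- list(monophyletic = mono,
              n_clades_recovered = sum(mono),
              clade_labels = clade_labels)
  if (!is.null(reference_tree)) {
    ref_sets <- tip_sets_of(reference_tree)
    ref_taxa <- sort(unique(unlist(ref_sets)))
    if (!identical(ref_taxa, all_sorted))
      stop("reference tree and dendrogram have different taxa")
    sd <- splits_canonical(sets, all_sorted)
    sr <- splits_canonical(ref_sets, all_sorted)
    out$rf <- length(setdiff(sd, sr)) + length(setdiff(sr, sd))
    out$shared_bipartitions <- length(intersect(sd, sr))
    out$unique_bipartitions <- c(dendrogram = length(setdiff(sd, sr)),
                                 reference = length(setdiff(sr, sd)))
    ref_mono <- vapply(clades, function(cl) {
      want <- sort(names(clade_labels)[clade_labels == cl])
      compl <- setdiff(all_sorted, want)
      any(vapply(ref_sets, function(s)
        identical(sort(s), want) || identical(sort(s), compl), logical(1)))
    }, logical(1))
    if (all(mono) && all(ref_mono)) {
      cd <- clade_splits(sets, clade_labels, all_sorted)
      cr <- clade_splits(ref_sets, clade_labels, all_sorted)
      out$rf_clade <- length(setdiff(cd, cr)) + length(setdiff(cr, cd))
    } else {
      out$rf_clade <- NA_integer_
    }
  }
  class(out) <- "clade_recovery"
  out
}

#' @export
print.clade_recovery <- function(x, ...) {
  cat("clade_recovery:", x$n_clades_recovered, "of",
      length(x$monophyletic), "clades monophyletic\n")
  for (cl in names(x$monophyletic))
    cat(sprintf("  %s: %s\n", cl,
                if (x$monophyletic[[cl]]) "monophyletic" else "not recovered"))
  if (!is.null(x$rf))
    cat(sprintf("  RF distance: %d (clade-level: %s)\n", x$rf,
                if (is.na(x$rf_clade)) "NA" else as.character(x$rf_clade)))
  invisible(x)
}

# tip-label sets below each internal node of a tree in any accepted form
tip_sets_of <- function(tree) {
  if (inherits(tree, "phyletic_dendrogram"))
    return(dendrogram_node_sets(tree))
  phy <- if (inherits(tree, "evol_tree")) tree$phy
         else if (inherits(tree, "phylo")) tree
         else if (is.character(tree) && length(tree) == 1L) {
           if (grepl(";", tree)) ape::read.tree(text = tree)
           else ape::read.tree(tree)
         } else stop("unsupported reference tree type")
  ntip <- length(phy$tip.label)
  sets <- vector("list", phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L] - ntip
    child <- po$edge[e, 2L]
    below <- if (child <= ntip) phy$tip.label[child]
             else sets[[child - ntip]]
    sets[[parent]] <- c(sets[[parent]], below)
  }
  lapply(sets, sort)
}

# canonical non-trivial unrooted bipartitions: represent each split by
# the sorted side containing the alphabetically first taxon
splits_canonical <- function(sets, all_sorted) {
  anchor <- all_sorted[1L]
  n <- length(all_sorted)
  keys <- vapply(sets, function(s) {
    side <- if (anchor %in% s) s else setdiff(all_sorted, s)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(side, collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# splits of the clade labels induced by clade-respecting bipartitions
clade_splits <- function(sets, clade_labels, all_sorted) {
  clades <- sort(unique(clade_labels))
  n <- length(clades)
  keys <- vapply(sets, function(s) {
    inside <- unique(clade_labels[s])
    outside <- unique(clade_labels[setdiff(all_sorted, s)])
    if (length(intersect(inside, outside))) return(NA_character_)
    side <- if (clades[1L] %in% inside) sort(inside) else sort(outside)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(side, collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}
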