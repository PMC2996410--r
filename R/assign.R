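#' Assign proteins to reference ortholog groups
#'
#' Aligns every protein of a proteome against all member sequences of a
#' reference database and assigns it to the group of its best-scoring
#' member, provided the hit's E-value is strictly below
#' `evalue_threshold`. Ties break by lower E-value, then
#' lexicographically smallest group id, then member id. Proteins with no
#' qualifying hit are omitted (their count is reported via `message()`).
#'
#' @param proteome named character vector of protein sequences.
#' @param refdb a [reference_db()] (non-empty).
#' @param scoring a [scoring_scheme()].
#' @param evalue_threshold strict upper bound on the assignment E-value.
#' @param all_hits if `TRUE`, report every group with a member hit below
#'   the threshold (best member per group) instead of only the single
#'   best group; intended for sensitivity analyses.
#' @return data.frame `protein`, `group_id`, `evalue`, sorted by protein
#'   then group.
#' @export
assign_to_reference <- function(proteome, refdb,
                                scoring = scoring_scheme(),
                                evalue_threshold = 1e-3,
                                all_hits = FALSE) {
  stopifnot(inherits(refdb, "reference_db"))
  if (nrow(refdb$members) == 0L) stop("reference database is empty")
  empty <- data.frame(protein = character(0), group_id = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (length(proteome) == 0L) return(empty)
  if (is.null(names(proteome))) stop("proteome sequences must be named")
  members <- refdb$members
  mem_seqs <- setNames(members$seq,
                       paste(members$group_id, members$member_id, sep = "|"))
  S <- sw_score_matrix(proteome, mem_seqs, scoring)
  E <- scoring$k_stat *
    outer(as.double(nchar(proteome)), as.double(nchar(mem_seqs))) *
    exp(-scoring$lambda_stat * S)
  rows <- list()
  for (i in order(names(proteome), method = "radix")) {
    ok <- which(S[i, ] > 0L & E[i, ] < evalue_threshold)
    if (length(ok) == 0L) next
    ord <- ok[order(-S[i, ok], E[i, ok], members$group_id[ok],
                    members$member_id[ok], method = "radix")]
    pick <- if (all_hits) ord[!duplicated(members$group_id[ord])] else ord[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      protein = names(proteome)[i],
      group_id = members$group_id[pick],
      evalue = E[i, pick], stringsAsFactors = FALSE)
  }
  n_un <- length(proteome) - length(rows)
  if (!all_hits && n_un > 0)
    message(n_un, " protein(s) unassigned (no hit below E-value threshold)")
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$protein, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate assignment group ids through a label map
#'
#' Applies a group-id translation table (e.g. linking virus-specific
#' ortholog groups to the categories of a cellular reference database).
#' Assignments whose group id is missing from the map are dropped, and
#' the dropped count is reported via `message()`.
#'
#' @param assignments data.frame from [assign_to_reference()].
#' @param label_map data.frame with columns `from`, `to`; keys must be
#'   unique.
#' @return translated assignments data.frame.
#' @export
map_group_labels <- function(assignments, label_map) {
  stopifnot(is.data.frame(label_map),
            all(c("from", "to") %in% names(label_map)))
  if (anyDuplicated(label_map$from))
    stop("label map keys must be unique")
  idx <- match(assignments$group_id, label_map$from)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " assignment(s) dropped: group id not in label map")
  out <- assignments[!is.na(idx), , drop = FALSE]
  out$group_id <- label_map$to[idx[!is.na(idx)]]
  out <- out[order(out$protein, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary phyletic (presence/absence) matrix
#'
#' Cell (taxon, group) is 1 iff the taxon has at least one protein
#' assigned to the group, else 0. Rows are the taxa sorted
#' lexicographically; columns are `group_universe` in the given order
#' (typically all groups of the category-filtered reference, so all-zero
#' columns are kept and matrices stay comparable across runs).
#'
#' @param assignments named list mapping taxon to its
#'   [assign_to_reference()] data.frame.
#' @param group_universe ordered character vector of group ids; an
#'   assignment outside the universe is an error.
#' @return taxa x groups integer matrix of 0/1.
#' @export
build_matrix <- function(assignments, group_universe) {
  if (length(group_universe) == 0L) stop("group universe is empty")
  if (anyDuplicated(group_universe)) stop("group universe has duplicates")
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stop("assignments must be a named list with unique taxon names")
  taxa <- sort(names(assignments))
  mat <- matrix(0L, nrow = length(taxa), ncol = length(group_universe),
                dimnames = list(taxa, group_universe))
  for (tx in taxa) {
    g <- assignments[[tx]]$group_id
    bad <- setdiff(g, group_universe)
    if (length(bad))
      stop("taxon ", tx, ": assignment to group(s) outside the universe: ",
           paste(bad, collapse = ", "))
    mat[tx, unique(g)] <- 1L
  }
  mat
}
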