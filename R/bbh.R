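#' Reciprocal best hits between two proteomes
#'
#' Computes exact local-alignment scores for every protein pair between
#' two proteomes, finds each protein's best hit in the other proteome
#' (ties: higher score, then lower E-value, then lexicographically
#' smallest subject id) and keeps the reciprocal pairs whose forward hit
#' passes the homology filters: strictly more than
#' `min_alignment_columns` alignment columns (gap columns included) and
#' strictly more than `min_percent_identity` percent identity. Because
#' exact Smith-Waterman is symmetric, the reverse hit of a reciprocal
#' pair has identical score, column counts and E-value.
#'
#' @param proteome_a,proteome_b named character vectors of sequences
#'   (non-empty).
#' @param scoring a [scoring_scheme()].
#' @param min_alignment_columns,min_percent_identity homology thresholds;
#'   defaults are the classic "over 70 aligned residues, over 20%
#'   identity" rule (strict inequalities).
#' @param taxon_a,taxon_b taxon labels recorded in the output.
#' @return data.frame with one row per reciprocal pair: `taxon_a`,
#'   `protein_a`, `taxon_b`, `protein_b`, `score`, `alignment_columns`,
#'   `identical_columns`, `percent_identity`, `evalue`; sorted by
#'   `protein_a`, then `protein_b`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 scoring = scoring_scheme(),
                                 min_alignment_columns = 70,
                                 min_percent_identity = 20,
                                 taxon_a = "A", taxon_b = "B") {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("both proteomes must be non-empty")
  S <- sw_score_matrix(proteome_a, proteome_b, scoring)
  la <- nchar(proteome_a); lb <- nchar(proteome_b)
  E <- scoring$k_stat * outer(as.double(la), as.double(lb)) *
    exp(-scoring$lambda_stat * S)
  ids_a <- names(proteome_a); ids_b <- names(proteome_b)
  best_of_a <- vapply(seq_along(ids_a), function(i) {
    if (max(S[i, ]) <= 0L) return(NA_integer_)
    order(-S[i, ], E[i, ], ids_b, method = "radix")[1L]
  }, integer(1))
  best_of_b <- vapply(seq_along(ids_b), function(j) {
    if (max(S[, j]) <= 0L) return(NA_integer_)
    order(-S[, j], E[, j], ids_a, method = "radix")[1L]
  }, integer(1))
  rows <- list()
  for (i in order(ids_a, method = "radix")) {
    j <- best_of_a[i]
    if (is.na(j) || is.na(best_of_b[j]) || best_of_b[j] != i) next
    hit <- smith_waterman(proteome_a[[i]], proteome_b[[j]], scoring)
    if (is.null(hit)) next
    if (!(hit$alignment_columns > min_alignment_columns &&
          hit$percent_identity > min_percent_identity)) next
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_a = taxon_a, protein_a = ids_a[i],
      taxon_b = taxon_b, protein_b = ids_b[j],
      score = hit$score, alignment_columns = hit$alignment_columns,
      identical_columns = hit$identical_columns,
      percent_identity = hit$percent_identity,
      evalue = hit$evalue, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_a = character(0), protein_a = character(0),
               taxon_b = character(0), protein_b = character(0),
               score = integer(0), alignment_columns = integer(0),
               identical_columns = integer(0),
               percent_identity = numeric(0), evalue = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' All-vs-all reciprocal best hits across a set of proteomes
#'
#' Runs [reciprocal_best_hits()] for every unordered taxon pair and binds
#' the results; taxon pairs are processed in sorted order so the output
#' is deterministic.
#'
#' @param proteomes named list of named character vectors.
#' @inheritParams reciprocal_best_hits
#' @return data.frame as in [reciprocal_best_hits()].
#' @export
all_vs_all_bbh <- function(proteomes, scoring = scoring_scheme(),
                           min_alignment_columns = 70,
                           min_percent_identity = 20) {
  taxa <- sort(names(proteomes))
  if (length(taxa) < 2L) stop("need at least two proteomes")
  out <- list()
  for (ia in seq_len(length(taxa) - 1L)) {
    for (ib in seq((ia + 1L), length(taxa))) {
      a <- taxa[ia]; b <- taxa[ib]
      if (length(proteomes[[a]]) == 0L || length(proteomes[[b]]) == 0L)
        next
      out[[length(out) + 1L]] <- reciprocal_best_hits(
        proteomes[[a]], proteomes[[b]], scoring,
        min_alignment_columns, min_percent_identity,
        taxon_a = a, taxon_b = b)
    }
  }
  do.call(rbind, out)
}

#' Group homologous proteins from reciprocal-best-hit pairs
#'
#' Homolog groups are the connected components of the graph whose
#' vertices are (taxon, protein) pairs and whose edges are BBH pairs.
#' Proteins in no pair are not emitted. Groups spanning fewer than
#' `min_taxa_span` taxa are dropped (default 2, the minimum a BBH edge
#' can produce).
#'
#' @param pairs data.frame from [reciprocal_best_hits()] /
#'   [all_vs_all_bbh()].
#' @param min_taxa_span minimum number of distinct taxa per group.
#' @return data.frame `group_id`, `taxon`, `protein`, sorted by group
#'   then member; group ids `HG0001`, ... ordered by each group's
#'   smallest member key.
#' @export
build_homolog_groups <- function(pairs, min_taxa_span = 2L) {
  if (nrow(pairs) == 0L)
    return(data.frame(group_id = character(0), taxon = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  va <- paste(pairs$taxon_a, pairs$protein_a, sep = "\r")
  vb <- paste(pairs$taxon_b, pairs$protein_b, sep = "\r")
  g <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb, stringsAsFactors = FALSE),
    directed = FALSE)
  comp <- igraph::components(g)
  member <- names(comp$membership)
  parts <- split(member, comp$membership)
  parts <- lapply(parts, sort)
  parts <- parts[order(vapply(parts, `[`, character(1), 1L))]
  rows <- list()
  gid <- 0L
  for (p in parts) {
    tx <- vapply(strsplit(p, "\r", fixed = TRUE), `[`, character(1), 1L)
    if (length(unique(tx)) < min_taxa_span) next
    gid <- gid + 1L
    pr <- vapply(strsplit(p, "\r", fixed = TRUE), `[`, character(1), 2L)
    rows[[gid]] <- data.frame(group_id = sprintf("HG%04d", gid),
                              taxon = tx, protein = pr,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), taxon = character(0),
               protein = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
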