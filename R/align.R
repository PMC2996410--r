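#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with affine gap penalties (Gotoh algorithm).
#' Reports the optimal raw score together with the column counts of one
#' optimal alignment: `alignment_columns` counts every column including
#' gap columns (the BLAST "alignment length" convention), and
#' `percent_identity` uses that count as denominator. Ties in the
#' traceback are resolved deterministically (end cell with smallest
#' indices; diagonal preferred over gaps).
#'
#' @param seq_a,seq_b amino-acid strings over the standard 20-letter
#'   alphabet; any other symbol is an error.
#' @param scoring a [scoring_scheme()].
#' @return a list of class `alignment_hit` with elements `score`,
#'   `alignment_columns`, `identical_columns`, `percent_identity` and
#'   `evalue`, or `NULL` ("no hit") when the optimal score is 0 or either
#'   sequence is empty.
#' @export
smith_waterman <- function(seq_a, seq_b, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  a <- aa_encode(seq_a)
  b <- aa_encode(seq_b)
  if (length(a) == 0L || length(b) == 0L) return(NULL)
  # canonical orientation: the optimal score is symmetric, but with
  # several co-optimal alignments the traceback could report different
  # column counts depending on argument order; aligning in a fixed
  # orientation makes the reported statistics symmetric too
  if (seq_a <= seq_b) res <- .sw_align_cpp(a, b, scoring$matrix,
                                           scoring$gap_open,
                                           scoring$gap_extend)
  else res <- .sw_align_cpp(b, a, scoring$matrix, scoring$gap_open,
                            scoring$gap_extend)
  if (res$score <= 0L) return(NULL)
  hit <- list(
    score = res$score,
    alignment_columns = res$columns,
    identical_columns = res$identical,
    percent_identity = 100 * res$identical / res$columns,
    evalue = evalue(res$score, length(a), length(b), scoring)
  )
  class(hit) <- "alignment_hit"
  hit
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf(
    "alignment_hit: score %d, %d columns (%d identical, %.1f%%), E = %.3g\n",
    x$score, x$alignment_columns, x$identical_columns,
    x$percent_identity, x$evalue))
  invisible(x)
}

# raw score matrix (queries x subjects) for named character vectors
sw_score_matrix <- function(queries, subjects, scoring) {
  q <- lapply(unname(queries), aa_encode)
  s <- lapply(unname(subjects), aa_encode)
  m <- .sw_score_matrix_cpp(q, s, scoring$matrix, scoring$gap_open,
                            scoring$gap_extend)
  dimnames(m) <- list(names(queries), names(subjects))
  m
}

#' Best local-alignment hit of a query in a target proteome
#'
#' Aligns the query against every target sequence and returns the hit with
#' the maximal raw score. Ties break by lower E-value, then by
#' lexicographically smallest subject identifier, so the result is
#' deterministic.
#'
#' @param query amino-acid string.
#' @param targets named character vector of target sequences (non-empty).
#' @param scoring a [scoring_scheme()].
#' @param query_id identifier recorded for the query.
#' @return a one-row data.frame with columns `query`, `subject`, `score`,
#'   `alignment_columns`, `identical_columns`, `percent_identity`,
#'   `evalue`, or `NULL` when no target scores above 0.
#' @export
best_hit <- function(query, targets, scoring = scoring_scheme(),
                     query_id = "query") {
  if (length(targets) == 0L) stop("target proteome is empty")
  if (is.null(names(targets)) || anyNA(names(targets)) ||
      any(names(targets) == ""))
    stop("target sequences must be named")
  scores <- drop(sw_score_matrix(setNames(query, query_id), targets, scoring))
  if (max(scores) <= 0L) return(NULL)
  ev <- evalue(scores, nchar(query), nchar(targets), scoring)
  ord <- order(-scores, ev, names(targets), method = "radix")
  subj <- names(targets)[ord[1L]]
  hit <- smith_waterman(query, targets[[subj]], scoring)
  data.frame(query = query_id, subject = subj, score = hit$score,
             alignment_columns = hit$alignment_columns,
             identical_columns = hit$identical_columns,
             percent_identity = hit$percent_identity,
             evalue = hit$evalue, stringsAsFactors = FALSE)
}
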