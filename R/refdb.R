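#' Category-labelled reference ortholog database
#'
#' A stand-in for a COG/NCVOG-style database: a set of ortholog groups,
#' each with a unique group id, a one-letter functional category and at
#' least one member amino-acid sequence.
#'
#' @param groups data.frame with columns `group_id`, `category`.
#' @param members data.frame with columns `group_id`, `member_id`, `seq`.
#' @return an object of class `reference_db`.
#' @export
reference_db <- function(groups, members) {
  stopifnot(is.data.frame(groups), is.data.frame(members),
            all(c("group_id", "category") %in% names(groups)),
            all(c("group_id", "member_id", "seq") %in% names(members)))
  if (anyDuplicated(groups$group_id))
    stop("group ids must be unique")
  if (!all(nchar(groups$category) == 1L))
    stop("categories must be single letters")
  orphan <- setdiff(groups$group_id, members$group_id)
  if (length(orphan))
    stop("groups without members: ", paste(orphan, collapse = ", "))
  if (!all(members$group_id %in% groups$group_id))
    stop("members reference unknown group ids")
  groups <- groups[order(groups$group_id), c("group_id", "category")]
  members <- members[order(members$group_id, members$member_id),
                     c("group_id", "member_id", "seq")]
  rownames(groups) <- rownames(members) <- NULL
  structure(list(groups = groups, members = members),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d groups (%d members), categories: %s\n",
              nrow(x$groups), nrow(x$members),
              paste(sort(unique(x$groups$category)), collapse = " ")))
  invisible(x)
}

#' Restrict a reference database to functional categories
#'
#' Keeps only the ortholog groups whose one-letter category is in
#' `allowed`. The default keeps the informational categories
#' (J translation, A RNA processing, K transcription, L replication and
#' repair, B chromatin) plus nucleotide metabolism (F), the classic
#' informational-gene universe for gene-content comparisons.
#'
#' @param refdb a [reference_db()].
#' @param allowed non-empty character vector of category letters.
#' @return the filtered `reference_db`; warns (not errors) when empty.
#' @export
filter_reference_by_category <- function(refdb,
                                         allowed = c("J", "A", "K", "L",
                                                     "B", "F")) {
  stopifnot(inherits(refdb, "reference_db"))
  if (length(allowed) == 0L) stop("allowed categories must be non-empty")
  keep <- refdb$groups$category %in% allowed
  groups <- refdb$groups[keep, , drop = FALSE]
  members <- refdb$members[refdb$members$group_id %in% groups$group_id, ,
                           drop = FALSE]
  rownames(groups) <- rownames(members) <- NULL
  if (nrow(groups) == 0L)
    warning("no reference groups left after category filter")
  structure(list(groups = groups, members = members),
            class = "reference_db")
}

#' Read / write a reference database
#'
#' On disk a reference database is a `groups.tsv` (columns group_id,
#' category) plus a `members.fasta` whose headers are
#' `>group_id|member_id`.
#'
#' @param groups_path,fasta_path file paths.
#' @return [read_reference_db()] returns a `reference_db`;
#'   `write_reference_db` returns the paths invisibly.
#' @export
read_reference_db <- function(groups_path, fasta_path) {
  groups <- read.delim(groups_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  seqs <- read_fasta(fasta_path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("member FASTA headers must be 'group_id|member_id'")
  members <- data.frame(
    group_id = vapply(parts, `[`, character(1), 1L),
    member_id = vapply(parts, `[`, character(1), 2L),
    seq = unname(seqs), stringsAsFactors = FALSE)
  reference_db(groups, members)
}

#' @rdname read_reference_db
#' @param refdb a [reference_db()].
#' @export
write_reference_db <- function(refdb, groups_path, fasta_path) {
  stopifnot(inherits(refdb, "reference_db"))
  write.table(refdb$groups, groups_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  seqs <- setNames(refdb$members$seq,
                   paste(refdb$members$group_id, refdb$members$member_id,
                         sep = "|"))
  write_fasta(seqs, fasta_path)
  invisible(c(groups_path, fasta_path))
}
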