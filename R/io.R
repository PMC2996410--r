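#' Read and write FASTA protein files
#'
#' Reading goes through Biostrings (tolerating CRLF endings); headers are
#' preserved verbatim as names, sequences are upper-cased, duplicate
#' record ids are an error and an empty file yields an empty vector with
#' a warning. Writing is byte-deterministic: records in input order,
#' sequences wrapped at 60 columns, LF endings.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA record id(s): ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param records named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  if (length(records) && (is.null(names(records)) || anyNA(names(records))))
    stop("records must be named")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con, sep = "\n")
    seq <- records[[i]]
    if (nchar(seq))
      writeLines(substring(seq, seq(1L, nchar(seq), 60L),
                           pmin(seq(1L, nchar(seq), 60L) + 59L, nchar(seq))),
                 con, sep = "\n")
  }
  invisible(path)
}

#' Read and write the binary phyletic matrix as TSV
#'
#' The on-disk format is a TSV with a header row of group ids and a
#' first column (`taxon`) of taxon ids; cells must be "0" or "1".
#' Rows and columns are written sorted, so serialization is
#' deterministic for any input order.
#'
#' @param path file path.
#' @return `read_matrix_tsv()`: taxa x groups integer matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("matrix must have at least one taxon row and one group column")
  taxa <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  bad_flag <- matrix(!(cells %in% c("0", "1")), nrow = nrow(cells))
  bad <- which(bad_flag, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary cell '%s' at row %s (taxon %s), column %s",
                 cells[bad[1L, , drop = FALSE]], bad[1L, 1L],
                 taxa[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]]))
  mat <- matrix(as.integer(cells), nrow = nrow(cells),
                dimnames = list(taxa, colnames(cells)))
  mat[sort(rownames(mat)), sort(colnames(mat)), drop = FALSE]
}

#' @rdname read_matrix_tsv
#' @param matrix taxa x groups 0/1 matrix with dimnames.
#' @export
write_matrix_tsv <- function(matrix, path) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix)))
    stop("matrix must have taxon row names and group column names")
  if (!all(matrix %in% c(0L, 1L))) stop("matrix cells must be 0/1")
  m <- matrix[sort(rownames(matrix)), sort(colnames(matrix)), drop = FALSE]
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_lf(df, path)
  invisible(path)
}

# deterministic TSV writer (LF endings, no quoting)
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

# square distance matrix writer (6-decimal cells, sorted labels)
write_distances_tsv <- function(D, path, digits = 6L) {
  lab <- sort(rownames(D))
  D <- D[lab, lab, drop = FALSE]
  df <- data.frame(taxon = lab,
                   apply(D, 2L, fmt_num, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_lf(df, path)
  invisible(path)
}
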