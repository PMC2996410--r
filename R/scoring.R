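#' Scoring scheme for local protein alignment
#'
#' Bundles a 20x20 integer substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to convert raw scores into
#' E-values. The default is the BLOSUM62 matrix with gap open 11 and gap
#' extend 1, and the gapped-BLASTP parameters lambda = 0.267, K = 0.041 for
#' that penalty combination. A gap of length L costs
#' `gap_open + L * gap_extend` (the first gapped column pays both).
#'
#' @param matrix 20x20 integer substitution matrix with amino-acid
#'   dimnames; must be symmetric. Defaults to BLOSUM62 (from Biostrings).
#' @param gap_open gap opening penalty, a positive integer subtracted once
#'   per gap.
#' @param gap_extend gap extension penalty, a positive integer subtracted
#'   per gapped column.
#' @param lambda_stat,k_stat Karlin-Altschul parameters (> 0) for
#'   `E = K * m * n * exp(-lambda * S)`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda_stat = 0.267, k_stat = 0.041) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  if (!is.matrix(matrix) || nrow(matrix) != 20L || ncol(matrix) != 20L)
    stop("substitution matrix must be 20x20")
  if (is.null(dimnames(matrix)) ||
      !identical(sort(rownames(matrix)), sort(AA_ALPHABET20)))
    stop("substitution matrix must have the 20 amino acids as dimnames")
  matrix <- matrix[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(matrix) <- "integer"
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open < 1L || gap_extend < 1L)
    stop("gap penalties must be positive integers")
  if (!is.finite(lambda_stat) || lambda_stat <= 0)
    stop("lambda_stat must be > 0")
  if (!is.finite(k_stat) || k_stat <= 0)
    stop("k_stat must be > 0")
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         lambda_stat = lambda_stat, k_stat = k_stat),
    class = "scoring_scheme"
  )
}

# BLOSUM62 restricted to the 20 standard residues
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(m) <- "integer"
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme: 20x20 substitution matrix,",
      sprintf("gap open %d / extend %d,", x$gap_open, x$gap_extend),
      sprintf("lambda = %g, K = %g\n", x$lambda_stat, x$k_stat))
  invisible(x)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and subject length `n`: linear in each sequence length and strictly
#' decreasing in the score.
#'
#' @param score non-negative raw alignment score (vectorised).
#' @param query_len,subject_len sequence lengths (>= 1).
#' @param scoring a [scoring_scheme()].
#' @return non-negative numeric E-value(s).
#' @export
evalue <- function(score, query_len, subject_len, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  if (any(score < 0)) stop("score must be >= 0")
  if (any(query_len < 1) || any(subject_len < 1))
    stop("sequence lengths must be >= 1")
  scoring$k_stat * as.double(query_len) * as.double(subject_len) *
    exp(-scoring$lambda_stat * as.double(score))
}
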