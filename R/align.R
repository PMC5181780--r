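#' Pairwise protein alignment with affine gap penalties
#'
#' `global_align()` computes an optimal Needleman-Wunsch global alignment and
#' `local_align()` an optimal Smith-Waterman local alignment, both under an
#' affine gap model in which a gap of length L costs
#' `gap_open + L * gap_extend`. Percent identity is defined over *all*
#' alignment columns, including gap columns, so that the 90% dereplication
#' cutoff used downstream is unambiguous.
#'
#' The dynamic programming itself is delegated to
#' [Biostrings::pairwiseAlignment()]; edmine fixes the scoring conventions
#' (default matrix [edmine_blosum62()], `gap_open = 10`, `gap_extend = 0.5`)
#' and the identity definition. When no residue pair scores positively the
#' local alignment is empty with score 0.
#'
#' @param a,b Protein sequences as plain character strings.
#' @param matrix A substitution matrix, see [substitution_matrix()].
#' @param gap_open,gap_extend Non-negative affine gap penalties.
#' @return An object of class `edmine_alignment`: a list with elements
#'   `aligned_a`, `aligned_b` (gapped strings of equal length), `score`,
#'   `n_identical`, `n_columns` and `identity_pct`
#'   (`100 * n_identical / n_columns`; 0 for an empty local alignment).
#' @examples
#' aln <- global_align("ACDE", "ACDE")
#' aln$score        # 24
#' aln$identity_pct # 100
#' @export
global_align <- function(a, b, matrix = edmine_blosum62(),
                         gap_open = 10, gap_extend = 0.5) {
  align_pair(a, b, matrix, gap_open, gap_extend, type = "global")
}

#' @rdname global_align
#' @export
local_align <- function(a, b, matrix = edmine_blosum62(),
                        gap_open = 10, gap_extend = 0.5) {
  align_pair(a, b, matrix, gap_open, gap_extend, type = "local")
}

align_pair <- function(a, b, matrix, gap_open, gap_extend, type) {
  if (!is_string(a) || !is_string(b) || nchar(a) == 0L || nchar(b) == 0L) {
    stopf("sequences must be non-empty character strings")
  }
  if (gap_open < 0 || gap_extend < 0) stopf("gap penalties must be non-negative")
  check_alphabet(a, matrix, "sequence `a`")
  check_alphabet(b, matrix, "sequence `b`")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = unclass(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = type
  )
  sc <- Biostrings::score(pa)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  if (type == "local" && sc <= 0) {
    sc <- 0
    aligned_a <- ""
    aligned_b <- ""
  }
  new_alignment(aligned_a, aligned_b, sc)
}

new_alignment <- function(aligned_a, aligned_b, score) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  n_columns <- nchar(aligned_a)
  if (n_columns > 0L) {
    ca <- chars(aligned_a)
    cb <- chars(aligned_b)
    n_identical <- sum(ca == cb & ca != "-")
    identity_pct <- 100 * n_identical / n_columns
  } else {
    n_identical <- 0L
    identity_pct <- 0
  }
  structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b, score = score,
         n_identical = n_identical, n_columns = n_columns,
         identity_pct = identity_pct),
    class = "edmine_alignment"
  )
}

#' @export
print.edmine_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment: score %.1f, %d/%d identical (%.1f%%)\n",
              x$score, x$n_identical, x$n_columns, x$identity_pct))
  if (x$n_columns > 0L) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  } else {
    cat("  <empty alignment>\n")
  }
  invisible(x)
}

#' Karlin-Altschul expected hit counts
#'
#' Converts a local alignment score into the expected number of chance hits
#' of at least that score, `E = K * m * n * exp(-lambda * score)`, where the
#' search space `m * n` is the product of the two ungapped sequence lengths
#' (a pairwise, self-contained convention). The default parameters are the
#' standard gapped BLOSUM62 statistics, `lambda = 0.267`, `K = 0.041`.
#'
#' @param score Alignment score (raw units of the substitution matrix).
#' @param len_a,len_b Ungapped lengths of the two sequences (positive).
#' @param params An [evalue_params()] object.
#' @return The expected chance-hit count, a non-negative number, strictly
#'   decreasing in `score` and linear in each length.
#' @examples
#' evalue(0, 100, 100)  # 410
#' @export
evalue <- function(score, len_a, len_b, params = evalue_params()) {
  if (any(len_a <= 0) || any(len_b <= 0)) {
    stopf("sequence lengths must be positive")
  }
  params$k * len_a * len_b * exp(-params$lambda * score)
}

#' @rdname evalue
#' @param lambda Scale parameter in nats per score unit (positive).
#' @param k Search-space correction constant (positive).
#' @export
evalue_params <- function(lambda = 0.267, k = 0.041) {
  if (lambda <= 0 || k <= 0) stopf("lambda and k must be positive")
  structure(list(lambda = lambda, k = k), class = "edmine_evalue_params")
}

# Vectorised local-alignment scores of many patterns against one subject.
# Used by the all-vs-all GNN stage; scores only, no traceback.
local_scores_vs <- function(patterns, subject, matrix, gap_open, gap_extend) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = unclass(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "local", scoreOnly = TRUE
  )
  pmax(sc, 0)
}

# Vectorised global identities of many patterns against one subject.
global_identities_vs <- function(patterns, subject, matrix, gap_open, gap_extend) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = unclass(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  n_id <- Biostrings::nmatch(pa)
  n_col <- nchar(as.character(Biostrings::alignedPattern(pa)))
  100 * n_id / n_col
}
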