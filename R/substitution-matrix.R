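#' Protein substitution matrices
#'
#' A substitution matrix in edmine is a symmetric numeric matrix whose row and
#' column names are the residue alphabet: the 20 standard amino acids plus the
#' ambiguity symbol `X`, which scores 0 against every symbol. Diagonal entries
#' must exceed the row minimum, so self-alignment is always favoured over the
#' worst mismatch.
#'
#' `substitution_matrix()` validates (and completes) a user matrix;
#' `edmine_blosum62()` returns the package default, the standard BLOSUM62
#' scores restricted to the 20 amino acids with an `X` row/column of zeros;
#' `read_substitution_matrix()` parses an NCBI-format matrix text file (the
#' format distributed with BLAST: `#` comments, a header row of symbols, then
#' one labelled row of integers per symbol).
#'
#' @param scores A square numeric matrix with identical row and column names
#'   giving the residue alphabet.
#' @return A validated substitution matrix of class `edmine_submat`.
#' @examples
#' m <- edmine_blosum62()
#' m["A", "A"]  # 4
#' @export
substitution_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stopf("`scores` must be a numeric matrix")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores)) ||
      !identical(rownames(scores), colnames(scores))) {
    stopf("`scores` must have identical row and column names (the alphabet)")
  }
  if (!all(AA20 %in% rownames(scores))) {
    missing <- setdiff(AA20, rownames(scores))
    stopf("alphabet is missing residues: %s", paste(missing, collapse = ", "))
  }
  keep <- c(AA20, "X")
  if (!"X" %in% rownames(scores)) {
    scores <- rbind(cbind(scores[AA20, AA20, drop = FALSE], X = 0), X = 0)
    rownames(scores)[nrow(scores)] <- "X"
  } else {
    scores <- scores[keep, keep, drop = FALSE]
  }
  scores["X", ] <- 0
  scores[, "X"] <- 0
  if (!isTRUE(all.equal(scores, t(scores), check.attributes = FALSE))) {
    stopf("substitution matrix must be symmetric")
  }
  aa <- scores[AA20, AA20, drop = FALSE]
  if (any(diag(aa) <= apply(aa, 1L, min))) {
    stopf("every diagonal entry must exceed its row minimum")
  }
  structure(scores, class = c("edmine_submat", class(unclass(scores))))
}

#' @rdname substitution_matrix
#' @export
edmine_blosum62 <- function() {
  b62 <- get_blosum62_raw()
  substitution_matrix(b62)
}

get_blosum62_raw <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' @rdname substitution_matrix
#' @param path Path to an NCBI-format substitution matrix file.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("not a valid NCBI matrix file: %s", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1L]))
  if (any(vapply(vals, length, 1L) != length(header))) {
    stopf("matrix rows do not match header width in %s", path)
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  substitution_matrix(m)
}

# Check that every residue of `seq` is in the matrix alphabet.
check_alphabet <- function(seq, matrix, arg = "sequence") {
  bad <- setdiff(unique(chars(seq)), rownames(matrix))
  if (length(bad) > 0L) {
    stopf("%s contains symbols outside the matrix alphabet: %s",
          arg, paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
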