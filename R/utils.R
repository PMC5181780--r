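# Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Split a sequence string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

paste0c <- function(x) paste(x, collapse = "")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Reverse complement of a plain DNA character string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a plain DNA string under the bacterial genetic code (table 11).
translate_cds <- function(dna) {
  if (nchar(dna) %% 3L != 0L) {
    stopf("CDS length %d is not a multiple of 3", nchar(dna))
  }
  aa <- Biostrings::translate(Biostrings::DNAString(dna),
                              genetic.code = Biostrings::getGeneticCode("11"),
                              no.init.codon = TRUE)
  aa <- as.character(aa)
  sub("\\*$", "", aa)
}
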