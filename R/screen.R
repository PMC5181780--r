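# In-silico PCR screen.
#
# The wet-lab survey interrogates each strain with two primer pairs bracketing
# E5/E and E/E10; a strain amplifying with both pairs carries the clustered
# E5/E/E10 cassette, one with exactly one product carries a split cassette,
# and one with none is negative. Here the PCR is modelled as primer-site
# matching with a bounded mismatch count (never in the 3' clamp), product
# length windows, and a salt-adjusted GC/length melting temperature as the
# in-silico analogue of the melting-curve peak.

#' Primer definitions
#'
#' @param name Primer name.
#' @param sequence DNA sequence (A/C/G/T, length >= 10, typically 15-30 nt).
#' @param pair_id Identifier of the primer pair (e.g. `"E5_E"`).
#' @param orientation `"fwd"` or `"rev"`: `fwd` anneals to the minus strand
#'   and extends along the plus strand, `rev` the converse.
#' @param max_mismatches Maximum tolerated mismatches; mismatches within the
#'   three 3'-terminal bases (the polymerase clamp) always reject a site.
#' @return An object of class `edmine_primer`.
#' @export
primer <- function(name, sequence, pair_id = NA_character_,
                   orientation = c("fwd", "rev"), max_mismatches = 2L) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) stopf("primer %s: sequence must be A/C/G/T only", name)
  if (nchar(sequence) < 10L) stopf("primer %s: length must be >= 10", name)
  structure(list(name = name, sequence = sequence, pair_id = pair_id,
                 orientation = orientation,
                 max_mismatches = as.integer(max_mismatches)),
            class = "edmine_primer")
}

#' Read primer definitions from a TSV file
#'
#' Expects columns `name`, `sequence`, `pair_id`, `orientation`.
#'
#' @param path TSV path.
#' @param max_mismatches Applied to every primer.
#' @return A list of [primer()] objects.
#' @export
read_primers <- function(path, max_mismatches = 2L) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "sequence", "pair_id", "orientation")
  if (!all(need %in% names(df))) {
    stopf("primer TSV must have columns %s", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    primer(df$name[[i]], df$sequence[[i]], df$pair_id[[i]], df$orientation[[i]],
           max_mismatches)
  })
}

#' Locate primer binding sites in a genome
#'
#' Scans both strands for sites matching the primer with at most
#' `max_mismatches` mismatches, none of which may fall in the three
#' 3'-terminal bases. On the plus strand the site is the primer sequence
#' itself; on the minus strand it is the reverse complement (so the primer's
#' 3' end faces the lower plus-strand coordinate).
#'
#' @param genome Genome sequence as a plain string (or
#'   [Biostrings::DNAString]).
#' @param prm A [primer()].
#' @return Data frame with columns `position` (0-based start of the primer
#'   footprint on the plus strand), `strand` (`"+"`/`"-"`) and
#'   `n_mismatches`, ordered by position. Empty when the primer is longer
#'   than the genome or has no site.
#' @export
find_primer_sites <- function(genome, prm) {
  stopifnot(inherits(prm, "edmine_primer"))
  genome <- as.character(genome)
  if (nchar(genome) == 0L) stopf("genome is empty")
  empty <- data.frame(position = integer(0), strand = character(0),
                      n_mismatches = integer(0))
  if (nchar(prm$sequence) > nchar(genome)) return(empty)
  subj <- Biostrings::DNAString(genome)
  hits <- list(empty)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") prm$sequence else revcomp(prm$sequence)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = prm$max_mismatches)
    if (length(m) == 0L) next
    starts <- Biostrings::start(m) - 1L
    keep <- logical(length(starts))
    nmm <- integer(length(starts))
    pat_chars <- chars(pat)
    L <- length(pat_chars)
    # 3' clamp: last 3 bases of the primer; on the minus strand these map to
    # the first 3 plus-strand positions of the footprint.
    clamp_idx <- if (strand == "+") (L - 2L):L else 1L:3L
    for (j in seq_along(starts)) {
      site <- chars(substr(genome, starts[[j]] + 1L, starts[[j]] + L))
      mism <- which(site != pat_chars)
      nmm[[j]] <- length(mism)
      keep[[j]] <- !any(mism %in% clamp_idx)
    }
    if (!any(keep)) next
    hits[[length(hits) + 1L]] <- data.frame(
      position = starts[keep], strand = strand, n_mismatches = nmm[keep])
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair
#'
#' Pairs every plus-strand site of the forward primer with every downstream
#' minus-strand site of the reverse primer whose product length lies within
#' `[min_len, max_len]`. The amplicon spans the forward primer's 5' start
#' through the reverse primer's 5' start, inclusive of both primer
#' footprints.
#'
#' @param genome Genome string.
#' @param fwd,rev Forward and reverse [primer()]s.
#' @param min_len,max_len Product length window in bp (defaults 300-3000).
#' @param genome_id Identifier recorded in the output.
#' @param na_molar Monovalent cation concentration for [melt_tm()].
#' @return Data frame of amplicon hits: `genome_id`, `pair_id`, `start`,
#'   `end` (0-based half-open), `strand`, `length`, `tm`.
#' @export
amplify <- function(genome, fwd, rev, min_len = 300L, max_len = 3000L,
                    genome_id = NA_character_, na_molar = 0.05) {
  if (min_len > max_len) stopf("min_len (%d) exceeds max_len (%d)", min_len, max_len)
  genome <- as.character(genome)
  fsites <- find_primer_sites(genome, fwd)
  rsites <- find_primer_sites(genome, rev)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  out <- list()
  pair_id <- fwd$pair_id
  for (i in seq_len(nrow(fsites))) {
    for (j in seq_len(nrow(rsites))) {
      start <- fsites$position[[i]]
      end <- rsites$position[[j]] + nchar(rev$sequence)
      len <- end - start
      if (end <= start || len < min_len || len > max_len) next
      amp <- substr(genome, start + 1L, end)
      out[[length(out) + 1L]] <- data.frame(
        genome_id = genome_id, pair_id = pair_id,
        start = start, end = end, strand = "+",
        length = len, tm = melt_tm(amp, na_molar),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty_amplicons())
  do.call(rbind, out)
}

empty_amplicons <- function() {
  data.frame(genome_id = character(0), pair_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             length = integer(0), tm = numeric(0), stringsAsFactors = FALSE)
}

#' Predicted melting temperature of a PCR product
#'
#' Salt-adjusted GC/length formula,
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 (%GC) - 675 / length`,
#' appropriate for products of a few hundred bp and used here as the
#' in-silico surrogate of the melting-curve peak position. Two products are
#' considered distinct peaks when their Tm differ by at least 0.5 degrees C.
#'
#' @param amplicon DNA string of length >= 14.
#' @param na_molar Monovalent cation molarity (default 0.05).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melt_tm(paste(rep("ACGT", 25), collapse = ""))  # 100 bp, 50% GC -> 73.65
#' @export
melt_tm <- function(amplicon, na_molar = 0.05) {
  if (na_molar <= 0) stopf("`na_molar` must be positive")
  len <- nchar(amplicon)
  if (len < 14L) stopf("amplicon shorter than 14 bp")
  cc <- chars(toupper(amplicon))
  gc_pct <- 100 * sum(cc %in% c("G", "C")) / len
  81.5 + 16.6 * log10(na_molar) + 0.41 * gc_pct - 675 / len
}

#' Call cassette architecture from amplification flags
#'
#' @param e5_e,e_e10 Logical: did the E5/E (resp. E/E10) pair amplify?
#' @return `"clustered"` when both did, `"split"` when exactly one,
#'   `"negative"` when neither.
#' @export
call_architecture <- function(e5_e, e_e10) {
  ifelse(e5_e & e_e10, "clustered", ifelse(e5_e | e_e10, "split", "negative"))
}

#' Screen a genome collection with primer pairs
#'
#' Runs [amplify()] on every genome for the `E5_E` and `E_E10` pairs (and any
#' further pairs present, e.g. `E_internal`, whose products are reported but
#' do not enter the architecture call), then calls the cassette architecture
#' per strain.
#'
#' @param genomes Named character vector of genome sequences.
#' @param primers A list of [primer()]s (see [read_primers()],
#'   [default_primers()]); a data frame in the primer-TSV layout is also
#'   accepted.
#' @param min_len,max_len Product length window.
#' @param max_mismatches Mismatch tolerance applied to all primers.
#' @param na_molar Salt concentration for Tm prediction.
#' @return An object of class `edmine_screen`: list with `calls` (per-strain
#'   data frame: `strain_id`, `e5_e`, `e_e10`, `architecture`) and
#'   `amplicons` (all amplicon hits).
#' @export
screen_cohort <- function(genomes, primers = default_primers(),
                          min_len = 300L, max_len = 3000L,
                          max_mismatches = 2L, na_molar = 0.05) {
  if (is.data.frame(primers)) {
    primers <- lapply(seq_len(nrow(primers)), function(i) {
      primer(primers$name[[i]], primers$sequence[[i]], primers$pair_id[[i]],
             primers$orientation[[i]], max_mismatches)
    })
  } else {
    primers <- lapply(primers, function(p) { p$max_mismatches <- as.integer(max_mismatches); p })
  }
  pair_ids <- unique(vapply(primers, `[[`, "", "pair_id"))
  pairs <- lapply(pair_ids, function(pid) {
    ps <- primers[vapply(primers, function(p) identical(p$pair_id, pid), TRUE)]
    ors <- vapply(ps, `[[`, "", "orientation")
    if (!setequal(ors, c("fwd", "rev"))) {
      stopf("primer pair %s must have one fwd and one rev primer", pid)
    }
    list(fwd = ps[[which(ors == "fwd")]], rev = ps[[which(ors == "rev")]])
  })
  names(pairs) <- pair_ids

  amps <- list()
  calls <- lapply(names(genomes), function(sid) {
    got <- setNames(logical(length(pair_ids)), pair_ids)
    for (pid in pair_ids) {
      a <- amplify(genomes[[sid]], pairs[[pid]]$fwd, pairs[[pid]]$rev,
                   min_len, max_len, genome_id = sid, na_molar = na_molar)
      if (nrow(a) > 0L) amps[[length(amps) + 1L]] <<- a
      got[[pid]] <- nrow(a) > 0L
    }
    e5e <- isTRUE(got[["E5_E"]])
    ee10 <- isTRUE(got[["E_E10"]])
    data.frame(strain_id = sid, e5_e = e5e, e_e10 = ee10,
               architecture = call_architecture(e5e, ee10),
               stringsAsFactors = FALSE)
  })
  amplicons <- if (length(amps) > 0L) do.call(rbind, amps) else empty_amplicons()
  structure(list(calls = do.call(rbind, calls), amplicons = amplicons),
            class = "edmine_screen")
}

#' @export
print.edmine_screen <- function(x, ...) {
  tab <- table(factor(x$calls$architecture, c("clustered", "split", "negative")))
  cat(sprintf("In-silico screen: %d strains surveyed, %d hits (%d clustered, %d split), %d negative\n",
              nrow(x$calls), sum(x$calls$architecture != "negative"),
              tab[["clustered"]], tab[["split"]], tab[["negative"]]))
  invisible(x)
}
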