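# Dereplication of screening hits.
#
# Hits are compared through the translated 1-kb internal fragment of the E
# (enediyne PKS) gene: a pairwise percent-identity matrix is computed with the
# global aligner, a neighbor-joining tree summarises the relationships, and
# hits are collapsed into clades at a 90% amino-acid identity cutoff so that
# only one representative per clade need be pursued.

#' Extract the internal fragment of an E-gene CDS
#'
#' Returns the centred, frame-preserving window of the CDS (default 999 bp,
#' i.e. the "1-kb internal fragment"): the start offset is rounded down to a
#' codon boundary and a non-multiple-of-3 window is rounded down to one, with
#' a warning.
#'
#' @param e_gene CDS DNA string (length a multiple of 3, at least
#'   `window_bp + 6`).
#' @param window_bp Window size in bp (default 999).
#' @return The DNA fragment (character).
#' @export
extract_internal_fragment <- function(e_gene, window_bp = 999L) {
  e_gene <- as.character(e_gene)
  len <- nchar(e_gene)
  if (window_bp %% 3L != 0L) {
    old <- window_bp
    window_bp <- (window_bp %/% 3L) * 3L
    warnf("window of %d bp is not a whole number of codons; using %d bp", old, window_bp)
  }
  if (len < window_bp + 6L) {
    stopf("CDS of %d bp is too short for a %d-bp internal window; reduce `window_bp`",
          len, window_bp)
  }
  offset <- (((len - window_bp) %/% 2L) %/% 3L) * 3L
  substr(e_gene, offset + 1L, offset + window_bp)
}

#' Pairwise percent-identity matrix over protein fragments
#'
#' Globally aligns every unordered pair (affine gaps, see [global_align()])
#' and records percent identity over all alignment columns, gap columns
#' included.
#'
#' @param fragments Named character vector of protein fragments (>= 2).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return A symmetric numeric matrix with a diagonal of 100 and
#'   `dimnames` equal to the fragment names.
#' @export
identity_matrix <- function(fragments, matrix = edmine_blosum62(),
                            gap_open = 10, gap_extend = 0.5) {
  if (length(fragments) < 2L) stopf("need at least 2 fragments")
  if (is.null(names(fragments)) || anyDuplicated(names(fragments))) {
    stopf("fragments must have unique names")
  }
  if (any(!nzchar(fragments))) stopf("empty fragment(s) present")
  for (nm in names(fragments)) check_alphabet(fragments[[nm]], matrix, nm)
  n <- length(fragments)
  m <- diag(100, n)
  dimnames(m) <- list(names(fragments), names(fragments))
  for (j in 2:n) {
    idents <- global_identities_vs(fragments[seq_len(j - 1L)], fragments[[j]],
                                   matrix, gap_open, gap_extend)
    m[seq_len(j - 1L), j] <- idents
    m[j, seq_len(j - 1L)] <- idents
  }
  m
}

#' Neighbor-joining tree from an identity matrix
#'
#' Converts identities to p-distances, `d = (100 - identity) / 100`
#' (optionally Poisson-corrected, `-log(1 - p)`), and builds a Saitou-Nei
#' neighbor-joining tree. Negative branch-length estimates are clamped to
#' zero with the deficit moved to the sibling edge, preserving path lengths
#' through the parent node.
#'
#' @param matrix Symmetric identity matrix (see [identity_matrix()]), >= 3
#'   strains.
#' @param correction `"none"` (p-distance, default) or `"poisson"`.
#' @return An [ape::phylo] tree with non-negative branch lengths.
#' @export
nj_tree <- function(matrix, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (nrow(matrix) < 3L) stopf("neighbor joining needs at least 3 strains")
  d <- (100 - matrix) / 100
  if (correction == "poisson") d <- -log(pmax(1 - d, .Machine$double.eps))
  diag(d) <- 0
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

# Set negative edge lengths to zero, transferring the deficit to the sibling
# edge under the same parent (standard NJ post-processing).
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  parents <- tree$edge[, 1L]
  for (i in order(el)) {
    if (el[[i]] >= 0) next
    sibs <- setdiff(which(parents == parents[[i]]), i)
    if (length(sibs) > 0L) {
      el[[sibs[[1L]]]] <- el[[sibs[[1L]]]] + el[[i]]
    }
    el[[i]] <- 0
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Collapse strains into clades at an identity cutoff
#'
#' Builds the graph whose edges join strain pairs with identity at or above
#' the cutoff and returns its connected components (single linkage: the
#' transitive closure of the >= cutoff relation), or complete-linkage
#' clusters cut at the same height.
#'
#' @param matrix Identity matrix.
#' @param cutoff Percent identity cutoff in `(0, 100]` (default 90, the
#'   dereplication cutoff).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return An object of class `edmine_clades`: list with `clade` (named
#'   integer vector, clade ids dense from 1 in order of first strain),
#'   `cutoff`, `linkage` and `n_clades`.
#' @export
collapse_clades <- function(matrix, cutoff = 90, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (cutoff <= 0 || cutoff > 100) stopf("`cutoff` must lie in (0, 100]")
  strains <- rownames(matrix)
  if (linkage == "single") {
    adj <- matrix >= cutoff
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    d <- stats::as.dist(100 - matrix)
    hc <- stats::hclust(d, method = "complete")
    memb <- stats::cutree(hc, h = 100 - cutoff)
  }
  ids <- unique(memb[strains])
  clade <- setNames(match(memb[strains], ids), strains)
  structure(list(clade = clade, cutoff = cutoff, linkage = linkage,
                 n_clades = max(clade)),
            class = "edmine_clades")
}

#' @export
print.edmine_clades <- function(x, ...) {
  cat(sprintf("Clade partition: %d strains collapsed into %d clades at %.0f%% identity (%s linkage)\n",
              length(x$clade), x$n_clades, x$cutoff, x$linkage))
  invisible(x)
}

#' Choose one representative strain per clade
#'
#' Per clade, the medoid: the strain maximising summed identity to its clade
#' mates, ties broken by lexicographic strain id.
#'
#' @param partition An [collapse_clades()] result.
#' @param matrix The identity matrix the partition was derived from.
#' @return Named character vector, clade id -> representative strain id.
#' @export
pick_representatives <- function(partition, matrix) {
  stopifnot(inherits(partition, "edmine_clades"))
  vapply(seq_len(partition$n_clades), function(cid) {
    members <- sort(names(partition$clade)[partition$clade == cid])
    if (length(members) == 1L) return(members)
    sums <- vapply(members, function(s) sum(matrix[s, setdiff(members, s)]), 0)
    members[[which.max(sums)]]  # which.max takes the first, hence lexicographic ties
  }, "")
}
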