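# Independent oracles used across the suite. These re-derive alignment
# scores, clade partitions and tree topologies by different routes than the
# package implementation.

ORACLE_AA4 <- c("A", "C", "G", "T")  # 4-letter reduced alphabet (valid residues)

AA20_test <- function() c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(len, alphabet = ORACLE_AA4) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Plain-R Gotoh dynamic program (affine gaps: a gap of length L costs
# open + L * ext), scores only. Independent of the package's alignment path.
oracle_align_score <- function(a, b, S, open, ext, type = c("global", "local")) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  local <- type == "local"
  if (!local) {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local) M[i, j] <- max(M[i, j], s)
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every gapped global alignment (all monotone move
# sequences), scoring affine gap runs directly. Exponential; tiny inputs only.
oracle_enumerate_global <- function(a, b, S, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  recur <- function(i, j, score, state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      recur(i + 1, j + 1, score + S[A[i], B[j]], "M")
    }
    if (i <= length(A)) {
      pen <- if (state == "X") ext else open + ext
      recur(i + 1, j, score - pen, "X")
    }
    if (j <= length(B)) {
      pen <- if (state == "Y") ext else open + ext
      recur(i, j + 1, score - pen, "Y")
    }
  }
  recur(1, 1, 0, "M")
  best
}

# Local score as the best global score over all substring pairs (including
# the empty alignment, score 0). Exponential via the enumerator; tiny only.
oracle_enumerate_local <- function(a, b, S, open, ext) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      best <- max(best, oracle_enumerate_global(substr(a, i1, i2),
                                                substr(b, j1, j2), S, open, ext))
    }
  }
  best
}

# Reduced substitution matrix over the oracle alphabet, from the package default.
oracle_submat <- function() {
  m <- edmine_blosum62()
  unclass(m)[ORACLE_AA4, ORACLE_AA4]
}

# Random additive distance matrix from a random binary tree with positive
# branch lengths; returns the matrix and the generating tree.
random_additive_matrix <- function(n_taxa, scale = 0.05) {
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.02, 1) * scale)
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tree)
}

# Do two trees share the same unrooted topology?
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[[1]] == 0
}

# Single-linkage partition by brute-force transitive closure (no graph code).
oracle_single_linkage <- function(identity, cutoff) {
  n <- nrow(identity)
  clade <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (identity[i, j] >= cutoff && clade[i] != clade[j]) {
        clade[clade == clade[j]] <- clade[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(match(clade, unique(clade)), rownames(identity))
}

# Adjusted Rand Index between two labelled partitions over the same names.
partition_ari <- function(p1, p2) {
  mclust::adjustedRandIndex(p1[names(p1)], p2[names(p1)])
}

# Relabelling-invariant equality of two partitions (co-membership identity);
# well defined even for degenerate one-block partitions, where ARI is 0/0.
partition_equal <- function(p1, p2) {
  p2 <- p2[names(p1)]
  identical(outer(p1, p1, "=="), outer(p2, p2, "=="))
}

# Small demo cohort shared by several test files.
demo_cohort <- function(seed = 42L, ...) {
  generate_cohort(simulation_config(seed = seed, ...))
}

# Ungapped percent identity of two equal-length sequences.
ungapped_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}
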