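# Dereplication: internal fragment extraction, identity matrix,
# neighbor-joining tree, clade collapsing, representatives.

test_that("internal fragment window is centred and frame-preserving", {
  set.seed(71)
  cds <- random_seq(3000, c("A", "C", "G", "T"))
  frag <- extract_internal_fragment(cds, 999L)
  expect_equal(nchar(frag), 999L)
  # centring: (3000 - 999) / 2 = 1000.5, rounded down to codon boundary 999
  expect_identical(frag, substr(cds, 1000, 1998))

  # boundary: window equal to CDS length minus two codons
  cds2 <- random_seq(300, c("A", "C", "G", "T"))
  expect_equal(nchar(extract_internal_fragment(cds2, 294L)), 294L)

  expect_warning(f <- extract_internal_fragment(cds, 1000L), "codons")
  expect_equal(nchar(f), 999L)
  expect_error(extract_internal_fragment(random_seq(900, c("A", "C", "G", "T")), 999L),
               "reduce")
})

test_that("identity matrices are symmetric with the expected entries", {
  frags <- c(a = "MKVLAWFEDQ", b = "MKVLAWFEDQ", c = "MKVLAWFEDQ")
  m <- identity_matrix(frags)
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_true(all(m == 100))

  set.seed(72)
  ref <- random_seq(200, AA20_test())
  frags2 <- c(x = ref, y = evolve_protein(ref, 0.90, seed = 1L))
  m2 <- identity_matrix(frags2)
  expect_equal(m2, t(m2))
  # substitution-only evolution: global alignment recovers the planted identity
  expect_equal(m2["x", "y"], 90, tolerance = 0.02)

  expect_error(identity_matrix(c(a = "MK")), "at least 2")
  expect_error(identity_matrix(c(a = "MK", b = "")), "empty")
})

test_that("neighbor joining recovers a hand-computed 4-taxon additive split", {
  # additive distances: d(A,B)=3, d(C,D)=7, d(A,C)=6, d(A,D)=7, d(B,C)=7,
  # d(B,D)=8, scaled into identity space. Unique tree: AB|CD with internal
  # edge 2 (A=1, B=2, C=3, D=4 pendant lengths).
  d <- matrix(c(0, 3, 6, 7,
                3, 0, 7, 8,
                6, 7, 0, 7,
                7, 8, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  idm <- 100 - d  # distances in percent -> nj_tree rescales by /100
  tree <- nj_tree(idm)
  expect_s3_class(tree, "phylo")
  truth <- ape::read.tree(text = "((A:0.01,B:0.02):0.02,C:0.03,D:0.04);")
  expect_true(same_topology(tree, truth))
  # branch lengths reproduce the additive metric (scaled by 1/100)
  expect_equal(ape::cophenetic.phylo(tree)[c("A", "B", "C", "D"), c("A", "B", "C", "D")],
               d / 100, tolerance = 1e-9)

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(100 - d3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["A", "B"], 0.02, tolerance = 1e-9)
  expect_equal(cp["A", "C"], 0.04, tolerance = 1e-9)

  expect_error(nj_tree(matrix(100, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
})

test_that("neighbor joining reconstructs random additive topologies", {
  set.seed(73)
  for (r in 1:30) {
    n <- sample(5:8, 1)
    gen <- random_additive_matrix(n)
    idm <- 100 * (1 - gen$d)
    tree <- nj_tree(idm)
    expect_true(same_topology(tree, gen$tree))
  }
})

test_that("trees have non-negative branch lengths and round-trip via Newick", {
  co <- demo_cohort(seed = 55L)
  frags <- vapply(co$clusters, function(cl) {
    e <- cl$orfs[which(cl$orfs$label %in% "E"), ]
    cds <- substr(co$genomes[[cl$cluster_id]], e$start + 1L, e$end)
    as.character(Biostrings::translate(
      Biostrings::DNAString(extract_internal_fragment(cds)),
      genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
  }, "")
  tree <- nj_tree(identity_matrix(frags))
  expect_true(all(tree$edge.length >= 0))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, path)
  back <- ape::read.tree(path)
  expect_true(same_topology(tree, back))
  reord <- match(back$tip.label, tree$tip.label)
  expect_equal(sort(back$edge.length), sort(tree$edge.length), tolerance = 1e-9)
})

test_that("clade collapsing equals single-linkage closure of the cutoff graph", {
  m <- matrix(c(100, 95, 50,
                95, 100, 50,
                50, 50, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- collapse_clades(m, 90)
  expect_equal(unname(p$clade[c("A", "B", "C")]), c(1L, 1L, 2L))
  expect_equal(p$n_clades, 2L)

  # all below cutoff: singletons; near-zero cutoff: one clade
  expect_equal(collapse_clades(m, 99)$n_clades, 3L)
  expect_equal(collapse_clades(m, 1e-6)$n_clades, 1L)
  expect_error(collapse_clades(m, 0), "\\(0, 100\\]")
  expect_error(collapse_clades(m, 101), "\\(0, 100\\]")

  # random matrices: agreement with a brute-force transitive-closure oracle,
  # and monotone nesting when the cutoff is raised
  set.seed(74)
  for (r in 1:15) {
    n <- sample(4:9, 1)
    idm <- matrix(runif(n * n, 0, 100), n, n)
    idm <- (idm + t(idm)) / 2
    diag(idm) <- 100
    dimnames(idm) <- list(letters[1:n], letters[1:n])
    cutoff <- runif(1, 20, 95)
    p1 <- collapse_clades(idm, cutoff)
    expect_true(partition_equal(p1$clade, oracle_single_linkage(idm, cutoff)))
    p2 <- collapse_clades(idm, min(cutoff + runif(1, 1, 20), 100))
    # raising the cutoff only refines: every higher-cutoff clade stays within
    # one lower-cutoff clade
    for (cid in unique(p2$clade)) {
      members <- names(p2$clade)[p2$clade == cid]
      expect_length(unique(p1$clade[members]), 1L)
    }
  }
})

test_that("representatives are clade medoids with lexicographic ties", {
  m <- matrix(c(100, 92, 91, 10,
                92, 100, 95, 10,
                91, 95, 100, 10,
                10, 10, 10, 100), 4, 4,
              dimnames = list(c("a", "b", "c", "z"), c("a", "b", "c", "z")))
  p <- collapse_clades(m, 90)
  reps <- pick_representatives(p, m)
  # b maximises summed identity (92 + 95 = 187) within {a,b,c}
  expect_equal(unname(reps), c("b", "z"))

  # symmetric two-strain clade: lexicographically first
  m2 <- matrix(c(100, 95, 95, 100), 2, 2, dimnames = list(c("y", "x"), c("y", "x")))
  p2 <- collapse_clades(m2, 90)
  expect_equal(unname(pick_representatives(p2, m2)), "x")
})
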