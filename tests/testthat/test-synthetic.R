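# Synthetic cohort generator: evolution model, reverse translation, cassette
# layout and cohort-level identity structure.

test_that("evolve_protein substitutes exactly the prescribed number of positions", {
  set.seed(1)
  ref <- random_seq(1000, AA20_test())
  out <- evolve_protein(ref, 0.90, seed = 7L)
  expect_equal(ungapped_identity(ref, out), 90)
  expect_equal(nchar(out), nchar(ref))

  expect_identical(evolve_protein(ref, 1.0, seed = 3L), ref)
  expect_identical(evolve_protein(ref, 0.5, seed = 9L),
                   evolve_protein(ref, 0.5, seed = 9L))
  expect_false(identical(evolve_protein(ref, 0.5, seed = 9L),
                         evolve_protein(ref, 0.5, seed = 10L)))

  # every substituted position differs from the original
  ev <- evolve_protein(ref, 0.7, seed = 2L)
  diff_pos <- which(strsplit(ref, "")[[1]] != strsplit(ev, "")[[1]])
  expect_length(diff_pos, round(0.3 * nchar(ref)))

  # protected positions are never touched
  prot <- 1:50
  ev2 <- evolve_protein(ref, 0.2, seed = 5L, protect = prot)
  expect_identical(substr(ev2, 1, 50), substr(ref, 1, 50))

  expect_error(evolve_protein("", 0.9, seed = 1L), "non-empty")
  expect_error(evolve_protein(ref, 1.5, seed = 1L), "\\[0, 1\\]")
})

test_that("reverse translation round-trips under genetic code table 11", {
  expect_equal(reverse_translate("M", seed = 1L), "ATG")
  expect_equal(reverse_translate("W", seed = 1L), "TGG")
  expect_error(reverse_translate("MA*K", seed = 1L), "stop")

  gc11 <- Biostrings::getGeneticCode("11")
  set.seed(5)
  for (r in 1:10) {
    p <- random_seq(sample(10:200, 1), AA20_test())
    dna <- reverse_translate(p, seed = r)
    back <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                               genetic.code = gc11,
                                               no.init.codon = TRUE))
    expect_identical(back, p)
  }
  p <- random_seq(60, AA20_test())
  expect_identical(reverse_translate(p, seed = 4L), reverse_translate(p, seed = 4L))
})

test_that("cassette layout obeys ring class, architecture and moieties", {
  refs <- ref_proteins()[c("E3", "E4", "E5", "E", "E10")]

  plan <- build_cassette(refs, "nine", "clustered", character(0), seed = 1L)
  expect_true("E2" %in% plan$label)
  expect_false("R3" %in% plan$label)
  i <- match(c("E5", "E", "E10"), plan$label)
  expect_equal(diff(i), c(1L, 1L))  # contiguous in genomic order
  expect_true(all(plan$spacer_before[i[-1]] <= 500L))

  plan10 <- build_cassette(refs, "ten", "split_E5", character(0), seed = 2L)
  expect_true("R3" %in% plan10$label)
  expect_false("E2" %in% plan10$label)
  # >= 10 kb separates the moved E5 from everything else
  i5 <- match("E5", plan10$label)
  expect_gte(plan10$spacer_before[i5], 10000L)

  plan_apo <- build_cassette(refs, "nine", "clustered", "apoprotein", seed = 3L)
  expect_equal(sum(plan_apo$label == "apoprotein"), 1L)

  expect_error(build_cassette(refs, "nine", "circular", character(0), seed = 1L),
               "architecture")
  expect_error(build_cassette(refs[1:3], "nine", "clustered", character(0), seed = 1L),
               "cassette proteins")
})

test_that("cohort structure echoes the configuration and is seed-deterministic", {
  co <- demo_cohort(seed = 101L)
  expect_length(co$genomes, 14L)
  expect_equal(sum(co$truth$is_producer), 9L)
  expect_equal(length(unique(na.omit(co$truth$clade_id))), 3L)
  expect_equal(unname(table(na.omit(co$truth$clade_id))), c(4L, 3L, 2L),
               ignore_attr = TRUE)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co, d1)
  write_cohort(demo_cohort(seed = 101L), d2)
  f1 <- list.files(file.path(d1, "genomes"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "genomes"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_false(identical(demo_cohort(seed = 102L)$genomes[[1]], co$genomes[[1]]))

  expect_error(simulation_config(n_strains = 5, n_producer_clades = 2,
                                 strains_per_clade = c(4, 3), seed = 1L),
               "exceeding")
  expect_error(simulation_config(seed = 1L, within_clade_identity = 1.2), "\\[0, 1\\]")
})

test_that("planted coordinates index substrings translating to the planted proteins", {
  co <- demo_cohort(seed = 77L)
  gc11 <- Biostrings::getGeneticCode("11")
  for (sid in names(co$clusters)) {
    orfs <- co$clusters[[sid]]$orfs
    genome <- co$genomes[[sid]]
    for (i in seq_len(nrow(orfs))) {
      cds <- substr(genome, orfs$start[i] + 1L, orfs$end[i])
      if (orfs$strand[i] == "-") {
        cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      }
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               genetic.code = gc11,
                                               no.init.codon = TRUE))
      expect_identical(aa, orfs$protein[i])
    }
  }
})

test_that("realized fragment identities respect the configured clade structure", {
  cfg <- simulation_config(
    n_strains = 9, n_producer_clades = 3, strains_per_clade = c(3, 3, 3),
    within_clade_identity = 0.95, between_clade_identity = c(0.40, 0.60),
    seed = 300L
  )
  co <- generate_cohort(cfg)
  frags <- vapply(co$clusters, function(cl) {
    e <- cl$orfs[which(cl$orfs$label %in% "E"), ]
    cds <- substr(co$genomes[[cl$cluster_id]], e$start + 1L, e$end)
    as.character(Biostrings::translate(
      Biostrings::DNAString(extract_internal_fragment(cds)),
      genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
  }, "")
  idm <- identity_matrix(frags)
  clade <- setNames(co$truth$clade_id, co$truth$strain_id)[names(frags)]
  same <- outer(clade, clade, "==") & upper.tri(idm)
  within <- idm[same]
  between <- idm[!outer(clade, clade, "==") & upper.tri(idm)]
  # within-clade pairs concentrate near the 95% target; binomial placement
  # noise over a 333-residue fragment justifies a few points of slack
  expect_true(all(within > 90))
  expect_lt(abs(mean(within) - 95), 2)
  # between-clade pairs fall in the configured band (same slack)
  expect_true(all(between > 35 & between < 65))
  expect_true(all(between < 90))
})
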