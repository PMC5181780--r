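# Genome neighborhood network: all-vs-all scoring, thresholded graph,
# family detection, annotation transfer and cluster similarity.

# a cluster of `n` mutually unrelated proteins (fixed composition shuffles)
make_cluster <- function(id, n, len = 150, seed = 1, labels = NULL, source = "hit") {
  set.seed(seed)
  prots <- replicate(n, random_seq(len, AA20_test()))
  orfs <- data.frame(
    orf_id = sprintf("o%02d", seq_len(n)),
    start = seq(0L, by = len * 3L + 100L, length.out = n),
    end = seq(0L, by = len * 3L + 100L, length.out = n) + len * 3L,
    strand = "+", protein = prots,
    label = if (is.null(labels)) NA_character_ else labels,
    stringsAsFactors = FALSE
  )
  gene_cluster(id, orfs, source = source)
}

test_that("a duplicated ten-gene cluster yields exactly ten two-member families", {
  c1 <- make_cluster("dupA", 10, seed = 91)
  c2 <- c1; c2$cluster_id <- "dupB"
  pairs <- all_vs_all(list(c1, c2))
  g <- build_gnn(pairs, 1e-6)
  fams <- detect_families(g)
  sizes <- table(fams$assignment$family_id)
  expect_length(sizes, 10L)
  expect_true(all(sizes == 2L))
  # each family pairs an orf with its own duplicate
  a <- fams$assignment
  for (fid in unique(a$family_id)) {
    expect_length(unique(a$orf_id[a$family_id == fid]), 1L)
  }
  # every node has at least one partner in a duplicated cohort
  expect_true(all(igraph::degree(g) >= 1))
})

test_that("unrelated proteins stay unconnected at the working threshold", {
  c1 <- make_cluster("solo", 12, len = 100, seed = 92)
  pairs <- all_vs_all(list(c1))
  # random-composition pairs are far from significance
  if (nrow(pairs$pairs) > 0) expect_true(all(pairs$pairs$evalue > 1e-6))
  g <- build_gnn(pairs, 1e-6)
  fams <- detect_families(g)
  expect_equal(length(unique(fams$assignment$family_id)), 12L)
  lab <- annotate_families(fams)
  expect_true(all(lab$assignment$label == "singleton"))
})

test_that("stricter thresholds give nested edge sets and nested families", {
  co <- demo_cohort(seed = 93L)
  clusters <- c(reference_clusters(), unname(co$clusters[1:4]))
  pairs <- all_vs_all(clusters)
  g_loose <- build_gnn(pairs, 1e-6)
  g_strict <- build_gnn(pairs, 1e-75)
  e_loose <- igraph::as_data_frame(g_loose, "edges")
  e_strict <- igraph::as_data_frame(g_strict, "edges")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true(all(key(e_strict) %in% key(e_loose)))
  expect_true(all(e_loose$evalue <= 1e-6))

  f_loose <- detect_families(g_loose)$assignment
  f_strict <- detect_families(g_strict)$assignment
  # every strict family lies inside exactly one loose family
  for (fid in unique(f_strict$family_id)) {
    nodes <- f_strict$node[f_strict$family_id == fid]
    expect_length(unique(f_loose$family_id[match(nodes, f_loose$node)]), 1L)
  }
  expect_error(build_gnn(pairs, 0), "positive")
})

test_that("the strict pass separates the E2/E3/R3 marker subfamilies", {
  co <- generate_cohort(simulation_config(
    n_strains = 4, n_producer_clades = 4, strains_per_clade = rep(1L, 4),
    ring_class_per_clade = c("nine", "ten", "nine", "ten"), seed = 94L))
  clusters <- c(reference_clusters(), unname(co$clusters))
  pairs <- all_vs_all(clusters)
  g <- build_gnn(pairs, 1e-6)
  plain <- annotate_families(detect_families(g))$assignment
  # at the loose threshold the E2/E3/R3 homologs merge into one family
  marker_nodes <- plain$node[!is.na(plain$ref_label) &
                               plain$ref_label %in% c("E2", "E3", "R3")]
  expect_length(unique(plain$family_id[match(marker_nodes, plain$node)]), 1L)

  refined <- annotate_families(detect_families(g, pairs, strict_threshold = 1e-75))
  a <- refined$assignment
  fam_of <- function(lab) unique(a$family_id[!is.na(a$ref_label) & a$ref_label == lab])
  expect_length(fam_of("E2"), 1L)
  expect_length(fam_of("R3"), 1L)
  expect_length(fam_of("E3"), 1L)
  expect_gt(length(unique(a$family_id[match(marker_nodes, a$node)])), 1L)
  # labels follow the references through the refinement
  planted <- a[a$source == "hit" & !is.na(a$ref_label), ]
  expect_equal(planted$label, planted$ref_label)
})

test_that("family labels transfer by majority with deterministic ties", {
  fam <- function(nodes, labels, sources, fid) {
    data.frame(node = nodes, cluster_id = "c", orf_id = nodes,
               ref_label = labels, source = sources, family_id = fid,
               stringsAsFactors = FALSE)
  }
  a <- rbind(
    fam(c("n1", "n2", "n3"), c("E3", "E3", "E2"), rep("reference", 3), 1L),
    fam(c("n4", "n5"), c(NA, NA), c("hit", "hit"), 2L),
    fam("n6", NA, "hit", 3L),
    fam("n7", "E5", "reference", 4L)
  )
  fams <- structure(list(assignment = a, threshold = 1e-6, strict_threshold = NULL),
                    class = "edmine_families")
  lab <- annotate_families(fams)
  expect_equal(unname(lab$family_labels[c("1", "2", "3", "4")]),
               c("E3", "unknown_family", "singleton", "E5"))
})

test_that("profiles conserve ORF counts and similarity behaves at the extremes", {
  co <- demo_cohort(seed = 95L)
  clusters <- c(reference_clusters(), unname(co$clusters[1:3]))
  pairs <- all_vs_all(clusters)
  fams <- annotate_families(detect_families(build_gnn(pairs, 1e-6), pairs, 1e-75))
  prof <- cluster_profile(fams)
  orf_counts <- vapply(clusters, function(cl) nrow(cl$orfs), 0L)
  names(orf_counts) <- vapply(clusters, `[[`, "", "cluster_id")
  expect_equal(rowSums(prof)[names(orf_counts)], orf_counts)

  sim <- cluster_similarity(prof)
  expect_equal(unname(diag(sim$jaccard)), rep(1, nrow(prof)))
  expect_equal(sim$jaccard, t(sim$jaccard))
  expect_true(all(sim$shared >= 0))

  # disjoint clusters: zero overlap
  d1 <- make_cluster("d1", 3, seed = 96)
  d2 <- make_cluster("d2", 3, seed = 97)
  p2 <- all_vs_all(list(d1, d2))
  f2 <- annotate_families(detect_families(build_gnn(p2, 1e-6)))
  s2 <- cluster_similarity(cluster_profile(f2))
  expect_equal(s2$shared["d1", "d2"], 0)
  expect_equal(s2$jaccard["d1", "d2"], 0)
})

test_that("family detection is invariant to cluster input order", {
  co <- demo_cohort(seed = 98L)
  clusters <- c(reference_clusters(), unname(co$clusters[1:3]))
  run <- function(cl) {
    pairs <- all_vs_all(cl)
    a <- annotate_families(detect_families(build_gnn(pairs, 1e-6), pairs, 1e-75))$assignment
    a[order(a$node), c("node", "label")]
  }
  a1 <- run(clusters)
  a2 <- run(rev(clusters))
  expect_equal(a1$node, a2$node)
  expect_equal(a1$label, a2$label)
})

test_that("GNN exports are written and the edge list matches the graph", {
  c1 <- make_cluster("dupA", 4, seed = 99)
  c2 <- c1; c2$cluster_id <- "dupB"
  pairs <- all_vs_all(list(c1, c2))
  g <- build_gnn(pairs, 1e-6)
  fams <- annotate_families(detect_families(g))
  prefix <- tempfile()
  paths <- write_gnn(g, fams, prefix)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[[2]])
  expect_equal(nrow(edges), igraph::ecount(g))
  expect_true(all(edges$evalue <= 1e-6))
  expect_match(readLines(paths[[1]], n = 2)[2], "graphml")
})
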