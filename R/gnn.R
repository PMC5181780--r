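# Genome neighborhood network (GNN).
#
# Nodes are proteins of gene clusters; edges connect protein pairs whose
# Smith-Waterman alignment is significant at an E-value threshold (default
# 1e-6, the display threshold). Connected components approximate protein
# families; families containing the well-conserved markers E2/E3/R3 are
# re-partitioned at a strict threshold (default 1e-75) to separate the
# subfamilies used for 9- versus 10-membered ring prediction. Family labels
# are transferred from reference clusters by majority vote.

node_id <- function(cluster_id, orf_id) paste(cluster_id, orf_id, sep = "::")

# Flatten clusters into one protein table.
protein_table <- function(clusters) {
  stopifnot(length(clusters) >= 1L)
  rows <- lapply(clusters, function(cl) {
    stopifnot(inherits(cl, "edmine_cluster"))
    data.frame(cluster_id = cl$cluster_id, orf_id = cl$orfs$orf_id,
               node = node_id(cl$cluster_id, cl$orfs$orf_id),
               label = cl$orfs$label, source = cl$source,
               protein = cl$orfs$protein, len = nchar(cl$orfs$protein),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$node)) stopf("duplicate cluster/ORF identifiers across clusters")
  rownames(tab) <- NULL
  tab
}

#' All-versus-all local alignment of cluster proteins
#'
#' Scores every unordered protein pair across and within the clusters with
#' the Smith-Waterman aligner and converts scores to Karlin-Altschul
#' E-values over the pairwise `m * n` search space. Pairs whose lengths
#' differ more than `length_ratio`-fold are skipped (no biologically
#' meaningful full-length homology), and pairs with E-value above
#' `keep_max_evalue` are dropped from the output.
#'
#' The default gap penalties here are the BLAST-standard 11/1 rather than the
#' 10/0.5 used for global identity computations: the Karlin-Altschul
#' parameters `lambda = 0.267`, `K = 0.041` are the published statistics for
#' gapped BLOSUM62 alignment at 11/1, and weaker gap extension pushes long
#' random local alignments out of the logarithmic score regime those
#' statistics assume, inflating significance for unrelated pairs.
#'
#' @param clusters List of [gene_cluster()] objects (references and hits).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param params [evalue_params()].
#' @param keep_max_evalue Retain only pairs with E at or below this value
#'   (default 1e-3, looser than any working threshold).
#' @param length_ratio Skip pairs with length ratio above this (default 5).
#' @return An object of class `edmine_pairs`: list with `pairs` (data frame
#'   `node_a`, `node_b`, `score`, `evalue`) and `proteins` (the node table).
#' @export
all_vs_all <- function(clusters, matrix = edmine_blosum62(),
                       gap_open = 11, gap_extend = 1,
                       params = evalue_params(),
                       keep_max_evalue = 1e-3, length_ratio = 5) {
  tab <- protein_table(clusters)
  n <- nrow(tab)
  out <- vector("list", n)
  for (j in seq_len(n)[-1L]) {
    i_cand <- seq_len(j - 1L)
    ratio <- pmax(tab$len[i_cand], tab$len[[j]]) / pmin(tab$len[i_cand], tab$len[[j]])
    i_cand <- i_cand[ratio <= length_ratio]
    if (length(i_cand) == 0L) next
    sc <- local_scores_vs(tab$protein[i_cand], tab$protein[[j]],
                          matrix, gap_open, gap_extend)
    ev <- evalue(sc, tab$len[i_cand], tab$len[[j]], params)
    keep <- ev <= keep_max_evalue
    if (!any(keep)) next
    out[[j]] <- data.frame(node_a = tab$node[i_cand[keep]], node_b = tab$node[[j]],
                           score = sc[keep], evalue = ev[keep],
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(pairs)) {
    pairs <- data.frame(node_a = character(0), node_b = character(0),
                        score = numeric(0), evalue = numeric(0))
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, proteins = tab), class = "edmine_pairs")
}

#' Build the genome neighborhood network at an E-value threshold
#'
#' Keeps the edges of the scored pair list with E-value at or below the
#' threshold; every protein is a node, so proteins without significant
#' partners appear as isolated nodes (singleton families).
#'
#' @param pairs An [all_vs_all()] result.
#' @param threshold E-value threshold (default 1e-6).
#' @return An undirected simple [igraph::igraph] with node attributes
#'   `cluster_id`, `orf_id`, `label`, `source`, edge attribute `evalue`, and
#'   graph attribute `threshold`.
#' @export
build_gnn <- function(pairs, threshold = 1e-6) {
  stopifnot(inherits(pairs, "edmine_pairs"))
  if (threshold <= 0) stopf("`threshold` must be positive")
  tab <- pairs$proteins
  keep <- pairs$pairs[pairs$pairs$evalue <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("node_a", "node_b", "evalue", "score")],
    directed = FALSE,
    vertices = data.frame(name = tab$node, cluster_id = tab$cluster_id,
                          orf_id = tab$orf_id, label = tab$label,
                          source = tab$source, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, edge.attr.comb = "min")
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Detect protein families as connected components
#'
#' Families are the connected components of the GNN. When a strict threshold
#' is given, every family containing a reference protein labelled with one of
#' `refine_labels` (default the E2/E3/R3 marker conglomerate) is
#' re-partitioned into the components of its induced subgraph restricted to
#' edges with E-value at or below the strict threshold — separating, e.g.,
#' the E2 and E3 subfamilies that merge at the display threshold.
#'
#' @param graph A [build_gnn()] graph.
#' @param pairs The [all_vs_all()] result the graph was built from (needed
#'   only for the strict pass; its edges are re-thresholded).
#' @param strict_threshold Strict E-value threshold (default `NULL`, no
#'   refinement; the marker separation uses 1e-75).
#' @param refine_labels Reference labels whose families are refined.
#' @return An object of class `edmine_families`: list with `assignment`
#'   (data frame `node`, `cluster_id`, `orf_id`, `ref_label`, `source`,
#'   `family_id`), `threshold`, `strict_threshold`.
#' @export
detect_families <- function(graph, pairs = NULL, strict_threshold = NULL,
                            refine_labels = c("E2", "E3", "R3")) {
  memb <- igraph::components(graph)$membership
  nodes <- igraph::V(graph)$name
  labels <- igraph::V(graph)$label
  sources <- igraph::V(graph)$source
  fam <- split(nodes, memb[nodes])

  if (!is.null(strict_threshold)) {
    if (is.null(pairs)) stopf("`pairs` is required for strict-threshold refinement")
    is_marker_ref <- !is.na(labels) & labels %in% refine_labels & sources == "reference"
    marker_nodes <- nodes[is_marker_ref]
    strict_edges <- pairs$pairs[pairs$pairs$evalue <= strict_threshold, , drop = FALSE]
    fam_new <- list()
    for (members in fam) {
      if (!any(members %in% marker_nodes)) {
        fam_new[[length(fam_new) + 1L]] <- members
        next
      }
      sub <- strict_edges[strict_edges$node_a %in% members &
                            strict_edges$node_b %in% members, , drop = FALSE]
      gs <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                          directed = FALSE,
                                          vertices = data.frame(name = members))
      msub <- igraph::components(gs)$membership
      fam_new <- c(fam_new, split(members, msub[members]))
    }
    fam <- fam_new
  }

  # dense, deterministic family ids: order by lexicographically first member
  fam <- lapply(fam, sort)
  fam <- fam[order(vapply(fam, `[[`, "", 1L))]
  node2fam <- setNames(rep(seq_along(fam), lengths(fam)), unlist(fam))
  ord <- order(node2fam[nodes], nodes)
  assignment <- data.frame(
    node = nodes, cluster_id = igraph::V(graph)$cluster_id,
    orf_id = igraph::V(graph)$orf_id, ref_label = labels, source = sources,
    family_id = unname(node2fam[nodes]), stringsAsFactors = FALSE
  )[ord, ]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment,
                 threshold = igraph::graph_attr(graph, "threshold"),
                 strict_threshold = strict_threshold),
            class = "edmine_families")
}

#' Transfer reference labels onto detected families
#'
#' Labels every family with the majority reference-gene label among its
#' reference-cluster members (ties broken lexicographically). A family with
#' no reference member is labelled `"unknown_family"`, or `"singleton"` if it
#' has a single member.
#'
#' @param families A [detect_families()] result.
#' @return The same object with a `label` column added to `assignment` and a
#'   `family_labels` lookup (family id -> label).
#' @export
annotate_families <- function(families) {
  stopifnot(inherits(families, "edmine_families"))
  a <- families$assignment
  labs <- vapply(split(seq_len(nrow(a)), a$family_id), function(idx) {
    refs <- a$ref_label[idx][a$source[idx] == "reference" & !is.na(a$ref_label[idx])]
    if (length(refs) > 0L) {
      tab <- sort(table(refs), decreasing = TRUE)
      best <- names(tab)[tab == max(tab)]
      sort(best)[[1L]]
    } else if (length(idx) == 1L) {
      "singleton"
    } else {
      "unknown_family"
    }
  }, "")
  families$family_labels <- labs
  families$assignment$label <- labs[as.character(a$family_id)]
  families
}

#' @export
print.edmine_families <- function(x, ...) {
  n_fam <- length(unique(x$assignment$family_id))
  cat(sprintf("Protein families: %d nodes in %d families (threshold %g%s)\n",
              nrow(x$assignment), n_fam, x$threshold,
              if (is.null(x$strict_threshold)) "" else
                sprintf(", strict %g", x$strict_threshold)))
  invisible(x)
}

#' Cluster-by-family count profile
#'
#' @param families An (annotated) [detect_families()] result.
#' @return Integer matrix, clusters in rows, families in columns; row sums
#'   equal the ORF counts of the clusters.
#' @export
cluster_profile <- function(families) {
  a <- families$assignment
  unclass(table(a$cluster_id, a$family_id))
}

#' Pairwise cluster similarity from family content
#'
#' Shared-family counts and Jaccard similarity on family presence/absence.
#'
#' @param profile A [cluster_profile()] matrix.
#' @return List with symmetric matrices `shared` (number of families present
#'   in both clusters) and `jaccard` (`|A & B| / |A | B|`; 1 on the
#'   diagonal).
#' @export
cluster_similarity <- function(profile) {
  pres <- profile > 0
  shared <- pres %*% t(pres)
  sizes <- rowSums(pres)
  union <- outer(sizes, sizes, `+`) - shared
  jac <- ifelse(union > 0, shared / union, 1)
  list(shared = shared, jaccard = jac)
}

#' Export GNN artifacts
#'
#' Writes the network as GraphML and as a 3-column edge list
#' (`node_a`, `node_b`, `evalue`), and the family assignment as TSV.
#'
#' @param graph A [build_gnn()] graph.
#' @param families An annotated [detect_families()] result.
#' @param out_prefix Path prefix for `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_families.tsv`.
#' @return The paths written, invisibly.
#' @export
write_gnn <- function(graph, families, out_prefix) {
  paths <- paste0(out_prefix, c(".graphml", "_edges.tsv", "_families.tsv"))
  igraph::write_graph(graph, paths[[1L]], format = "graphml")
  ed <- igraph::as_data_frame(graph, what = "edges")
  write.table(setNames(ed[, c("from", "to", "evalue")],
                       c("node_a", "node_b", "evalue")),
              paths[[2L]], sep = "\t", quote = FALSE, row.names = FALSE)
  a <- families$assignment
  write.table(a[, c("cluster_id", "orf_id", "family_id", "label")],
              paths[[3L]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
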