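# Rule-based structural prediction.
#
# Ring size follows the exclusive-presence rule: a cluster sharing a protein
# family with a reference E2 is predicted 9-membered, one sharing a family
# with a reference R3 10-membered; both markers give "ambiguous", neither
# "unknown". Peripheral moieties (chromoprotein/apoprotein, beta-amino acid,
# amino sugar, benzoxazolinate) are predicted from curated reference gene
# sets with a minimum-hit threshold. A novelty report counts unknown families
# and singletons per cluster.

#' Predict enediyne ring size from marker families
#'
#' Applies the exclusive-presence rule over annotated protein families: a
#' cluster is called `nine` when at least one of its ORFs shares a family
#' with a reference E2 protein and none with a reference R3, `ten` in the
#' converse case, `ambiguous` when both markers hit and `unknown` when
#' neither does. Families should have been refined at the strict E-value
#' threshold (see [detect_families()]) so the E2/E3/R3 subfamilies are
#' separated.
#'
#' @param families An annotated [detect_families()] result covering the
#'   clusters and at least one reference cluster carrying E2 and R3 labels.
#' @param markers Marker labels, `c(nine = "E2", ten = "R3")`.
#' @return Data frame, one row per non-reference cluster: `cluster_id`,
#'   `ring_call`, `e2_family`, `r3_family` (the evidence family ids, `NA`
#'   when absent).
#' @export
predict_ring_size <- function(families, markers = c(nine = "E2", ten = "R3")) {
  a <- families$assignment
  fam_of_marker <- function(lab) {
    unique(a$family_id[a$source == "reference" & !is.na(a$ref_label) &
                         a$ref_label == lab])
  }
  e2_fams <- fam_of_marker(markers[["nine"]])
  r3_fams <- fam_of_marker(markers[["ten"]])
  if (length(e2_fams) == 0L && length(r3_fams) == 0L) {
    stopf("no reference %s or %s proteins among the families; cannot predict ring size",
          markers[["nine"]], markers[["ten"]])
  }
  hits <- a[a$source != "reference", , drop = FALSE]
  out <- lapply(unique(hits$cluster_id), function(cid) {
    fams <- hits$family_id[hits$cluster_id == cid]
    e2 <- intersect(fams, e2_fams)
    r3 <- intersect(fams, r3_fams)
    call <- if (length(e2) > 0L && length(r3) > 0L) "ambiguous"
    else if (length(e2) > 0L) "nine"
    else if (length(r3) > 0L) "ten"
    else "unknown"
    data.frame(cluster_id = cid, ring_call = call,
               e2_family = if (length(e2) > 0L) e2[[1L]] else NA_integer_,
               r3_family = if (length(r3) > 0L) r3[[1L]] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default peripheral-moiety gene-set definitions
#'
#' One definition per moiety: the reference gene labels constituting the set
#' and the minimum number of distinct labels that must hit for the moiety to
#' be predicted (1 for the single apoprotein gene, the majority of the set
#' otherwise). The sets are keyed to the synthetic reference clusters and are
#' editable via [read_moiety_config()].
#'
#' @return Named list of `list(labels, min_hits)`.
#' @export
default_moiety_definitions <- function() {
  defs <- lapply(MOIETY_GENES, function(labs) {
    list(labels = labs, min_hits = max(1L, ceiling(length(labs) / 2)))
  })
  names(defs)[names(defs) == "apoprotein"] <- "chromoprotein"
  defs
}

#' Read moiety definitions from a plain-text config
#'
#' Format: one moiety per line, `name: label1 label2 ... : min_hits`
#' (the trailing `: min_hits` may be omitted, defaulting to the majority of
#' the set). Lines starting with `#` are ignored.
#'
#' @param path Config file path.
#' @return Named list of `list(labels, min_hits)`.
#' @export
read_moiety_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  defs <- list()
  for (l in lines) {
    parts <- trimws(strsplit(l, ":", fixed = TRUE)[[1L]])
    if (length(parts) < 2L) stopf("bad moiety definition line: %s", l)
    labels <- strsplit(parts[[2L]], "\\s+")[[1L]]
    min_hits <- if (length(parts) >= 3L) as.integer(parts[[3L]]) else
      max(1L, ceiling(length(labels) / 2))
    defs[[parts[[1L]]]] <- list(labels = labels, min_hits = min_hits)
  }
  defs
}

#' Predict peripheral moieties from family content
#'
#' A moiety is predicted for a cluster when the cluster's ORFs hit at least
#' `min_hits` distinct families labelled with genes of the moiety's set.
#'
#' @param families An annotated [detect_families()] result.
#' @param definitions Moiety definitions, see [default_moiety_definitions()].
#' @return Data frame: `cluster_id`, `moieties` (`;`-joined predicted
#'   names), plus one logical column per moiety.
#' @export
predict_moieties <- function(families, definitions = default_moiety_definitions()) {
  a <- families$assignment
  if (is.null(a$label)) stopf("families must be annotated first (see annotate_families)")
  known <- unique(a$label)
  hits <- a[a$source != "reference", , drop = FALSE]
  out <- lapply(unique(hits$cluster_id), function(cid) {
    labs <- unique(hits$label[hits$cluster_id == cid])
    flags <- vapply(definitions, function(d) {
      sum(d$labels %in% labs) >= d$min_hits
    }, TRUE)
    row <- data.frame(cluster_id = cid,
                      moieties = paste(names(definitions)[flags], collapse = ";"),
                      stringsAsFactors = FALSE)
    cbind(row, as.data.frame(as.list(flags)))
  })
  do.call(rbind, out)
}

#' Report structural novelty per cluster
#'
#' Counts, per non-reference cluster, the ORFs falling into families without
#' any reference member (`n_unknown`), the singleton families (`n_singletons`,
#' families of size 1), and lists the family ids absent from every reference
#' cluster.
#'
#' @param families An annotated [detect_families()] result.
#' @return List with `per_cluster` (data frame `cluster_id`, `n_orfs`,
#'   `n_unknown`, `n_singletons`) and `novel_families` (integer vector of
#'   family ids with no reference member).
#' @export
novelty_report <- function(families) {
  a <- families$assignment
  fam_size <- table(a$family_id)
  fam_has_ref <- vapply(split(a$source, a$family_id),
                        function(s) any(s == "reference"), TRUE)
  hits <- a[a$source != "reference", , drop = FALSE]
  per_cluster <- do.call(rbind, lapply(unique(hits$cluster_id), function(cid) {
    fams <- hits$family_id[hits$cluster_id == cid]
    data.frame(
      cluster_id = cid, n_orfs = length(fams),
      n_unknown = sum(!fam_has_ref[as.character(fams)]),
      n_singletons = sum(fam_size[as.character(fams)] == 1L),
      stringsAsFactors = FALSE
    )
  }))
  novel <- as.integer(names(fam_has_ref))[!fam_has_ref]
  list(per_cluster = per_cluster, novel_families = novel)
}
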