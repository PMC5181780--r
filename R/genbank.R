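# Gene clusters and GenBank flat-file I/O.
#
# A gene cluster is the unit of genome-neighborhood analysis: an ordered set
# of ORFs with 0-based half-open coordinates, strand, protein translation and
# an optional reference gene label. The GenBank reader/writer covers the flat
# file subset needed here: LOCUS/ORIGIN, CDS features with simple,
# complement() and join() locations, and locus_tag / gene / translation
# qualifiers.

#' Gene cluster objects
#'
#' @param cluster_id Identifier of the cluster (typically the strain or
#'   accession name).
#' @param orfs Data frame with columns `orf_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `protein`, and optionally `label`
#'   (reference gene label such as `"E5"`; `NA` when unknown).
#' @param source `"reference"` for labelled known clusters, `"hit"` for newly
#'   screened ones.
#' @return An object of class `edmine_cluster`.
#' @export
gene_cluster <- function(cluster_id, orfs, source = c("hit", "reference")) {
  source <- match.arg(source)
  need <- c("orf_id", "start", "end", "strand", "protein")
  if (!is.data.frame(orfs) || !all(need %in% names(orfs))) {
    stopf("`orfs` must be a data frame with columns %s", paste(need, collapse = ", "))
  }
  if (is.null(orfs$label)) orfs$label <- NA_character_
  if (any(orfs$end <= orfs$start)) stopf("ORF coordinates must satisfy start < end")
  if (!all(orfs$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (anyDuplicated(orfs$orf_id)) stopf("duplicate orf_id in cluster %s", cluster_id)
  rownames(orfs) <- NULL
  structure(list(cluster_id = cluster_id, source = source, orfs = orfs),
            class = "edmine_cluster")
}

#' @export
print.edmine_cluster <- function(x, ...) {
  cat(sprintf("Gene cluster %s (%s): %d ORFs, %d labelled\n",
              x$cluster_id, x$source, nrow(x$orfs), sum(!is.na(x$orfs$label))))
  invisible(x)
}

#' Read a gene cluster from a GenBank flat file
#'
#' Parses CDS features of a single-record GenBank flat file into a
#' [gene_cluster()]. The protein is taken from the `/translation` qualifier
#' when present; otherwise the CDS is translated with genetic code table 11.
#' When a supplied translation disagrees with the translated sequence a
#' warning is raised and the qualifier wins. Compound `join()` locations are
#' concatenated before translation; `complement()` locations are translated
#' from the reverse complement. Coordinates are normalised to 0-based
#' half-open plus-strand.
#'
#' @param path Path to a GenBank flat file with at least one CDS feature.
#' @param source Passed to [gene_cluster()].
#' @return A [gene_cluster()]; the record sequence (if present) is attached
#'   as attribute `"sequence"`.
#' @export
read_genbank_cluster <- function(path, source = "hit") {
  if (!file.exists(path)) stopf("GenBank file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(grepl("^LOCUS", lines))) {
    stopf("not a GenBank flat file (no LOCUS line): %s", path)
  }
  locus <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[grepl("^LOCUS", lines)][1L])), "\\s+")[[1L]][1L]

  seq <- genbank_origin_sequence(lines)
  feats <- genbank_cds_features(lines)
  if (length(feats) == 0L) stopf("no CDS features in %s", path)

  orfs <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    prot <- f$qualifiers[["translation"]]
    if (!is.null(seq)) {
      exons <- vapply(seq_len(nrow(f$parts)), function(j) {
        substr(seq, f$parts$start[[j]] + 1L, f$parts$end[[j]])
      }, "")
      cds <- paste0c(exons)
      if (f$strand == "-") cds <- revcomp(cds)
      own <- tryCatch(sub("\\*$", "", translate_cds(cds)), error = function(e) NULL)
      if (is.null(prot)) {
        if (is.null(own)) stopf("CDS %d in %s has no translation and cannot be translated", i, path)
        prot <- own
      } else if (!is.null(own) && !identical(own, prot)) {
        warnf("translation qualifier of CDS %d in %s disagrees with the sequence; keeping the qualifier",
              i, path)
      }
    }
    if (is.null(prot)) stopf("CDS %d in %s has no translation and no ORIGIN sequence", i, path)
    data.frame(
      orf_id = f$qualifiers[["locus_tag"]] %||% sprintf("%s_%02d", locus, i),
      start = min(f$parts$start), end = max(f$parts$end), strand = f$strand,
      protein = prot,
      label = f$qualifiers[["gene"]] %||% NA_character_,
      stringsAsFactors = FALSE
    )
  })
  cl <- gene_cluster(locus, do.call(rbind, orfs), source = source)
  attr(cl, "sequence") <- seq
  cl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genbank_origin_sequence <- function(lines) {
  i <- which(grepl("^ORIGIN", lines))
  if (length(i) == 0L) return(NULL)
  j <- which(grepl("^//", lines))
  j <- j[j > i[1L]][1L]
  if (is.na(j)) j <- length(lines) + 1L
  block <- lines[(i[1L] + 1L):(j - 1L)]
  toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
}

# Extract CDS features: location string + qualifiers, handling multi-line
# locations and qualifiers.
genbank_cds_features <- function(lines) {
  fstart <- which(grepl("^FEATURES", lines))
  if (length(fstart) == 0L) return(list())
  fend <- which(grepl("^(ORIGIN|CONTIG|//)", lines))
  fend <- c(fend[fend > fstart[1L]], length(lines) + 1L)[1L]
  block <- lines[(fstart[1L] + 1L):(fend - 1L)]

  # feature starts: a key in columns 6-20
  is_key <- grepl("^ {1,10}\\S", block) & !grepl("^ {21}", block)
  key_idx <- which(is_key)
  keys <- trimws(substr(block[key_idx], 1L, 20L))
  feats <- list()
  for (n in seq_along(key_idx)) {
    if (keys[[n]] != "CDS") next
    from <- key_idx[[n]]
    to <- if (n < length(key_idx)) key_idx[[n + 1L]] - 1L else length(block)
    body <- block[from:to]
    body[1L] <- trimws(substr(body[1L], 21L, nchar(body[1L])))
    body[-1L] <- trimws(body[-1L])
    # location = leading lines up to the first qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at) > 0L) qual_at[1L] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    quals <- parse_qualifiers(body[-seq_len(loc_end)])
    feats[[length(feats) + 1L]] <- c(parse_location(loc), list(qualifiers = quals))
  }
  feats
}

parse_qualifiers <- function(lines) {
  quals <- list()
  cur <- NULL
  for (l in lines) {
    if (grepl("^/", l)) {
      m <- regmatches(l, regexec('^/([A-Za-z_]+)(=(.*))?$', l))[[1L]]
      cur <- m[[2L]]
      val <- if (length(m) >= 4L && nzchar(m[[4L]])) m[[4L]] else ""
      quals[[cur]] <- val
    } else if (!is.null(cur)) {
      sep <- if (cur == "translation") "" else " "
      quals[[cur]] <- paste0(quals[[cur]], sep, l)
    }
  }
  lapply(quals, function(v) gsub('^"|"$', "", v))
}

# GenBank locations are 1-based inclusive; convert to 0-based half-open.
parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", p))[[1L]]
    if (length(m) != 3L) stopf("unsupported GenBank location: %s", p)
    c(as.integer(m[[2L]]) - 1L, as.integer(m[[3L]]))
  })
  parts_df <- data.frame(start = vapply(rng, `[[`, 0L, 1L),
                         end = vapply(rng, `[[`, 0L, 2L))
  list(strand = strand, parts = parts_df)
}

#' Write a gene cluster as a GenBank flat file
#'
#' Emits a minimal single-record GenBank flat file with one CDS feature per
#' ORF (`locus_tag`, `gene` when labelled, `translation`) and the full genome
#' sequence in the ORIGIN block, round-trippable by [read_genbank_cluster()].
#'
#' @param cluster A [gene_cluster()].
#' @param sequence The genome/cluster DNA as a plain string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank_cluster <- function(cluster, sequence, path) {
  stopifnot(inherits(cluster, "edmine_cluster"))
  con <- file(path, "w")
  on.exit(close(con))
  out <- function(...) writeLines(sprintf(...), con)
  out("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-1980",
      cluster$cluster_id, nchar(sequence))
  out("DEFINITION  synthetic genome record %s.", cluster$cluster_id)
  out("FEATURES             Location/Qualifiers")
  out("     source          1..%d", nchar(sequence))
  for (i in seq_len(nrow(cluster$orfs))) {
    o <- cluster$orfs[i, ]
    loc <- sprintf("%d..%d", o$start + 1L, o$end)
    if (o$strand == "-") loc <- sprintf("complement(%s)", loc)
    out("     CDS             %s", loc)
    out("                     /locus_tag=\"%s\"", o$orf_id)
    if (!is.na(o$label)) out("                     /gene=\"%s\"", o$label)
    tr <- sprintf("/translation=\"%s\"", o$protein)
    for (chunk in strwrap_fixed(tr, 58L)) {
      out("                     %s", chunk)
    }
  }
  out("ORIGIN")
  seqchars <- chars(tolower(sequence))
  for (off in seq(1L, length(seqchars), by = 60L)) {
    line <- seqchars[off:min(off + 59L, length(seqchars))]
    groups <- split(line, ceiling(seq_along(line) / 10L))
    out("%9d %s", off, paste(vapply(groups, paste0c, ""), collapse = " "))
  }
  out("//")
  invisible(path)
}

strwrap_fixed <- function(x, width) {
  n <- nchar(x)
  starts <- seq(1L, n, by = width)
  vapply(starts, function(s) substr(x, s, min(s + width - 1L, n)), "")
}
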