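# Pipeline orchestration: simulate -> screen -> phylo -> gnn -> classify.
#
# Each stage consumes only the artifacts of the previous one, so the pipeline
# is equivalent to running the stages by hand with the same parameters. All
# randomness is confined to the simulation stage; given a configuration and
# seed the whole report bundle is byte-identical across runs.

#' Pipeline configuration
#'
#' Validates stage parameters and paths for [run_pipeline()]. Either
#' `genomes_dir` (FASTA genomes, one record per strain) or `simulate` (a
#' [simulation_config()], in which case the cohort is generated under
#' `out_dir/cohort` first) must be given.
#'
#' @param out_dir Output directory for the report bundle.
#' @param genomes_dir Directory of FASTA genomes (`.fasta`/`.fa`).
#' @param genbank_dir Directory of GenBank flat files for the screened hits
#'   (used by the GNN stage); defaults to `<genomes_dir>/../genbank`.
#' @param primers Path to a primer TSV, or `NULL` for [default_primers()].
#' @param simulate Optional [simulation_config()].
#' @param max_mismatches,min_len,max_len Screen parameters.
#' @param window_bp 1-kb internal fragment window.
#' @param cutoff,linkage Dereplication parameters (percent identity cutoff
#'   and `"single"`/`"complete"` linkage).
#' @param threshold,strict_threshold GNN E-value thresholds.
#' @param na_molar Salt concentration for Tm prediction.
#' @return A validated list of class `edmine_config`.
#' @export
pipeline_config <- function(out_dir,
                            genomes_dir = NULL,
                            genbank_dir = NULL,
                            primers = NULL,
                            simulate = NULL,
                            max_mismatches = 2L,
                            min_len = 300L, max_len = 3000L,
                            window_bp = 999L,
                            cutoff = 90, linkage = "single",
                            threshold = 1e-6, strict_threshold = 1e-75,
                            na_molar = 0.05) {
  fail <- function(fmt, ...) {
    stop(structure(class = c("edmine_config_error", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = NULL)))
  }
  if (is.null(genomes_dir) && is.null(simulate)) {
    fail("either `genomes_dir` or `simulate` must be provided")
  }
  if (!is.null(genomes_dir) && !dir.exists(genomes_dir)) {
    fail("genomes directory does not exist: %s", genomes_dir)
  }
  if (!is.null(primers) && !file.exists(primers)) fail("primer file not found: %s", primers)
  if (!is.null(simulate) && !inherits(simulate, "edmine_simconfig")) {
    fail("`simulate` must be a simulation_config()")
  }
  if (cutoff <= 0 || cutoff > 100) fail("`cutoff` must lie in (0, 100]")
  if (min_len > max_len) fail("`min_len` exceeds `max_len`")
  if (threshold <= 0 || strict_threshold <= 0) fail("E-value thresholds must be positive")
  if (!linkage %in% c("single", "complete")) fail("`linkage` must be single or complete")
  structure(list(out_dir = out_dir, genomes_dir = genomes_dir,
                 genbank_dir = genbank_dir, primers = primers,
                 simulate = simulate,
                 max_mismatches = as.integer(max_mismatches),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 window_bp = as.integer(window_bp),
                 cutoff = cutoff, linkage = linkage,
                 threshold = threshold, strict_threshold = strict_threshold,
                 na_molar = na_molar),
            class = "edmine_config")
}

#' Read a pipeline configuration file
#'
#' A human-editable YAML (`key: value`) file; unknown keys are rejected,
#' omitted keys take their defaults. The `simulate:` block, when present,
#' is passed to [simulation_config()].
#'
#' @param path Config file path.
#' @param out_dir Overrides the `out_dir` key when given.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  if (!is.null(out_dir)) y$out_dir <- out_dir
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop(structure(class = c("edmine_config_error", "error", "condition"),
                   list(message = sprintf("unknown config key(s): %s",
                                          paste(unknown, collapse = ", ")),
                        call = NULL)))
  }
  do.call(pipeline_config, y)
}

#' Generate a synthetic cohort (pipeline stage)
#'
#' Thin wrapper over [generate_cohort()] that writes the cohort under
#' `dir` and logs a one-line summary.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return The cohort, invisibly.
#' @export
simulate_cohort <- function(config, dir) {
  cohort <- generate_cohort(config, dir = dir)
  message(sprintf("[simulate] %d genomes, %d producers in %d clades -> %s",
                  length(cohort$genomes), sum(cohort$truth$is_producer),
                  config$n_producer_clades, dir))
  invisible(cohort)
}

read_genomes_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(structure(class = c("edmine_config_error", "error", "condition"),
                   list(message = sprintf("no FASTA genomes found in %s", dir),
                        call = NULL)))
  }
  out <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  })
  unlist(out)
}

#' Run the strain-prioritization pipeline
#'
#' Executes the stages in order — simulate (optional), in-silico PCR screen,
#' fragment dereplication into clades, genome neighborhood network, and
#' structural classification — and writes the report bundle under
#' `config$out_dir`: `screen.tsv`, `amplicons.tsv`, `identity.tsv`,
#' `tree.nwk`, `clades.tsv`, `gnn.graphml`, `gnn_edges.tsv`,
#' `families.tsv`, `profile.tsv`, `predictions.tsv` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param last_stage Run the pipeline only up to this stage
#'   (`"screen"`, `"phylo"`, `"gnn"` or the default `"classify"`, i.e. all).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `screen`, `identity`, `clades`, `representatives`, `tree`, `families`,
#'   `predictions`, `manifest`).
#' @export
run_pipeline <- function(config,
                         last_stage = c("classify", "gnn", "phylo", "screen")) {
  stopifnot(inherits(config, "edmine_config"))
  last_stage <- match.arg(last_stage)
  stage_rank <- c(screen = 1L, phylo = 2L, gnn = 3L, classify = 4L)
  want <- function(stage) stage_rank[[stage]] <= stage_rank[[last_stage]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  timings <- list()

  cohort <- NULL
  genomes_dir <- config$genomes_dir
  genbank_dir <- config$genbank_dir
  if (!is.null(config$simulate)) {
    st <- t_stage(simulate_cohort(config$simulate, file.path(config$out_dir, "cohort")))
    cohort <- st$value
    timings$simulate <- st$seconds
    genomes_dir <- file.path(config$out_dir, "cohort", "genomes")
    if (is.null(genbank_dir)) genbank_dir <- file.path(config$out_dir, "cohort", "genbank")
  } else if (is.null(genbank_dir)) {
    genbank_dir <- file.path(dirname(genomes_dir), "genbank")
  }

  # --- screen ---------------------------------------------------------------
  st <- t_stage({
    genomes <- read_genomes_dir(genomes_dir)
    primers <- if (is.null(config$primers)) default_primers() else
      read_primers(config$primers, config$max_mismatches)
    screen_cohort(genomes, primers, config$min_len, config$max_len,
                  config$max_mismatches, config$na_molar)
  })
  screen <- st$value
  timings$screen <- st$seconds
  hits <- screen$calls$strain_id[screen$calls$architecture != "negative"]
  message(sprintf("[screen] surveyed %d strains: %d hits, %d negative",
                  nrow(screen$calls), length(hits),
                  sum(screen$calls$architecture == "negative")))
  write.table(screen$calls, file.path(config$out_dir, "screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(screen$amplicons, file.path(config$out_dir, "amplicons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- phylo ----------------------------------------------------------------
  fragments <- character(0)
  identity <- NULL; clades <- NULL; reps <- character(0); tree <- NULL
  families <- NULL; predictions <- NULL
  if (want("phylo")) {
  st <- t_stage({
    genomes <- read_genomes_dir(genomes_dir)
    amp <- screen$amplicons
    amp <- amp[amp$pair_id == "E_internal" & amp$genome_id %in% hits, , drop = FALSE]
    amp <- amp[!duplicated(amp$genome_id), , drop = FALSE]
    frags <- setNames(vapply(seq_len(nrow(amp)), function(i) {
      translate_cds(substr(genomes[[amp$genome_id[[i]]]],
                           amp$start[[i]] + 1L, amp$end[[i]]))
    }, ""), amp$genome_id)
    frags
  })
  fragments <- st$value
  timings$fragments <- st$seconds

  if (length(fragments) >= 2L) {
    st <- t_stage(identity_matrix(fragments))
    identity <- st$value
    timings$identity <- st$seconds
    clades <- collapse_clades(identity, config$cutoff, config$linkage)
    reps <- pick_representatives(clades, identity)
    if (length(fragments) >= 3L) {
      tree <- nj_tree(identity)
      ape::write.tree(tree, file.path(config$out_dir, "tree.nwk"))
    }
    write.table(round(identity, 4), file.path(config$out_dir, "identity.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    clade_df <- data.frame(strain_id = names(clades$clade),
                           clade_id = unname(clades$clade),
                           representative = names(clades$clade) %in% reps,
                           stringsAsFactors = FALSE)
    write.table(clade_df, file.path(config$out_dir, "clades.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[phylo] %d hit fragments collapsed into %d clades at %.0f%% identity (%s linkage)",
                    length(fragments), clades$n_clades, config$cutoff, config$linkage))
  } else if (length(fragments) == 1L) {
    reps <- names(fragments)
    message("[phylo] single hit; one clade by definition")
  } else {
    message("[phylo] no hits; skipping dereplication")
  }

  }

  # --- gnn ------------------------------------------------------------------
  rep_files <- file.path(genbank_dir, paste0(reps, ".gbk"))
  rep_files <- rep_files[file.exists(rep_files)]
  if (want("gnn") && length(rep_files) > 0L) {
    st <- t_stage({
      hit_clusters <- lapply(rep_files, read_genbank_cluster, source = "hit")
      clusters <- c(reference_clusters(), hit_clusters)
      pairs <- all_vs_all(clusters, keep_max_evalue = max(1e-3, config$threshold))
      graph <- build_gnn(pairs, config$threshold)
      fams <- detect_families(graph, pairs, config$strict_threshold)
      fams <- annotate_families(fams)
      write_gnn(graph, fams, file.path(config$out_dir, "gnn"))
      prof <- cluster_profile(fams)
      write.table(prof, file.path(config$out_dir, "profile.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      fams
    })
    families <- st$value
    timings$gnn <- st$seconds
    n_fam <- length(unique(families$assignment$family_id))
    message(sprintf("[gnn] %d proteins from %d clusters in %d families (E <= %g, strict %g)",
                    nrow(families$assignment),
                    length(unique(families$assignment$cluster_id)), n_fam,
                    config$threshold, config$strict_threshold))

    # --- classify -----------------------------------------------------------
    if (want("classify")) {
    st <- t_stage({
      ring <- predict_ring_size(families)
      moi <- predict_moieties(families)
      nov <- novelty_report(families)
      pred <- merge(merge(ring[, c("cluster_id", "ring_call")],
                          moi[, c("cluster_id", "moieties")], by = "cluster_id"),
                    nov$per_cluster[, c("cluster_id", "n_unknown", "n_singletons")],
                    by = "cluster_id")
      write.table(pred, file.path(config$out_dir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      pred
    })
    predictions <- st$value
    timings$classify <- st$seconds
    message(sprintf("[classify] ring calls: %s",
                    paste(sprintf("%s=%d", names(table(predictions$ring_call)),
                                  as.integer(table(predictions$ring_call))),
                          collapse = ", ")))
    }
  } else if (want("gnn")) {
    message("[gnn] no GenBank records for representatives; skipping GNN and classification")
  }

  # --- manifest -------------------------------------------------------------
  outputs <- list.files(config$out_dir, pattern = "\\.(tsv|nwk|graphml)$",
                        full.names = TRUE)
  manifest <- list(
    tool = "edmine",
    version = as.character(utils::packageVersion("edmine")),
    parameters = config_echo(config),
    n_strains = nrow(screen$calls),
    n_hits = length(hits),
    n_clades = if (is.null(clades)) length(reps) else clades$n_clades,
    stage_seconds = timings,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, screen = screen, fragments = fragments,
                 identity = identity, clades = clades, representatives = reps,
                 tree = tree, families = families, predictions = predictions,
                 manifest = manifest))
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out[!vapply(out, is.null, TRUE)]
}
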