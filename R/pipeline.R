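# End-to-end orchestration: subtract host -> align markers across an
# identity-threshold sweep -> FC1/FCT profiles per rank -> rarefaction ->
# community comparison -> fungal-fraction extrapolation. Every tabular
# artifact carries the configuration hash and seed in '#' header lines, so
# a rerun with the same configuration is byte-identical.

#' Assemble and validate a pipeline run configuration
#'
#' Inputs are given either as file paths (`reads`, `host`, `markers` +
#' `markers_taxonomy`, optionally `genomes` + `genomes_taxonomy`) or as a
#' `simulate` list of [sim_config()] arguments, in which case the dataset
#' is generated on the fly. Thresholds must lie in (0, 1] and be strictly
#' decreasing; the seed length `k` must satisfy the pigeonhole guarantee
#' `L >= k * (budget + 1)` at the loosest threshold for the shortest read,
#' so every admissible placement is discoverable.
#'
#' @param out_dir Output directory for artifacts.
#' @param reads,host,markers,markers_taxonomy,genomes,genomes_taxonomy
#'   Input file paths (ignored when `simulate` is given; `genomes` is
#'   optional and enables the fraction-estimation stage).
#' @param simulate Optional named list of [sim_config()] arguments.
#' @param thresholds Identity thresholds, strictly decreasing.
#' @param ranks Ranks at which profiles are built.
#' @param k Seed length for all indexes.
#' @param rarefaction List with `replicates` and optional `depths`.
#' @param genome_subset Optional genome record ids used as the calibration
#'   subset for the fraction estimator (default: all genomes).
#' @param seed Seed for the stochastic stages (rarefaction; simulation
#'   uses its own seed inside `simulate`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       reads = NULL, host = NULL,
                       markers = NULL, markers_taxonomy = NULL,
                       genomes = NULL, genomes_taxonomy = NULL,
                       simulate = NULL,
                       thresholds = c(1, 0.99, 0.97, 0.95),
                       ranks = c("phylum", "subphylum", "class", "genus"),
                       k = 16L, rarefaction = list(replicates = 50L),
                       genome_subset = NULL, seed = 1L) {
  if (any(thresholds <= 0) || any(thresholds > 1))
    .fail("thresholds must lie in (0, 1]")
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    .fail("thresholds must be strictly decreasing")
  if (!all(ranks %in% tax_ranks()))
    .fail("unknown rank(s): %s",
          paste(setdiff(ranks, tax_ranks()), collapse = ", "))
  if (is.null(simulate)) {
    if (is.null(reads) || is.null(host) || is.null(markers))
      .fail("reads, host and markers are required without 'simulate'")
    for (p in c(reads, host, markers)) {
      if (!file.exists(p)) .fail("no such file: %s", p)
    }
    if (!is.null(genomes) && !file.exists(genomes))
      .fail("no such file: %s", genomes)
  }
  structure(list(out_dir = out_dir, reads = reads, host = host,
                 markers = markers, markers_taxonomy = markers_taxonomy,
                 genomes = genomes, genomes_taxonomy = genomes_taxonomy,
                 simulate = simulate, thresholds = thresholds,
                 ranks = ranks, k = as.integer(k),
                 rarefaction = rarefaction,
                 genome_subset = genome_subset, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML whose keys are the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# hash of the analysis parameters (the destination directory is excluded,
# so the same analysis rerun elsewhere produces byte-identical artifacts)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate inputs; subtract host reads (100% identity);
#' sweep the identity thresholds against the marker set; build FC1 and FCT
#' profiles at every configured rank (at the loosest threshold); rarefy
#' the FC1 community at the finest configured rank; compare the
#' per-threshold class-level FC1 profiles by Bray-Curtis + neighbour
#' joining (when at least two are non-empty); and, when a genome set is
#' given, extrapolate the total fungal read content. Any stage error
#' aborts with a message naming the stage.
#'
#' @param config A `run_config` (or a YAML path understood by
#'   [read_run_config()]).
#' @return Invisibly, a manifest data.frame (`artifact`, `path`) of every
#'   file written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  hash <- config_hash(config)
  meta <- c(sprintf("config_hash=%s", hash), sprintf("seed=%d", config$seed))
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(line, log_con)
    message("[mycomine] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifest <- list()
  emit <- function(artifact, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      artifact = artifact, path = path, stringsAsFactors = FALSE)
  }

  ## inputs
  inp <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(do.call(sim_config, config$simulate))
      list(reads = sim$reads[, c("read_id", "sequence")],
           host = reference_set("host_genome", sim$host,
                                "UNKNOWN", name = "host",
                                source_kind = "GENOME"),
           markers = sim$markers, genomes = sim$genomes)
    } else {
      fmt <- if (grepl("\\.(fq|fastq)$", config$reads)) "fastq" else "fasta"
      list(reads = read_reads(config$reads, fmt),
           host = read_reference_set(config$host, name = "host",
                                     source_kind = "GENOME"),
           markers = read_reference_set(config$markers,
                                        config$markers_taxonomy,
                                        source_kind = "ITS"),
           genomes = if (is.null(config$genomes)) NULL else
             read_reference_set(config$genomes, config$genomes_taxonomy,
                                source_kind = "GENOME"))
    }
  })
  n_raw <- nrow(inp$reads)
  log("inputs: %d reads, %d marker reference(s), genomes: %s",
      n_raw, nrow(inp$markers),
      if (is.null(inp$genomes)) "none" else nrow(inp$genomes))

  stage("validate", {
    min_L <- min(nchar(inp$reads$sequence))
    t_min <- min(config$thresholds)
    b <- mismatch_budget(min_L, t_min)
    if (min_L < config$k * (b + 1L))
      .fail(paste0("seed length k=%d cannot guarantee detection: need ",
                   "L >= k*(budget+1) = %d but shortest read is %d bp"),
            config$k, config$k * (b + 1L), min_L)
  })

  ## host subtraction
  sub <- stage("subtract-host", {
    host_index <- build_index(inp$host, k = config$k)
    subtract_host(inp$reads, host_index)
  })
  log("subtract-host: total %d = host %d + unmapped %d",
      sub$counts["total"], sub$counts["host_matched"], sub$counts["unmapped"])
  p <- file.path(config$out_dir, "host_subtraction.tsv")
  write_tsv_meta(data.frame(total = sub$counts["total"],
                            host_matched = sub$counts["host_matched"],
                            unmapped = sub$counts["unmapped"],
                            unmapped_fraction =
                              sub$counts["unmapped"] / max(n_raw, 1L)),
                 p, meta)
  emit("host_subtraction", p)

  ## marker alignment sweep
  marker_index <- stage("align", build_index(inp$markers, k = config$k))
  sweeps <- stage("sweep", {
    lapply(setNames(config$ranks, config$ranks), function(rank)
      threshold_sweep(sub$unmapped, marker_index, inp$markers,
                      thresholds = config$thresholds, rank = rank))
  })
  sweep <- sweeps[["class"]] %||% sweeps[[1L]]
  log("sweep: matched %s read(s) at thresholds %s",
      paste(sweep$summary$matched_reads, collapse = "/"),
      paste(sweep$summary$threshold, collapse = "/"))
  sweep_tab <- do.call(rbind, lapply(names(sweeps), function(rank)
    cbind(rank = rank, sweeps[[rank]]$summary)))
  p <- file.path(config$out_dir, "threshold_sweep.tsv")
  write_tsv_meta(sweep_tab, p, meta)
  emit("sweep_summary", p)
  p <- file.path(config$out_dir, "threshold_overlap.tsv")
  write_tsv_meta(sweep$overlap, p, meta)
  emit("sweep_overlap", p)

  ## per-rank FC1/FCT profiles at the loosest threshold
  t_min <- min(config$thresholds)
  hits <- stage("align", align_reads(sub$unmapped, marker_index, t_min))
  profs <- stage("profile", {
    out <- list()
    for (rank in config$ranks) {
      asn <- assign_reads(hits, inp$markers, rank,
                          read_ids = sub$unmapped$read_id)
      for (mode in c("FC1", "FCT")) {
        prof <- build_profile(asn, mode, rank)
        pp <- file.path(config$out_dir,
                        sprintf("profile_%s_%s.tsv", mode, rank))
        write_profile(prof, pp, meta)
        emit(sprintf("profile_%s_%s", mode, rank), pp)
        out[[sprintf("%s_%s", mode, rank)]] <- prof
      }
    }
    out
  })
  log("profile: %d rank(s) x FC1/FCT written", length(config$ranks))

  ## rarefaction at the finest configured rank
  fine <- config$ranks[length(config$ranks)]
  stage("rarefy", {
    asn <- assign_reads(hits, inp$markers, fine)
    labels <- asn$taxon[asn$status == "FC1"]
    if (length(labels)) {
      rc <- rarefy(labels, depths = config$rarefaction$depths,
                   replicates = config$rarefaction$replicates %||% 50L,
                   seed = config$seed)
      pp <- file.path(config$out_dir, "rarefaction.tsv")
      write_tsv_meta(as.data.frame(rc), pp, meta)
      emit("rarefaction", pp)
      log("rarefy: %d depth(s), %d replicate(s), rank %s",
          nrow(rc), attr(rc, "replicates"), fine)
    } else log("rarefy: skipped (no FC1 reads at rank %s)", fine)
  })

  ## community comparison across thresholds (class-level FC1 profiles)
  stage("compare", {
    counts <- lapply(sweep$profiles, function(pr) pr$counts)
    counts <- counts[vapply(counts, function(x) sum(x) > 0, TRUE)]
    if (length(counts) >= 2L) {
      D <- bray_curtis_matrix(counts)
      pp <- file.path(config$out_dir, "bray_curtis.tsv")
      write_tsv_meta(data.frame(label = rownames(D), D,
                                check.names = FALSE), pp, meta)
      emit("bray_curtis", pp)
      tree <- nj_tree(D)
      pt <- file.path(config$out_dir, "community_tree.nwk")
      ape::write.tree(tree, pt)
      emit("community_tree", pt)
      log("compare: %d communities clustered", nrow(D))
    } else log("compare: skipped (fewer than 2 non-empty profiles)")
  })

  ## fungal-fraction extrapolation
  if (!is.null(inp$genomes)) stage("estimate-fraction", {
    subset_ids <- config$genome_subset %||% inp$genomes$record_id
    gsub_set <- inp$genomes[inp$genomes$record_id %in% subset_ids, ,
                            drop = FALSE]
    if (nrow(gsub_set) == 0L) .fail("genome_subset matches no genome")
    genera <- unique(gsub_set$genus)
    marker_sub_ids <- inp$markers$record_id[inp$markers$genus %in% genera]
    gidx <- build_index(structure(gsub_set,
                                  class = c("reference_set", "data.frame"),
                                  name = "genome_subset",
                                  source_kind = "GENOME"),
                        k = config$k)
    ghits <- align_reads(sub$unmapped, gidx, t_min)
    its_full <- length(matched_reads(hits))
    its_sub <- length(matched_reads(
      hits[hits$ref_id %in% marker_sub_ids, , drop = FALSE]))
    est <- estimate_fraction(
      its_hits_full = its_full,
      genome_hits_sub = length(matched_reads(ghits)),
      its_hits_sub = its_sub,
      n_unmapped = as.integer(sub$counts["unmapped"]),
      n_raw = n_raw)
    pp <- file.path(config$out_dir, "fraction_estimate.tsv")
    write_tsv_meta(data.frame(its_hits_full = est$its_hits_full,
                              genome_hits_sub = est$genome_hits_sub,
                              its_hits_sub = est$its_hits_sub,
                              ratio_r = est$ratio_r,
                              total_estimate = est$total_estimate,
                              pct_unmapped = est$pct_unmapped,
                              pct_raw = est$pct_raw), pp, meta)
    emit("fraction_estimate", pp)
    log("estimate-fraction: ratio %.1f, total %.0f (%.2f%% of unmapped)",
        est$ratio_r, est$total_estimate, est$pct_unmapped)
  })

  manifest <- do.call(rbind, manifest)
  p <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
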