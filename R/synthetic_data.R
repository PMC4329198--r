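# Ground-truthed synthetic datasets: a host genome plus a multi-genus
# fungal community whose genomes embed genus-specific marker regions, and
# an error-bearing shotgun read mix with per-read origin labels.
#
# The generator emulates the statistical structure the analysis assumes —
# host/fungal read mixture, marker regions inside fungal genomes, a known
# taxonomy, substitution sequencing errors — not biological realism:
# genomes outside markers are random sequence and the error model has no
# indels (consistent with the ungapped matcher).

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a dominant-genus community (weights 0.88/0.05/0.04/0.03 for four
#' genera), 100,000 reads of 100 bp, 83% of reads from the host, 1%
#' per-base substitution error, 500-bp genus-specific markers embedded
#' once per 30-kb fungal genome.
#'
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param host_length Host genome length in bp.
#' @param n_fungal_genera Number of fungal genera.
#' @param genomes_per_genus Fungal genomes per genus.
#' @param genome_length Length of each fungal genome in bp.
#' @param marker_length Length of the genus marker sequence in bp.
#' @param marker_copies_per_genome Marker copies embedded in each genome.
#' @param composition Per-genus weights (summing to 1). Default: the
#'   dominant-genus weights above for 4 genera, uniform otherwise.
#' @param dirichlet_alpha If given, composition is instead drawn from a
#'   symmetric Dirichlet with this concentration (reproducibly from
#'   `seed`).
#' @param n_reads Total reads to emit.
#' @param read_length Read length L in bp.
#' @param host_fraction Expected fraction of reads drawn from the host.
#' @param error_rate Per-base substitution error rate (in `[0, 0.25)`).
#' @param confusable_distance If given, the second genus's marker is a
#'   copy of the first genus's marker with exactly this many substitutions
#'   (exercises MULTI assignments); default `NULL` (independent markers).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       host_length = 200000L,
                       n_fungal_genera = 4L,
                       genomes_per_genus = 1L,
                       genome_length = 30000L,
                       marker_length = 500L,
                       marker_copies_per_genome = 1L,
                       composition = NULL,
                       dirichlet_alpha = NULL,
                       n_reads = 100000L,
                       read_length = 100L,
                       host_fraction = 0.83,
                       error_rate = 0.01,
                       confusable_distance = NULL) {
  G <- as.integer(n_fungal_genera)
  if (G < 1L) .fail("need at least one fungal genus")
  if (!is.null(dirichlet_alpha)) {
    if (dirichlet_alpha <= 0) .fail("dirichlet_alpha must be positive")
    composition <- withr::with_seed(as.integer(seed), {
      w <- stats::rgamma(G, shape = dirichlet_alpha)
      w / sum(w)
    })
  }
  if (is.null(composition)) {
    composition <- if (G == 4L) c(0.88, 0.05, 0.04, 0.03) else rep(1 / G, G)
  }
  if (length(composition) != G) .fail("composition must have one weight per genus")
  if (any(composition < 0)) .fail("composition weights must be non-negative")
  s <- sum(composition)
  if (abs(s - 1) > 1e-6) .fail("composition weights must sum to 1")
  composition <- composition / s
  if (host_fraction < 0 || host_fraction > 1)
    .fail("host_fraction must be in [0, 1]")
  if (error_rate < 0 || error_rate >= 0.25)
    .fail("error_rate must be in [0, 0.25)")
  if (marker_length >= genome_length)
    .fail("marker_length must be smaller than genome_length")
  if (read_length > genome_length || read_length > host_length)
    .fail("read_length exceeds a source genome length")
  if (read_length < 1L || n_reads < 1L) .fail("need positive read_length and n_reads")
  if (marker_copies_per_genome < 1L) .fail("need at least one marker copy")
  seg <- genome_length %/% marker_copies_per_genome
  if (seg < marker_length)
    .fail("cannot place %d non-overlapping marker copies of %d bp in a %d bp genome",
          marker_copies_per_genome, marker_length, genome_length)
  if (!is.null(confusable_distance)) {
    if (G < 2L) .fail("confusable markers need at least two genera")
    if (confusable_distance < 1L || confusable_distance > marker_length)
      .fail("confusable_distance must be in [1, marker_length]")
  }
  structure(list(seed = as.integer(seed),
                 host_length = as.integer(host_length),
                 n_fungal_genera = G,
                 genomes_per_genus = as.integer(genomes_per_genus),
                 genome_length = as.integer(genome_length),
                 marker_length = as.integer(marker_length),
                 marker_copies_per_genome = as.integer(marker_copies_per_genome),
                 composition = composition,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 host_fraction = host_fraction,
                 error_rate = error_rate,
                 confusable_distance = confusable_distance),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# nested 7-rank lineage for genus g: two genera per class, two classes per
# subphylum, two subphyla per phylum; order mirrors class, family mirrors
# genus, species is genus-specific
genus_lineage <- function(g) {
  cl <- ceiling(g / 2)
  sp <- ceiling(cl / 2)
  ph <- ceiling(sp / 2)
  sprintf("Phylum%02d;Subphylum%02d;Class%02d;Order%02d;Family%02d;Genus%02d;Genus%02d_sp",
          ph, sp, cl, cl, g, g, g)
}

# substitute exactly `d` positions of a DNA string with different bases
mutate_dna <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), d)
  for (p in pos) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a ground-truthed synthetic dataset
#'
#' Builds a random host genome; one marker per fungal genus with a nested
#' seven-rank taxonomy; fungal genomes embedding their genus's marker at
#' recorded coordinates; and a shotgun read mix with per-read truth labels.
#' Host reads are drawn uniformly from the host genome; fungal reads from
#' genomes sampled by the composition weights; every read gets a uniform
#' start, a random strand, and i.i.d. substitution errors at the
#' configured rate (the realized error count is recorded). Fully
#' reproducible from `config$seed`; identical seeds give byte-identical
#' output files.
#'
#' @param config A [sim_config()].
#' @param out_dir If given, files are written there: `host.fasta`,
#'   `genomes.fasta` + `genomes_taxonomy.tsv`, `markers.fasta` +
#'   `markers_taxonomy.tsv`, `reads.fastq`, `truth.tsv`.
#' @return A `sim_dataset` list: `config`, `host` (named sequence),
#'   `markers` (a `reference_set`, source ITS), `genomes` (a
#'   `reference_set`, source GENOME), `marker_coords` (data.frame
#'   `genome_id`, `copy`, `start`, `end`), `reads` (data.frame `read_id`,
#'   `sequence`, `quality`), `truth` (data.frame `read_id`, `origin`,
#'   `genus`, `genome_id`, `start`, `strand`, `overlaps_marker`,
#'   `within_marker`, `n_errors`), and `files` (paths, if written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$read_length > cfg$marker_length)
    warning("read_length exceeds marker_length: no read can match a marker end-to-end",
            call. = FALSE)

  res <- withr::with_seed(cfg$seed, {
    G <- cfg$n_fungal_genera
    L <- cfg$read_length
    genus_names <- sprintf("Genus%02d", seq_len(G))

    host_seq <- random_dna(cfg$host_length)

    marker_seqs <- vapply(seq_len(G), function(g) random_dna(cfg$marker_length), "")
    if (!is.null(cfg$confusable_distance))
      marker_seqs[2L] <- mutate_dna(marker_seqs[1L], cfg$confusable_distance)
    markers <- reference_set(
      record_id = paste0("marker_", genus_names),
      sequence = marker_seqs,
      lineage = vapply(seq_len(G), genus_lineage, ""),
      name = "synthetic_markers", source_kind = "ITS")

    # genomes: random background with marker copies embedded, one copy per
    # equal-length segment so copies never overlap
    n_genomes <- G * cfg$genomes_per_genus
    genome_ids <- character(n_genomes)
    genome_genus <- integer(n_genomes)
    genome_seqs <- character(n_genomes)
    coords <- vector("list", n_genomes)
    seg <- cfg$genome_length %/% cfg$marker_copies_per_genome
    gi <- 0L
    for (g in seq_len(G)) {
      for (j in seq_len(cfg$genomes_per_genus)) {
        gi <- gi + 1L
        genome_ids[gi] <- sprintf("genome_%s_%d", genus_names[g], j)
        genome_genus[gi] <- g
        s <- random_dna(cfg$genome_length)
        starts <- integer(cfg$marker_copies_per_genome)
        for (cp in seq_len(cfg$marker_copies_per_genome)) {
          lo <- (cp - 1L) * seg + 1L
          starts[cp] <- lo + sample.int(seg - cfg$marker_length + 1L, 1L) - 1L
          substr(s, starts[cp], starts[cp] + cfg$marker_length - 1L) <-
            marker_seqs[g]
        }
        genome_seqs[gi] <- s
        coords[[gi]] <- data.frame(genome_id = genome_ids[gi],
                                   copy = seq_along(starts),
                                   start = starts,
                                   end = starts + cfg$marker_length - 1L,
                                   stringsAsFactors = FALSE)
      }
    }
    genomes <- reference_set(
      record_id = genome_ids, sequence = genome_seqs,
      lineage = vapply(genome_genus, genus_lineage, ""),
      name = "synthetic_genomes", source_kind = "GENOME")
    marker_coords <- do.call(rbind, coords)

    # reads
    n <- cfg$n_reads
    read_id <- sprintf("read_%07d", seq_len(n))
    is_host <- stats::runif(n) < cfg$host_fraction
    genus_idx <- rep(NA_integer_, n)
    genome_idx <- rep(NA_integer_, n)
    nf <- sum(!is_host)
    if (nf > 0L) {
      genus_idx[!is_host] <- sample.int(G, nf, replace = TRUE,
                                        prob = cfg$composition)
      within <- sample.int(cfg$genomes_per_genus, nf, replace = TRUE)
      genome_idx[!is_host] <- (genus_idx[!is_host] - 1L) *
        cfg$genomes_per_genus + within
    }
    src_len <- ifelse(is_host, cfg$host_length,
                      cfg$genome_length)
    start <- floor(stats::runif(n) * (src_len - L + 1)) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)

    seqs <- character(n)
    if (any(is_host))
      seqs[is_host] <- substring(host_seq, start[is_host],
                                 start[is_host] + L - 1L)
    if (nf > 0L) {
      fi <- which(!is_host)
      for (gidx in unique(genome_idx[fi])) {
        sel <- fi[genome_idx[fi] == gidx]
        seqs[sel] <- substring(genome_seqs[gidx], start[sel],
                               start[sel] + L - 1L)
      }
    }
    rev <- strand == "-"
    if (any(rev))
      seqs[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev])))

    # i.i.d. substitution errors: binomial count per read, uniform positions,
    # each substitution forced to a different base
    n_err <- stats::rbinom(n, L, cfg$error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(L, n_err[i])
      for (p in pos) {
        b <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(.BASES, b), 1L)
      }
    }

    # marker overlap flags (coordinates are on the source genome, pre-strand)
    overlaps <- rep(FALSE, n)
    within_marker <- rep(FALSE, n)
    if (nf > 0L) {
      fi <- which(!is_host)
      for (gidx in unique(genome_idx[fi])) {
        sel <- fi[genome_idx[fi] == gidx]
        mc <- coords[[gidx]]
        for (r in seq_len(nrow(mc))) {
          ov <- start[sel] <= mc$end[r] & (start[sel] + L - 1L) >= mc$start[r]
          wi <- start[sel] >= mc$start[r] & (start[sel] + L - 1L) <= mc$end[r]
          overlaps[sel] <- overlaps[sel] | ov
          within_marker[sel] <- within_marker[sel] | wi
        }
      }
    }

    truth <- data.frame(
      read_id = read_id,
      origin = ifelse(is_host, "HOST", "FUNGAL"),
      genus = ifelse(is_host, NA_character_, genus_names[genus_idx]),
      genome_id = ifelse(is_host, "host_genome", genome_ids[genome_idx]),
      start = start, strand = strand,
      overlaps_marker = overlaps, within_marker = within_marker,
      n_errors = n_err, stringsAsFactors = FALSE)

    reads <- data.frame(read_id = read_id, sequence = seqs,
                        quality = strrep("I", L), stringsAsFactors = FALSE)

    list(host = host_seq, markers = markers, genomes = genomes,
         marker_coords = marker_coords, reads = reads, truth = truth)
  })

  out <- c(list(config = cfg), res)
  class(out) <- "sim_dataset"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(host = file.path(out_dir, "host.fasta"),
               genomes = file.path(out_dir, "genomes.fasta"),
               genomes_tax = file.path(out_dir, "genomes_taxonomy.tsv"),
               markers = file.path(out_dir, "markers.fasta"),
               markers_tax = file.path(out_dir, "markers_taxonomy.tsv"),
               reads = file.path(out_dir, "reads.fastq"),
               truth = file.path(out_dir, "truth.tsv"))
    host_dss <- Biostrings::DNAStringSet(setNames(res$host, "host_genome"))
    Biostrings::writeXStringSet(host_dss, paths[["host"]])
    write_reference_set(res$genomes, paths[["genomes"]], paths[["genomes_tax"]])
    write_reference_set(res$markers, paths[["markers"]], paths[["markers_tax"]])
    write_fastq(res$reads, paths[["reads"]])
    utils::write.table(res$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$files <- paths
  }
  out
}

# plain 4-line-per-record FASTQ writer (constant placeholder qualities)
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality),
             con)
  invisible(path)
}

#' Read a FASTQ/FASTA file into the package's reads representation
#'
#' Qualities are not retained (the matcher ignores them).
#'
#' @param path FASTQ or FASTA file.
#' @param format `"fastq"` or `"fasta"`.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dss <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(read_id = sub("\\s.*$", "", names(dss)),
             sequence = as.character(dss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected fraction of fungal reads overlapping a marker copy
#'
#' Closed-form companion of [simulate_dataset()]: a read of length L
#' overlaps a marker of length m embedded in a genome of length G from
#' `m + L - 1` of the ~G possible start positions, so the per-genome
#' fraction is `copies * (m + L - 1) / G` (capped at 1), and the overall
#' expectation is the composition-weighted mean over genomes. Used as an
#' analytic oracle for the fraction-estimator tests; the small edge effect
#' (starts range over `G - L + 1`, not `G`) is ignored.
#'
#' @param config A [sim_config()].
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_marker_read_fraction <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_genome <- min(1, config$marker_copies_per_genome *
                      (config$marker_length + config$read_length - 1) /
                      config$genome_length)
  # all genomes share length/copies, so the weighted mean equals per_genome
  sum(config$composition * per_genome)
}
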