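# FC1/FCT taxon assignment and per-rank community tables.
#
# FC1: the community of reads whose best-stratum hits all agree on a single
# taxon at the rank under consideration; the only mode with a defined
# relative abundance. FCT: the presence catalogue over all matched reads,
# including multi-taxon reads; it overestimates richness and carries only
# supporting-read counts, never abundances.

#' Assign matched reads to taxa at one rank
#'
#' For each read, the distinct taxa named at `rank` by its best-stratum
#' hits are collected (hits whose lineage is `"UNKNOWN"` at that rank are
#' ignored for the agreement vote). A read is `FC1` when exactly one taxon
#' remains, `MULTI` when several distinct taxa remain or when every hit is
#' `UNKNOWN` at the rank (unassignable), and `UNMATCHED` when it has no
#' hits at all.
#'
#' @param hits A `hit_table` from [align_reads()].
#' @param refset The [reference_set()] the hits refer to; every `ref_id`
#'   must resolve in it.
#' @param rank One of [tax_ranks()].
#' @param read_ids Optional character vector defining the full read
#'   universe, so unmatched reads appear with status `UNMATCHED`. Defaults
#'   to the reads present in `hits`.
#' @return A `read_assignment` data.frame: `read_id`, `status`
#'   (`UNMATCHED`/`FC1`/`MULTI`), `taxon` (the agreed taxon for FC1 reads,
#'   otherwise `NA`), and the list column `hit_taxa` (distinct non-UNKNOWN
#'   taxa hit). Attribute `rank` records the rank used.
#' @export
assign_reads <- function(hits, refset, rank, read_ids = NULL) {
  stopifnot(inherits(refset, "reference_set"))
  if (!(rank %in% tax_ranks())) .fail("unknown rank '%s'", rank)
  read_ids <- read_ids %||% unique(hits$read_id)

  if (nrow(hits)) {
    m <- match(hits$ref_id, refset$record_id)
    if (anyNA(m))
      .fail("hit ref_id not found in reference set: %s",
            hits$ref_id[which(is.na(m))[1L]])
    H <- data.table::data.table(read_id = hits$read_id,
                                taxon = refset[[rank]][m])
    agg <- H[, list(hit_taxa = list(sort(unique(taxon[taxon != .UNKNOWN])))),
             by = "read_id"]
    n_taxa <- vapply(agg$hit_taxa, length, 1L)
    all_unknown <- n_taxa == 0L
    status <- ifelse(n_taxa == 1L, "FC1", "MULTI")
    taxon <- ifelse(n_taxa == 1L,
                    vapply(agg$hit_taxa,
                           function(v) if (length(v)) v[1L] else NA_character_,
                           ""),
                    NA_character_)
    out <- data.frame(read_id = agg$read_id, status = status, taxon = taxon,
                      stringsAsFactors = FALSE)
    out$hit_taxa <- agg$hit_taxa
  } else {
    out <- data.frame(read_id = character(), status = character(),
                      taxon = character(), stringsAsFactors = FALSE)
    out$hit_taxa <- list()
  }

  missing_ids <- setdiff(read_ids, out$read_id)
  if (length(missing_ids)) {
    um <- data.frame(read_id = missing_ids, status = "UNMATCHED",
                     taxon = NA_character_, stringsAsFactors = FALSE)
    um$hit_taxa <- rep(list(character()), length(missing_ids))
    out <- rbind(out, um)
  }
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("read_assignment", "data.frame"), rank = rank)
}

#' Build an FC1 or FCT community profile at one rank
#'
#' In `FC1` mode only FC1 reads are counted, one count per read, so counts
#' sum to the number of FC1 reads at that rank. In `FCT` mode every taxon
#' appearing among any matched read's hit taxa is recorded with its number
#' of supporting reads — a presence catalogue, not an abundance table.
#'
#' @param assignments A `read_assignment` from [assign_reads()].
#' @param mode `"FC1"` or `"FCT"`.
#' @param rank Rank the profile is built at; must equal the rank the
#'   assignments were produced at.
#' @return A `community_profile`: list with `mode`, `rank`, `counts`
#'   (named integer vector, taxa sorted by count desc then name asc),
#'   `total_reads_considered`.
#' @export
build_profile <- function(assignments, mode = c("FC1", "FCT"),
                          rank = attr(assignments, "rank")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assignments, "read_assignment"))
  if (!identical(rank, attr(assignments, "rank")))
    .fail("profile rank '%s' does not match assignment rank '%s'",
          rank, attr(assignments, "rank"))
  if (mode == "FC1") {
    tx <- assignments$taxon[assignments$status == "FC1"]
    counts <- table(tx)
  } else {
    keep <- assignments$status != "UNMATCHED"
    tx <- unlist(assignments$hit_taxa[keep], use.names = FALSE)
    counts <- table(tx)
  }
  counts <- setNames(as.integer(counts), names(counts) %||% character())
  # dominance order: count desc, then name asc (deterministic tie-break)
  if (length(counts))
    counts <- counts[order(-counts, names(counts))]
  structure(list(mode = mode, rank = rank, counts = counts,
                 total_reads_considered = nrow(assignments)),
            class = "community_profile")
}

#' Relative abundance of an FC1 profile
#'
#' Defined only for FC1 profiles: multi-taxon (FCT) reads make exact
#' abundance calculation impossible, so requesting abundance of an FCT
#' profile is an error.
#'
#' @param profile A `community_profile` in FC1 mode with at least one read.
#' @return Named numeric vector of fractions summing to 1.
#' @export
relative_abundance <- function(profile) {
  stopifnot(inherits(profile, "community_profile"))
  if (profile$mode != "FC1")
    .fail("abundance undefined for FCT profiles")
  total <- sum(profile$counts)
  if (total == 0L) .fail("empty profile: no FC1 reads at rank '%s'",
                         profile$rank)
  profile$counts / total
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> mode=%s rank=%s | %d taxa, %d read(s)\n",
              x$mode, x$rank, length(x$counts), sum(x$counts)))
  shown <- utils::head(x$counts, 8L)
  for (i in seq_along(shown))
    cat(sprintf("  %-28s %d\n", names(shown)[i], shown[i]))
  if (length(x$counts) > 8L) cat(sprintf("  ... %d more\n",
                                         length(x$counts) - 8L))
  invisible(x)
}

#' Write a community profile as TSV
#'
#' Columns: `rank`, `taxon`, `reads`, and (FC1 mode only) `fraction`.
#'
#' @param profile A `community_profile`.
#' @param path Output path.
#' @param meta Optional character vector of `#`-prefixed header lines.
#' @export
write_profile <- function(profile, path, meta = character()) {
  df <- data.frame(rank = profile$rank, taxon = names(profile$counts),
                   reads = as.integer(profile$counts),
                   stringsAsFactors = FALSE)
  if (profile$mode == "FC1" && sum(profile$counts) > 0)
    df$fraction <- as.numeric(relative_abundance(profile))
  write_tsv_meta(df, path, c(sprintf("mode=%s", profile$mode), meta))
}

#' Sweep identity thresholds and compare the resulting communities
#'
#' Aligns the reads once at the loosest threshold and derives each stricter
#' community by filtering on the per-read minimal mismatch count (the best
#' stratum is identical wherever the read is admissible, so this is exact).
#' Matched-read sets are nested: lowering the threshold never removes a
#' matched read.
#'
#' @param reads Reads (data.frame or named character vector).
#' @param index A `seed_index` over the marker reference set.
#' @param refset The matching [reference_set()].
#' @param thresholds Strictly decreasing identity thresholds
#'   (default `c(1, 0.99, 0.97, 0.95)`).
#' @param rank Rank for the FC1 profiles and richness (default `"class"`).
#' @return A `threshold_sweep` list: `summary` (per-threshold matched
#'   reads, matched ratio, FC1 reads, FC1 richness), `profiles` (FC1
#'   profile per threshold), `matched_ids` (per-threshold matched read
#'   ids), `presence` (taxon x threshold logical matrix), and `overlap`
#'   (pairwise shared/unique taxon counts).
#' @export
threshold_sweep <- function(reads, index, refset,
                            thresholds = c(1, 0.99, 0.97, 0.95),
                            rank = "class") {
  if (length(thresholds) < 1L || any(diff(thresholds) >= 0))
    .fail("thresholds must be strictly decreasing")
  reads <- as_reads(reads)
  t_min <- thresholds[length(thresholds)]
  hits <- align_reads(reads, index, min_identity = t_min)

  profiles <- list()
  matched_ids <- list()
  summary <- data.frame(threshold = thresholds, matched_reads = NA_integer_,
                        matched_ratio = NA_real_, fc1_reads = NA_integer_,
                        richness = NA_integer_)
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    keep <- hits$mismatches <= mismatch_budget(hits$read_length, t)
    sub <- hits[keep, , drop = FALSE]
    asn <- assign_reads(sub, refset, rank)
    prof <- build_profile(asn, "FC1", rank)
    key <- sprintf("%.2f", t)
    profiles[[key]] <- prof
    matched_ids[[key]] <- matched_reads(sub)
    summary$matched_reads[i] <- length(matched_ids[[key]])
    summary$matched_ratio[i] <- length(matched_ids[[key]]) / max(nrow(reads), 1L)
    summary$fc1_reads[i] <- sum(asn$status == "FC1")
    summary$richness[i] <- length(prof$counts)
  }

  all_taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))
  presence <- vapply(profiles,
                     function(p) all_taxa %in% names(p$counts),
                     logical(length(all_taxa)))
  presence <- matrix(presence, nrow = length(all_taxa),
                     dimnames = list(all_taxa, names(profiles)))

  pairs <- utils::combn(seq_along(thresholds), 2L)
  overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- names(profiles)[pairs[1L, j]]
    b <- names(profiles)[pairs[2L, j]]
    ta <- names(profiles[[a]]$counts)
    tb <- names(profiles[[b]]$counts)
    data.frame(threshold_a = a, threshold_b = b,
               shared = length(intersect(ta, tb)),
               unique_a = length(setdiff(ta, tb)),
               unique_b = length(setdiff(tb, ta)),
               stringsAsFactors = FALSE)
  }))

  structure(list(summary = summary, profiles = profiles,
                 matched_ids = matched_ids, presence = presence,
                 overlap = overlap, rank = rank),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> rank=%s\n", x$rank))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
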