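# Host subtraction and identity-threshold marker matching.
#
# The matcher emulates bowtie-1 `--best --strata` semantics: end-to-end
# ungapped placement of each read (both strands), Hamming mismatches over
# the full read length, an identity threshold translated into a mismatch
# budget, and reporting of the minimal-mismatch stratum only.

#' Maximum mismatches allowed at an identity threshold
#'
#' A minimum identity `t` on a read of length `L` translates into a budget
#' of `floor((1 - t) * L)` mismatches: identity is computed per read as
#' `(L - mismatches) / L`, and the floor makes the threshold conservative
#' (95% on a 76-bp read allows at most 3 mismatches, not 4).
#'
#' @param L Read length (>= 1).
#' @param min_identity Minimum identity in (0, 1].
#' @return Integer mismatch budget.
#' @export
#' @examples
#' mismatch_budget(100, 0.95)  # 5
#' mismatch_budget(76, 0.95)   # 3
mismatch_budget <- function(L, min_identity) {
  if (!is.numeric(min_identity) || any(min_identity <= 0) ||
      any(min_identity > 1))
    .fail("min_identity must be in (0, 1]")
  if (!is.numeric(L) || any(L < 1)) .fail("read length must be >= 1")
  as.integer(floor((1 - min_identity) * L + 1e-9))
}

# normalize reads input: data.frame(read_id, sequence[, quality]) or a
# named character vector
as_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
    reads <- data.frame(read_id = ids, sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id))
    .fail("duplicate read_id: %s",
          reads$read_id[duplicated(reads$read_id)][1L])
  reads
}

#' Build an exact k-mer seed index over a reference set
#'
#' Every length-`k` substring of every reference (forward strand only,
#' skipping windows containing non-ACGT codes) is indexed. With a mismatch
#' budget `b`, seed discovery of every admissible placement is guaranteed
#' when the read length satisfies `L >= k * (b + 1)` (pigeonhole); the
#' pipeline enforces this at configuration time.
#'
#' @param refset A [reference_set()].
#' @param k Seed length (8--31; default 16).
#' @return A `seed_index` object.
#' @export
build_index <- function(refset, k = 16L) {
  stopifnot(inherits(refset, "reference_set"))
  k <- as.integer(k)
  if (is.na(k) || k < 8L || k > 31L) .fail("seed length k must be in [8, 31]")
  ptr <- cpp_build_index(refset$record_id, refset$sequence, k)
  structure(list(ptr = ptr, k = k, name = attr(refset, "name"),
                 n_refs = nrow(refset)),
            class = "seed_index")
}

#' Summary statistics of a seed index
#'
#' @param index A `seed_index`.
#' @return List with `n_refs`, `k`, `n_postings`, `ref_ids`, `ref_lengths`.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "seed_index"))
  cpp_index_info(index$ptr)
}

#' @export
print.seed_index <- function(x, ...) {
  s <- index_stats(x)
  cat(sprintf("<seed_index '%s'> %d reference(s), k=%d, %.0f posting(s)\n",
              x$name, s$n_refs, s$k, s$n_postings))
  invisible(x)
}

#' Align reads to an indexed reference set (best stratum only)
#'
#' Each read is placed end-to-end and ungapped on both strands of every
#' reference it shares an exact seed k-mer with (at a compatible offset).
#' Placements within the mismatch budget implied by `min_identity` are
#' scored by Hamming distance over the full read; any position where either
#' base is not A/C/G/T counts as a mismatch. Only the minimal-mismatch
#' stratum is reported, with all distinct `(ref_id, offset, strand)`
#' placements deduplicated. Reads shorter than the seed length are
#' classified unmatched with a warning.
#'
#' @param reads A data.frame with columns `read_id`, `sequence` (a named
#'   character vector also works).
#' @param index A `seed_index` from [build_index()].
#' @param min_identity Minimum identity threshold in (0, 1].
#' @return A `hit_table` data.frame: `read_id`, `ref_id`, `strand`
#'   (`"+"`/`"-"`), `offset` (0-based start on the reference),
#'   `mismatches`, `read_length`, `identity`. A read absent from the table
#'   is unmatched. Attributes: `min_identity`, `n_reads`.
#' @export
align_reads <- function(reads, index, min_identity = 0.95) {
  stopifnot(inherits(index, "seed_index"))
  if (!is.numeric(min_identity) || length(min_identity) != 1L ||
      min_identity <= 0 || min_identity > 1)
    .fail("min_identity must be a single value in (0, 1]")
  reads <- as_reads(reads)
  if (nrow(reads) == 0L) {
    hits <- data.frame(read_id = character(), ref_id = character(),
                       strand = character(), offset = integer(),
                       mismatches = integer(), read_length = integer(),
                       identity = numeric(), stringsAsFactors = FALSE)
  } else {
    res <- cpp_align(index$ptr, as.character(reads$read_id),
                     toupper(reads$sequence), min_identity)
    hits <- res$hits
    if (length(res$short_reads))
      warning(sprintf(
        "%d read(s) shorter than the seed length (k=%d) classified unmatched",
        length(res$short_reads), index$k), call. = FALSE)
  }
  structure(hits, class = c("hit_table", "data.frame"),
            min_identity = min_identity, n_reads = nrow(reads))
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read; the returned
#' rows are that read's best-stratum hit set (empty if unmatched).
#'
#' @param read_id,sequence Identifier and sequence of the read.
#' @inheritParams align_reads
#' @export
align_read <- function(read_id, sequence, index, min_identity = 0.95) {
  align_reads(data.frame(read_id = read_id, sequence = sequence,
                         stringsAsFactors = FALSE),
              index, min_identity)
}

#' Read ids with at least one hit
#'
#' @param hits A `hit_table`.
#' @return Character vector of unique matched read ids.
#' @export
matched_reads <- function(hits) unique(hits$read_id)

#' Remove reads matching the host genome at 100% identity
#'
#' A read is classified as host iff it has at least one perfect (zero
#' mismatch) end-to-end placement on either strand of the host genome,
#' mirroring host-genome exclusion at 100% similarity. The operation is
#' idempotent: subtracting twice changes nothing.
#'
#' @param reads Reads (data.frame or named character vector).
#' @param host_index A `seed_index` built over the host genome FASTA.
#' @return A `host_subtraction` list: `unmapped` (data.frame of surviving
#'   reads), `host_read_ids`, and `counts` (`total`, `host_matched`,
#'   `unmapped`; `total = host_matched + unmapped`).
#' @export
subtract_host <- function(reads, host_index) {
  reads <- as_reads(reads)
  if (nrow(reads) == 0L) {
    return(structure(list(unmapped = reads, host_read_ids = character(),
                          counts = c(total = 0L, host_matched = 0L,
                                     unmapped = 0L)),
                     class = "host_subtraction"))
  }
  hits <- suppressWarnings(align_reads(reads, host_index, min_identity = 1.0))
  host_ids <- matched_reads(hits)
  keep <- !(reads$read_id %in% host_ids)
  structure(list(unmapped = reads[keep, , drop = FALSE],
                 host_read_ids = host_ids,
                 counts = c(total = nrow(reads),
                            host_matched = length(host_ids),
                            unmapped = sum(keep))),
            class = "host_subtraction")
}

#' @export
print.host_subtraction <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(
    "<host_subtraction> total %d | host-matched %d (%.2f%%) | unmapped %d (%.2f%%)\n",
    ct["total"], ct["host_matched"], 100 * ct["host_matched"] / max(ct["total"], 1L),
    ct["unmapped"], 100 * ct["unmapped"] / max(ct["total"], 1L)))
  invisible(x)
}
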