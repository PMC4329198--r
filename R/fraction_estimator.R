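# Ratio-based extrapolation of the total fungal read content.
#
# Marker (e.g. ITS) hits see only the small slice of each fungal genome
# covered by the marker. For a subset of fungi with sequenced genomes AND
# marker sequences, the ratio r = genome hits / marker hits calibrates how
# many genome-wide reads stand behind one marker hit; applying r to the
# marker hits against the full marker dataset extrapolates the total
# fungal read content of the unmapped pool.

#' Extrapolate the total fungal read count from marker and genome hits
#'
#' All five inputs are deduplicated read counts obtained at the same
#' identity threshold (default 0.95 throughout the pipeline).
#'
#' @param its_hits_full Reads matching the full marker reference dataset.
#' @param genome_hits_sub Reads matching the genome subset.
#' @param its_hits_sub Reads matching the subset's own marker sequences
#'   (must be >= 1, otherwise the ratio is undefined).
#' @param n_unmapped Size of the unmapped read pool (>= `its_hits_full`).
#' @param n_raw Size of the raw read pool (>= `n_unmapped`).
#' @return A `fraction_estimate` list: the five inputs plus `ratio_r`
#'   (`genome_hits_sub / its_hits_sub`), `total_estimate`
#'   (`its_hits_full * ratio_r`), `frac_unmapped`, `frac_raw`
#'   (proportions) and `pct_unmapped`, `pct_raw` (percentages). Full
#'   precision is kept; the print method rounds to the conventional
#'   presentation (ratio 1 d.p., percentages 2 d.p.).
#' @export
estimate_fraction <- function(its_hits_full, genome_hits_sub, its_hits_sub,
                              n_unmapped, n_raw) {
  vals <- c(its_hits_full = its_hits_full, genome_hits_sub = genome_hits_sub,
            its_hits_sub = its_hits_sub, n_unmapped = n_unmapped,
            n_raw = n_raw)
  if (any(!is.finite(vals)) || any(vals < 0))
    .fail("all counts must be finite and non-negative")
  if (its_hits_sub < 1) .fail("ratio undefined: its_hits_sub must be >= 1")
  if (n_raw < n_unmapped) .fail("n_raw must be >= n_unmapped")
  if (n_unmapped < its_hits_full)
    .fail("n_unmapped must be >= its_hits_full")
  ratio_r <- genome_hits_sub / its_hits_sub
  total_estimate <- its_hits_full * ratio_r
  structure(list(its_hits_full = its_hits_full,
                 genome_hits_sub = genome_hits_sub,
                 its_hits_sub = its_hits_sub,
                 n_unmapped = n_unmapped, n_raw = n_raw,
                 ratio_r = ratio_r, total_estimate = total_estimate,
                 frac_unmapped = total_estimate / n_unmapped,
                 frac_raw = total_estimate / n_raw,
                 pct_unmapped = 100 * total_estimate / n_unmapped,
                 pct_raw = 100 * total_estimate / n_raw),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("<fraction_estimate>\n")
  cat(sprintf("  marker hits (full dataset) : %s\n",
              format(x$its_hits_full, big.mark = ",")))
  cat(sprintf("  genome/marker hit ratio r  : %.1f  (%s / %s)\n", x$ratio_r,
              format(x$genome_hits_sub, big.mark = ","),
              format(x$its_hits_sub, big.mark = ",")))
  cat(sprintf("  estimated total reads      : %s\n",
              format(round(x$total_estimate), big.mark = ",")))
  cat(sprintf("  of unmapped pool           : %.2f%%\n", x$pct_unmapped))
  cat(sprintf("  of raw pool                : %.2f%%\n", x$pct_raw))
  invisible(x)
}

#' Matched reads per reference sequence
#'
#' Normalizes a matched-read count by the size of the reference dataset,
#' making marker datasets of different sizes comparable.
#'
#' @param matched_reads Matched read count (>= 0).
#' @param n_references Number of reference sequences (>= 1).
#' @return `matched_reads / n_references` at full precision.
#' @export
#' @examples
#' reads_per_reference(89, 2362)
reads_per_reference <- function(matched_reads, n_references) {
  if (n_references < 1) .fail("n_references must be >= 1")
  if (matched_reads < 0) .fail("matched_reads must be >= 0")
  matched_reads / n_references
}
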