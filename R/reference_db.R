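# Marker reference sets: FASTA sequences plus a seven-rank lineage per record.

# Parse semicolon-delimited lineage strings into a 7-column character matrix.
# Accepts optional "p__Ascomycota"-style rank prefixes; empty or missing
# fields become UNKNOWN. `where` describes the source for error messages.
parse_lineages <- function(x, where = "lineage") {
  ranks <- tax_ranks()
  out <- matrix(.UNKNOWN, nrow = length(x), ncol = 7,
                dimnames = list(NULL, ranks))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s)) next
    if (grepl("\t", s, fixed = TRUE))
      .fail("%s %d: tab character inside lineage string", where, i)
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (length(parts) > 7)
      .fail("%s %d: more than seven ranks ('%s')", where, i, s)
    parts <- sub("^[A-Za-z]+__", "", trimws(parts))
    parts[parts == ""] <- .UNKNOWN
    if (length(parts)) out[i, seq_along(parts)] <- parts
  }
  out
}

# TRUE where a named rank sits below an UNKNOWN rank (permitted but flagged)
lineage_has_gap <- function(lin_mat) {
  apply(lin_mat, 1L, function(r) {
    unk <- r == .UNKNOWN
    any(unk) && any(!unk & cumsum(unk) > 0)
  })
}

#' Load a marker reference set from FASTA (+ optional taxonomy sidecar)
#'
#' Reads marker sequences (ITS, LSU, or whole genomes used as references)
#' together with a seven-rank lineage per record. Lineages come either from
#' a two-column tab-separated sidecar file (`record_id<TAB>lineage`, lineage
#' semicolon-delimited from phylum down to species, optionally with
#' `p__`-style prefixes) or, when `taxonomy` is `NULL`, from the FASTA
#' header itself: everything after the first whitespace in the header is
#' parsed as the lineage string.
#'
#' Sequences are uppercased and `U` is mapped to `T`; IUPAC ambiguity codes
#' are retained. Unresolvable ranks become `"UNKNOWN"`. Records whose
#' lineage names a rank below an `"UNKNOWN"` rank are kept but flagged in
#' the `lineage_gap` column.
#'
#' @param fasta_path Path to the reference FASTA file.
#' @param taxonomy Path to the taxonomy sidecar TSV, or `NULL` to parse
#'   lineages from FASTA headers.
#' @param name Name for the reference set (defaults to the file name).
#' @param source_kind One of `"ITS"`, `"LSU"`, `"GENOME"`.
#' @return A `reference_set`: a data.frame with columns `record_id`,
#'   `sequence`, the seven ranks, `lineage_gap`, and attributes `name` and
#'   `source_kind`.
#' @export
read_reference_set <- function(fasta_path, taxonomy = NULL,
                               name = basename(fasta_path),
                               source_kind = c("ITS", "LSU", "GENOME")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(fasta_path)) .fail("no such file: %s", fasta_path)
  # read as raw strings so RNA-style U survives long enough to be mapped to T
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) .fail("empty reference FASTA: %s", fasta_path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    .fail("duplicate record_id in %s: %s", fasta_path, dup[1L])
  sequence <- chartr("U", "T", toupper(as.character(seqs)))
  if (any(nchar(sequence) < 1L)) .fail("zero-length reference sequence")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", sequence)
  if (any(bad))
    .fail("record %s contains non-IUPAC characters", ids[which(bad)[1L]])

  if (is.null(taxonomy)) {
    lin_str <- ifelse(grepl("\\s", headers),
                      sub("^\\S+\\s+", "", headers), NA_character_)
    lin <- parse_lineages(lin_str, where = sprintf("%s record", fasta_path))
  } else {
    if (!file.exists(taxonomy)) .fail("no such file: %s", taxonomy)
    lines <- readLines(taxonomy)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) != 2L)
    if (length(bad))
      .fail("%s line %d: expected 2 tab-separated columns", taxonomy, bad[1L])
    tab_id <- vapply(fields, `[[`, "", 1L)
    tab_lin <- vapply(fields, `[[`, "", 2L)
    lin_all <- parse_lineages(tab_lin, where = sprintf("%s line", taxonomy))
    m <- match(ids, tab_id)
    lin <- matrix(.UNKNOWN, nrow = length(ids), ncol = 7,
                  dimnames = list(NULL, tax_ranks()))
    ok <- !is.na(m)
    lin[ok, ] <- lin_all[m[ok], , drop = FALSE]
  }

  df <- data.frame(record_id = ids, sequence = sequence,
                   lin, lineage_gap = lineage_has_gap(lin),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(df, class = c("reference_set", "data.frame"),
            name = name, source_kind = source_kind)
}

#' Construct a reference set from in-memory vectors
#'
#' Programmatic counterpart of [read_reference_set()], used by the
#' synthetic-data generator and in tests.
#'
#' @param record_id Character vector of unique record ids.
#' @param sequence Character vector of DNA sequences (IUPAC codes).
#' @param lineage Character vector of semicolon-delimited lineages (or a
#'   7-column matrix with the rank names of [tax_ranks()]).
#' @param name,source_kind As in [read_reference_set()].
#' @return A `reference_set`.
#' @export
reference_set <- function(record_id, sequence, lineage,
                          name = "reference_set",
                          source_kind = c("ITS", "LSU", "GENOME")) {
  source_kind <- match.arg(source_kind)
  if (anyDuplicated(record_id))
    .fail("duplicate record_id: %s", record_id[duplicated(record_id)][1L])
  if (length(sequence) != length(record_id))
    .fail("record_id and sequence lengths differ")
  lin <- if (is.matrix(lineage)) lineage else parse_lineages(lineage)
  sequence <- chartr("Uu", "TT", toupper(sequence))
  df <- data.frame(record_id = as.character(record_id), sequence = sequence,
                   lin, lineage_gap = lineage_has_gap(lin),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(df, class = c("reference_set", "data.frame"),
            name = name, source_kind = source_kind)
}

#' Write a reference set back to FASTA plus taxonomy TSV
#'
#' Round-trip companion of [read_reference_set()]: reloading the written
#' pair yields an identical set (same ids, sequences, lineages).
#'
#' @param refset A `reference_set`.
#' @param fasta_path Output FASTA path.
#' @param taxonomy_path Output taxonomy TSV path.
#' @return Invisibly, the two paths.
#' @export
write_reference_set <- function(refset, fasta_path, taxonomy_path) {
  stopifnot(inherits(refset, "reference_set"))
  dss <- Biostrings::DNAStringSet(refset$sequence)
  names(dss) <- refset$record_id
  Biostrings::writeXStringSet(dss, fasta_path)
  lin <- apply(as.matrix(refset[, tax_ranks()]), 1L, paste, collapse = ";")
  writeLines(paste(refset$record_id, lin, sep = "\t"), taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

#' Count distinct taxa in a reference set at one rank
#'
#' `"UNKNOWN"` placeholders are excluded from the count.
#'
#' @param refset A `reference_set`.
#' @param rank One of [tax_ranks()].
#' @return Integer count of distinct non-UNKNOWN names at that rank.
#' @export
#' @examples
#' rs <- reference_set("r1", "ACGT", "Ascomycota;;Saccharomycetes")
#' summarize_richness(rs, "phylum")
summarize_richness <- function(refset, rank) {
  stopifnot(inherits(refset, "reference_set"))
  if (!is.character(rank) || length(rank) != 1L || !(rank %in% tax_ranks()))
    .fail("unknown rank '%s' (must be one of: %s)",
          paste(rank, collapse = ","), paste(tax_ranks(), collapse = ", "))
  v <- refset[[rank]]
  length(unique(v[v != .UNKNOWN]))
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set '%s'> %d %s record(s)\n",
              attr(x, "name"), nrow(x), attr(x, "source_kind")))
  for (r in c("phylum", "class", "genus"))
    cat(sprintf("  distinct %-6s: %d\n", r, summarize_richness(x, r)))
  if (any(x$lineage_gap))
    cat(sprintf("  %d record(s) flagged: named rank below an UNKNOWN rank\n",
                sum(x$lineage_gap)))
  invisible(x)
}
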