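# In-code fixtures and the exhaustive-offset alignment oracle.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_at <- function(seq, n_mut) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 10 records spanning 2 phyla / 3 subphyla / 4 classes / 7 genera
# (hand-counted richness: phylum 2, subphylum 3, class 4, genus 7)
lineage_fixture <- function(seq_len_bp = 60) {
  lins <- c(
    r01 = "P1;S1;C1;O1;F1;G1;G1sp",
    r02 = "P1;S1;C1;O1;F1;G1;G1sp2",
    r03 = "P1;S1;C1;O1;F2;G2;G2sp",
    r04 = "P1;S1;C2;O2;F3;G3;G3sp",
    r05 = "P1;S1;C2;O2;F3;G3;G3sp2",
    r06 = "P2;S2;C3;O3;F4;G4;G4sp",
    r07 = "P2;S2;C3;O3;F5;G5;G5sp",
    r08 = "P2;S3;C4;O4;F6;G6;G6sp",
    r09 = "P2;S3;C4;O4;F6;G6;G6sp2",
    r10 = "P2;S3;C4;O4;F7;G7;G7sp")
  reference_set(names(lins), vapply(seq_along(lins),
                                    function(i) random_seq(seq_len_bp), ""),
                unname(lins), name = "lineage_fixture")
}

# two yeast genera sharing a class, one mould in a different class
yeast_fixture <- function(seq_len_bp = 80) {
  ids <- c("cand1", "cand2", "pich1", "clad1")
  lins <- c(
    "Ascomycota;Saccharomycotina;Saccharomycetes;Saccharomycetales;Debaryomycetaceae;Candida;Candida_sp",
    "Ascomycota;Saccharomycotina;Saccharomycetes;Saccharomycetales;Debaryomycetaceae;Candida;Candida_sp2",
    "Ascomycota;Saccharomycotina;Saccharomycetes;Saccharomycetales;Pichiaceae;Pichia;Pichia_sp",
    "Ascomycota;Pezizomycotina;Dothideomycetes;Capnodiales;Cladosporiaceae;Cladosporium;Cladosporium_sp")
  reference_set(ids, vapply(ids, function(i) random_seq(seq_len_bp), ""),
                lins, name = "yeast_fixture")
}

write_fasta_fixture <- function(ids, seqs, headers = ids) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# Exhaustive-offset brute force: Hamming mismatch counts at EVERY
# end-to-end placement (both strands), computed by Biostrings, independent
# of the package's seeded C++ path. Returns all placements with their
# mismatch counts; filter to a budget + minimal stratum with oracle_hitset().
oracle_mm <- function(read_seq, refset) {
  L <- nchar(read_seq)
  qs <- list(`+` = Biostrings::DNAString(read_seq),
             `-` = Biostrings::DNAString(revcomp(read_seq)))
  rows <- list()
  for (strand in names(qs)) {
    for (i in seq_len(nrow(refset))) {
      n_off <- nchar(refset$sequence[i]) - L + 1L
      if (n_off < 1L) next
      mm <- Biostrings::neditStartingAt(qs[[strand]],
                                        Biostrings::DNAString(refset$sequence[i]),
                                        starting.at = seq_len(n_off),
                                        with.indels = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = refset$record_id[i], strand = strand,
        offset = seq_len(n_off) - 1L, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_hitset <- function(mm_table, L, min_identity) {
  b <- mismatch_budget(L, min_identity)
  adm <- mm_table[mm_table$mismatches <= b, , drop = FALSE]
  if (!nrow(adm)) return(adm)
  adm <- adm[adm$mismatches == min(adm$mismatches), , drop = FALSE]
  adm[order(adm$ref_id, adm$strand, adm$offset), , drop = FALSE]
}

normalize_hits <- function(hits) {
  h <- data.frame(ref_id = as.character(hits$ref_id),
                  strand = as.character(hits$strand),
                  offset = as.integer(hits$offset),
                  mismatches = as.integer(hits$mismatches),
                  stringsAsFactors = FALSE)
  h <- h[order(h$ref_id, h$strand, h$offset), , drop = FALSE]
  rownames(h) <- NULL
  h
}
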