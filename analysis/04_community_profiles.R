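#!/usr/bin/env Rscript
# Stage 4: FC1 and FCT community profiles at 95% identity.
#
# FC1 (reads whose best-stratum hits all name one taxon) supports exact
# relative abundances; FCT (every taxon touched by any matched read) is a
# presence catalogue that deliberately carries no abundances. On this
# synthetic community with genus-specific markers, the FC1 genus profile
# should recover the configured composition.

library(mycomine)

stopifnot(file.exists("scratch/unmapped.fasta"))  # run 02 first

unmapped <- read_reads("scratch/unmapped.fasta", format = "fasta")
markers <- read_reference_set("scratch/sim/markers.fasta",
                              "scratch/sim/markers_taxonomy.tsv")
hits <- align_reads(unmapped, build_index(markers, 16), 0.95)

for (rank in c("phylum", "subphylum", "class", "genus")) {
  asn <- assign_reads(hits, markers, rank, read_ids = unmapped$read_id)
  for (mode in c("FC1", "FCT")) {
    prof <- build_profile(asn, mode, rank)
    write_profile(prof, sprintf("results/04_profile_%s_%s.tsv", mode, rank))
  }
}

asn <- assign_reads(hits, markers, "genus", read_ids = unmapped$read_id)
prof <- build_profile(asn, "FC1")
print(prof)
ra <- relative_abundance(prof)
message("FC1 genus relative abundances (configured: 0.88/0.05/0.04/0.03):")
print(round(ra, 3))
message("wrote results/04_profile_{FC1,FCT}_{rank}.tsv")
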