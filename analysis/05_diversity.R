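#!/usr/bin/env Rscript
# Stage 5: rarefaction of the FC1 community and cross-threshold
# comparison (Bray-Curtis + neighbour joining).
#
# The rarefaction curve shows how much of the genus richness the matched
# reads have saturated; the cluster tree summarizes how similar the
# communities recovered at the four identity thresholds are.

library(mycomine)

stopifnot(file.exists("scratch/unmapped.fasta"))  # run 02 first

unmapped <- read_reads("scratch/unmapped.fasta", format = "fasta")
markers <- read_reference_set("scratch/sim/markers.fasta",
                              "scratch/sim/markers_taxonomy.tsv")
idx <- build_index(markers, 16)

hits <- align_reads(unmapped, idx, 0.95)
asn <- assign_reads(hits, markers, "genus")
labels <- asn$taxon[asn$status == "FC1"]
rc <- rarefy(labels, replicates = 100L, seed = 20260923L)
write.table(as.data.frame(rc), "results/05_rarefaction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("rarefaction: %d FC1 reads, %d genera at full depth",
                length(labels), rc$mean_richness[nrow(rc)]))

sw <- threshold_sweep(unmapped, idx, markers, rank = "class")
counts <- lapply(sw$profiles, function(p) p$counts)
counts <- counts[vapply(counts, function(x) sum(x) > 0, TRUE)]
if (length(counts) >= 2) {
  D <- bray_curtis_matrix(counts)
  write.table(data.frame(label = rownames(D), D, check.names = FALSE),
              "results/05_bray_curtis.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(nj_tree(D), "results/05_community_tree.nwk")
  message("pairwise Bray-Curtis across thresholds:")
  print(round(D, 4))
}
message("wrote results/05_rarefaction.tsv, 05_bray_curtis.tsv, 05_community_tree.nwk")
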