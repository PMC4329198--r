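#!/usr/bin/env Rscript
# Stage 6: extrapolate the total fungal read content of the unmapped pool.
#
# A calibration subset (here the genomes of the first two genera, standing
# in for the fungi with both a sequenced genome and a marker in the
# reference set) yields the ratio r = genome hits / marker hits; applying
# r to the marker hits against the full marker set estimates the total
# fungal read count, which the truth table lets us check directly.

library(mycomine)

stopifnot(file.exists("scratch/unmapped.fasta"))  # run 02 first

unmapped <- read_reads("scratch/unmapped.fasta", format = "fasta")
markers <- read_reference_set("scratch/sim/markers.fasta",
                              "scratch/sim/markers_taxonomy.tsv")
genomes <- read_reference_set("scratch/sim/genomes.fasta",
                              "scratch/sim/genomes_taxonomy.tsv",
                              source_kind = "GENOME")
truth <- read.delim("scratch/sim/truth.tsv")
n_raw <- nrow(truth)

hits <- align_reads(unmapped, build_index(markers, 16), 0.95)
its_full <- length(matched_reads(hits))

subset_ids <- genomes$record_id[genomes$genus %in% c("Genus01", "Genus02")]
gsub <- genomes[genomes$record_id %in% subset_ids, , drop = FALSE]
class(gsub) <- c("reference_set", "data.frame")
attr(gsub, "name") <- "calibration_subset"
genome_sub <- length(matched_reads(
  align_reads(unmapped, build_index(gsub, 16), 0.95)))
its_sub <- length(matched_reads(
  hits[hits$ref_id %in% paste0("marker_", unique(gsub$genus)), ,
       drop = FALSE]))

est <- estimate_fraction(its_full, genome_sub, its_sub,
                         n_unmapped = nrow(unmapped), n_raw = n_raw)
print(est)

n_true <- sum(truth$origin == "FUNGAL")
message(sprintf("true fungal reads: %d; relative error %.1f%%",
                n_true, 100 * abs(est$total_estimate - n_true) / n_true))

out <- data.frame(its_hits_full = its_full, genome_hits_sub = genome_sub,
                  its_hits_sub = its_sub, ratio_r = est$ratio_r,
                  total_estimate = est$total_estimate,
                  pct_unmapped = est$pct_unmapped, pct_raw = est$pct_raw,
                  true_fungal_reads = n_true,
                  rel_error = abs(est$total_estimate - n_true) / n_true)
write.table(out, "results/06_fraction_estimate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/06_fraction_estimate.tsv")
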