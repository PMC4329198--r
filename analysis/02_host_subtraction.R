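#!/usr/bin/env Rscript
# Stage 2: remove reads matching the host genome at 100% identity.
#
# Only perfect end-to-end placements count as host: reads carrying even a
# single sequencing error survive subtraction, which is why the unmapped
# pool is larger than the true non-host fraction — exactly the behaviour
# of exact-match host exclusion on real data. The surviving pool is the
# input for all downstream fungal screening.

library(mycomine)

stopifnot(file.exists("scratch/sim/reads.fastq"))  # run 01_simulate.R first

reads <- read_reads("scratch/sim/reads.fastq")
host <- read_reference_set("scratch/sim/host.fasta", name = "host",
                           source_kind = "GENOME")
sub <- subtract_host(reads, build_index(host, k = 16))
print(sub)

truth <- read.delim("scratch/sim/truth.tsv")
n_host_err <- sum(truth$origin == "HOST" & truth$n_errors > 0)
message(sprintf(
  "unmapped pool = %d fungal + %d error-bearing host reads",
  sum(truth$origin == "FUNGAL"), n_host_err))

out <- data.frame(total = sub$counts["total"],
                  host_matched = sub$counts["host_matched"],
                  unmapped = sub$counts["unmapped"],
                  unmapped_fraction_pct =
                    100 * sub$counts["unmapped"] / sub$counts["total"],
                  true_fungal = sum(truth$origin == "FUNGAL"),
                  host_with_errors = n_host_err)
write.table(out, "results/02_host_subtraction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# persist the unmapped pool for the later stages
writeLines(paste0(">", sub$unmapped$read_id, "\n", sub$unmapped$sequence),
           "scratch/unmapped.fasta")
message("wrote results/02_host_subtraction.tsv, scratch/unmapped.fasta")
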