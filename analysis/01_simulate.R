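#!/usr/bin/env Rscript
# Build the synthetic study: a host genome (3 autosomes, U, V, organelles)
# at 45% GC plus 65% GC contaminants, and one male and one female 100 bp
# paired-end read set at 20x with contaminant admixture. Bulky sequence
# files go to scratch/, small summaries to results/.

suppressPackageStartupMessages(library(uvlinker))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 101)
ref <- simulate_reference(cfg)
write_reference(ref, "scratch/sim")
saveRDS(ref, "scratch/sim/reference.rds")  # scratch only, not a deliverable

male <- simulate_reads(ref, "male", depth = 20, seed = 102)
female <- simulate_reads(ref, "female", depth = 20, seed = 103)
write_fastq_pair(male, "scratch/sim/male")
write_fastq_pair(female, "scratch/sim/female")
saveRDS(male, "scratch/sim/male.rds")
saveRDS(female, "scratch/sim/female.rds")

seg_summary <- ref$segments
seg_summary$gc <- round(gc_content(ref$seqs), 4)
write.table(seg_summary, "results/01_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d segments, %d bp total\n", nrow(ref$segments),
            sum(ref$segments$length)))
cat(sprintf("reads: %d male pairs, %d female pairs (%.1f%% contaminant)\n",
            nrow(male), nrow(female),
            100 * mean(grepl("^contam", c(male$segment, female$segment)))))
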