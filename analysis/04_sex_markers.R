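#!/usr/bin/env Rscript
# Sex-marker candidate cascade: regions -> genes on the same scaffold ->
# best homology hit -> concordance with the homolog's sex-chromosome class.
# Homology against the related reference species is emulated from the truth
# labels (each simulated sex gene hits its own chromosome class).

suppressPackageStartupMessages(library(uvlinker))

ref <- readRDS("scratch/sim/reference.rds")
regions <- read.table("results/03_regions.tsv", sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)

genes <- data.frame(seqid = ref$genes$seqid, start = ref$genes$start,
                    end = ref$genes$end, gene_id = ref$genes$gene_id,
                    stringsAsFactors = FALSE)
class_to_subject <- c(male_specific = "RefV", male_allele = "RefV",
                      female_specific = "RefU", female_allele = "RefU",
                      autosomal = "RefAuto", mitochondrial = "RefMito",
                      chloroplast = "RefChloro")
besthits <- data.frame(qseqid = ref$genes$gene_id,
                       sseqid = unname(class_to_subject[ref$genes$gene_class]),
                       stringsAsFactors = FALSE)
classes <- c(RefV = "V", RefU = "U", RefAuto = "autosome",
             RefMito = "organelle", RefChloro = "organelle")

res <- cascade(regions, genes, besthits, classes,
               segments = ref$segments$id)
write.table(res$candidates, "results/04_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(res$stage_counts)

exp <- export_candidates(res$candidates, ref$seqs,
                         "results/04_markers.bed", "scratch/sim/markers.fa")
cat(sprintf("%d sex-concordant marker candidates exported (%d male, %d female)\n",
            nrow(exp), sum(exp$sex_prediction == "male"),
            sum(exp$sex_prediction == "female")))
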