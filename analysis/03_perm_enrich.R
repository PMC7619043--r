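#!/usr/bin/env Rscript
# Stage 3: matched-region permutation enrichment of the high-confidence
# OCRs within the chromatin-state maps.
#
# For each state, 1,000 random region sets matching the OCRs' chromosome
# distribution and size multiset are drawn; an OCR overlaps a state when
# more than half of its bases fall in state regions. Fold = observed /
# mean simulated count, with +1-corrected empirical p-values.

suppressMessages(library(ocrpipe))

seed <- as.integer(Sys.getenv("OCRPIPE_SEED", "1"))
synth <- file.path("results", "synth")

genome <- read_chrom_sizes(file.path(synth, "chrom.sizes"))
hc <- read_bed(file.path("results", "high_confidence.bed"), label = "hc")

state_files <- list.files(file.path(synth, "states"), full.names = TRUE)
states <- annotation_map(stats::setNames(
  lapply(state_files, read_bed),
  sub("\\.bed$", "", basename(state_files))))

enr <- permutation_enrichment(hc, states, n_sim = 1000, genome = genome,
                              seed = seed + 300)
enr <- enr[order(-enr$fold), ]
write.table(enr, file.path("results", "state_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Chromatin-state enrichment of high-confidence OCRs (1,000 sims):\n")
print(enr, row.names = FALSE, digits = 3)
cat("\nThe planted Promoter (10x) and Enhancer (5x) enrichments should",
    "lead the table;\nthe remaining states cover true peaks at the shared",
    "baseline rate, so their\nfolds cluster well below the planted pair.\n")
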