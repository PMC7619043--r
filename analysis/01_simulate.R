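#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the study design the pipeline expects: three biological
# replicates of bulk open-chromatin peak calls over a 3 x 2 Mb toy genome,
# a pooled call, NeuN+/NeuN- fraction calls, a blacklist, eight
# chromatin-state maps with planted Promoter/Enhancer enrichment, histone
# marks, gene models, a 5,000-SNP LD panel (50-SNP compound-symmetric
# blocks), GWAS summary statistics with a planted 5-fold heritability
# enrichment inside the (extended) true peaks, and an eQTL table with two
# planted fine-mapped loci. Ground truth is written alongside.

suppressMessages(library(ocrpipe))

seed <- as.integer(Sys.getenv("OCRPIPE_SEED", "1"))
out <- file.path("results", "synth")

study <- generate_study(synthetic_config(seed = seed), out_dir = out)

cat(sprintf("Synthetic study (seed %d) written to %s\n", seed, out))
cat(sprintf("  true peaks:        %d\n", nrow(study$true_peaks)))
cat(sprintf("  replicate peaks:   %s\n",
            paste(vapply(study$replicates, nrow, 0L), collapse = ", ")))
cat(sprintf("  pooled peaks:      %d\n", nrow(study$pooled)))
cat(sprintf("  SNP panel:         %d SNPs in %d LD blocks\n",
            nrow(study$panel$snps), length(unique(study$panel$snps$block))))
cat(sprintf("  OCR SNP fraction:  %.3f (planted fold %g)\n",
            study$truth$prop_snps_ocr, study$truth$target_fold))
cat(sprintf("  planted GWAS loci: %d\n", nrow(study$truth$planted)))
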