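#!/usr/bin/env Rscript
# Stage 5: LD-aware prioritization of GWAS SNPs inside OCRs.
#
# Keeps SNPs that sit inside a high-confidence OCR, reach genome-wide
# significance (p < 5e-8), and are in strong LD (r² > .8) with the index
# SNP of their (distance-clumped) locus; annotates them with histone
# membership, NeuN attribution, fetal-brain eQTL evidence (p < 5e-5) and
# r² with the top eQTL SNP of each implicated transcript.

suppressMessages(library(ocrpipe))

synth <- file.path("results", "synth")

hc <- read_bed(file.path("results", "high_confidence.bed"), label = "hc")
panel <- read_snp_panel(file.path(synth, "panel_dosages.tsv"))
assoc <- read.delim(file.path(synth, "gwas_assoc.tsv"))
recs <- snp_records(assoc$snp_id, assoc$chrom, assoc$pos, assoc$gwas_p,
                    assoc$trait)
eqtl <- read.delim(file.path(synth, "eqtl.tsv"))
att <- read.delim(file.path("results", "attribution.tsv"))
h3k4me1 <- read_bed(file.path(synth, "h3k4me1.bed"))
h3k4me3 <- read_bed(file.path(synth, "h3k4me3.bed"))

pri <- prioritize_snps(recs, hc, panel, h3k4me1 = h3k4me1,
                       h3k4me3 = h3k4me3, attribution = att, eqtl = eqtl)
write.table(pri, file.path("results", "prioritized_snps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Prioritized %d SNP(s):\n", nrow(pri)))
print(pri[, c("snp_id", "locus_id", "index_snp", "gwas_p", "r2_index",
              "eqtl_transcript", "r2_top_eqtl")],
      row.names = FALSE)

truth <- yaml::read_yaml(file.path(synth, "truth.yaml"))
planted <- vapply(truth$planted, function(x) x$causal_snp, "")
cat(sprintf("\nPlanted causal OCR SNPs recovered: %d / %d\n",
            sum(planted %in% pri$snp_id), length(planted)))
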