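#!/usr/bin/env Rscript
# Stage 2: high-confidence OCR consensus and NeuN fraction attribution.
#
# Pooled peaks are kept (in their pooled coordinates) when they avoid the
# blacklist and overlap a union interval supported by peaks from at least
# two of the three biological replicates; the surviving OCRs are labelled
# by >= 1 bp overlap with the NeuN+ / NeuN- fraction calls, and subset by
# histone marks.

suppressMessages(library(ocrpipe))

synth <- file.path("results", "synth")
out <- "results"

reps <- lapply(sprintf("%s/rep%d.bed", synth, 1:3), read_bed)
pooled <- read_bed(file.path(synth, "pooled.bed"), label = "pooled")
blacklist <- read_bed(file.path(synth, "blacklist.bed"))

hc <- high_confidence(pooled, reps, blacklist = blacklist, min_count = 2)
write_bed(hc, file.path(out, "high_confidence.bed"))

truth <- read_bed(file.path(synth, "true_peaks.bed"))
ov <- count_overlapping(merge_peaks(truth), merge_peaks(hc))
cat(sprintf("High-confidence OCRs: %d of %d pooled peaks\n",
            nrow(hc), nrow(pooled)))
cat(sprintf("  true peaks recovered: %d / %d (%.1f%%)\n",
            ov$n_a_hit, nrow(truth), 100 * ov$n_a_hit / nrow(truth)))
cat(sprintf("  OCRs without true-peak support: %d (%.1f%%)\n",
            nrow(hc) - ov$n_b_hit, 100 * (nrow(hc) - ov$n_b_hit) / nrow(hc)))

att <- attribute_fractions(hc, read_bed(file.path(synth, "neun_pos.bed")),
                           read_bed(file.path(synth, "neun_neg.bed")))
write.table(att$table, file.path(out, "attribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("NeuN attribution: ",
    paste(sprintf("%s=%d", names(att$counts), att$counts),
          collapse = ", "), "\n")

for (mark in c("h3k4me1", "h3k4me3")) {
  sub <- histone_subset(hc, read_bed(file.path(synth, paste0(mark, ".bed")),
                                     label = mark))
  write_bed(sub, file.path(out, paste0("ocr_", mark, ".bed")))
  cat(sprintf("OCR + %s regions: %d\n", mark, nrow(sub)))
}
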