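# ocrpipe

Regulatory-genomics analyses built around ATAC-Seq open chromatin regions
(OCRs), packaged as testable R functions plus a small analysis workflow.
The pipeline covers four stages that are usually stitched together from
ad-hoc scripts when relating maps of open chromatin (for example from
fetal brain tissue) to GWAS of neuropsychiatric disorders:

1. **Consensus peak calling** — pooled peak calls are reduced to
   high-confidence OCRs by requiring support from at least two of three
   biological replicates (DiffBind-style occupancy on union intervals),
   after ENCODE-blacklist exclusion; OCRs are then attributed to NeuN+
   (neuron-enriched) and/or NeuN− (neuron-depleted) nuclei fractions and
   subset by H3K4me1/H3K4me3 histone marks.
2. **Matched-region permutation enrichment** — for each chromatin state
   in an annotation map, the number of OCRs whose bases are >50% covered
   by the state is compared against `n_sim` random region sets matching
   the OCRs' chromosome distribution and size multiset. The fold
   enrichment is `observed / mean(simulated)`; one-sided empirical
   p-values use the +1 correction `(#{sim ≥ obs} + 1)/(n_sim + 1)`, and
   the two-sided p is `p_over + (1 − p_under)` when fold > 1 (mirrored
   when fold < 1).
3. **Partitioned SNP heritability** — a simplified stratified LD-score
   regression: `E[χ²_j] = N Σ_c τ_c ℓ(j,c) + 1` with stratified LD scores
   `ℓ(j,c) = Σ_k r²(j,k) 1[k ∈ c]`, weighted least squares, and a
   delete-one block jackknife for standard errors. Annotations are peaks
   extended by ±500 bp; enrichment is reported as
   `fold = prop_h2 / prop_snps`, with a Bonferroni display threshold
   (α = .05 over 7 traits → p < .0071).
4. **SNP prioritization** — GWAS SNPs are kept when they lie inside a
   high-confidence OCR, reach genome-wide significance (p < 5×10⁻⁸), and
   are in strong LD (r² > .8) with the index SNP of their distance-clumped
   locus; survivors are annotated with histone membership, NeuN
   attribution, fetal-brain eQTL evidence (p < 5×10⁻⁵) and r² with the
   top eQTL SNP of each implicated transcript.

Real inputs at every stage are plain-text standards (BED3/BED5,
chrom.sizes, TSV tables). Because the raw sequencing data behind such
studies cannot ship with a package, `ocrpipe` includes a first-class
synthetic-data generator (`generate_study()`) that emits every input with
known ground truth — planted peaks, planted state enrichment, planted
heritability architecture, planted fine-mapped loci — so each stage's
statistical behaviour is verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic study (seed taken from `OCRPIPE_SEED`, default 1), writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus.R
Rscript analysis/03_perm_enrich.R
Rscript analysis/04_h2_enrich.R
Rscript analysis/05_prioritize.R
```

At seed 1 the consensus stage prints:

```
High-confidence OCRs: 290 of 333 pooled peaks
  true peaks recovered: 289 / 300 (96.3%)
  OCRs without true-peak support: 1 (0.3%)
NeuN attribution:  both=203, neun_pos_only=43, neun_neg_only=44, neither=0
```

i.e. the two-of-three rule recovers 96% of planted peaks while admitting
a single false one. The permutation stage ranks the two planted states
first, far above the six states that only cover true peaks at the shared
baseline rate:

```
           state observed mean_sim  fold   p_over
        Promoter      144    10.04 14.34 0.000999
        Enhancer       87     8.53 10.21 0.000999
   RegPermissive       24     6.74  3.56 0.000999
...
```

The heritability stage estimates the planted enrichment from one
simulated GWAS (`7.6% of SNPs carry 53.7% of SNP heritability: 7.1-fold
enrichment`, planted truth 5-fold, jackknife SE ≈ 3 — the vignette
discusses why a single 5,000-SNP GWAS is noisy), and the prioritization
stage recovers both planted causal OCR SNPs with `r2_index = 1` and both
planted transcripts each.

`run_pipeline(pipeline_config(...))` performs the same stages
programmatically from a set of input paths and writes a JSON run report.

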