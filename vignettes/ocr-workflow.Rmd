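---
title: "Open chromatin consensus, enrichment and SNP prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open chromatin consensus, enrichment and SNP prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrpipe)
```

This vignette documents the models, conventions and design choices behind
`ocrpipe`, in the spirit of the methods sections of mature omics
packages: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and where the numerically
delicate corners are.

## Coordinates and interval arithmetic

All intervals are BED-convention **0-based half-open** `[start, end)`.
GWAS and eQTL tables carry 1-based SNP positions; these are converted at
ingestion (`pos − 1 → start`, `pos → end`), so a SNP at 1-based position
`p` is "inside" a peak exactly when `start ≤ p − 1 < end`. One
consequence worth spelling out: a peak `[1500, 2000)` extended by 500 bp
becomes `[1000, 2500)` and covers 1-based positions 1001–2500 — position
1000 sits one base short of it.

Merging joins intervals separated by at most `gap` bp; at `gap = 0`
bookended intervals (`[a,b)` + `[b,c)`) join, matching `bedtools merge`.
"Overlap" means ≥ 1 bp everywhere except the permutation test's >50%
rule (below). Strand is ignored for all peak operations — ATAC peaks are
unstranded — and honoured only when building per-gene TSS windows
(`[tss − upstream, tss + downstream)` in the direction of transcription;
defaults 30 kb upstream, 100 bp downstream). For the promoter / gene-body
/ distal classification the package uses any-overlap with a ±5 kb TSS
window rather than a peak-midpoint rule; midpoint assignment differs only
for peaks straddling a window edge and any-overlap composes cleanly with
the rest of the interval algebra.

Set operations run per chromosome on `IRanges`; the test suite checks
them against an independent per-base boolean-mask oracle on thousands of
random instances.

## Consensus peak calling

`high_confidence(pooled, replicates, blacklist, min_count = 2)` encodes
the standard replicate-reconciliation recipe:

1. drop any pooled peak touching the blacklist (≥ 1 bp);
2. merge the union of all replicate peaks into disjoint intervals and
   keep those overlapped by peaks from ≥ `min_count` distinct replicates
   (occupancy on union intervals, the consensus convention of DiffBind);
3. keep pooled peaks overlapping a surviving union interval by ≥ 1 bp,
   **in their original pooled coordinates** — the pooled call, made on
   the merged depth-matched alignment, is the coordinate authority; the
   replicates only vouch for reproducibility.

The minimum overlap for "observed in a replicate" is exposed as a
parameter and defaults to 1 bp; peak callers rarely produce sub-peak
slivers at FDR < 0.01, so the result is insensitive to this choice on
realistic inputs. Fraction attribution (`attribute_fractions()`) labels
each OCR `both` / `neun_pos_only` / `neun_neg_only` / `neither` by ≥ 1 bp
overlap with the NeuN+ and NeuN− peak sets; the four labels partition the
OCR set by construction. Technical-replicate merging happens upstream at
the alignment level in real studies and is deliberately out of scope
here: the module takes one peak set per biological replicate plus one
pooled set.

## Matched-region permutation enrichment

For a target set of `n` peaks and a chromatin state `S` (merged), the
observed statistic is the number of peaks whose bases inside `S` strictly
exceed half the peak length. Two conventions needed fixing:

* **Summed coverage.** A peak split across two nearby same-state regions
  counts if the summed intersection exceeds half its length. The
  alternative — requiring a single region to provide the majority — is
  available as `per_region = "max"`.
* **Strict inequality.** Exactly 50% coverage does not count.

Null sets are drawn by placing, per chromosome, the same number of
intervals with the same length multiset uniformly over valid start
positions (`simulate_matched_set()`). Simulated intervals are placed
independently (self-overlap allowed) and are not blacklist- or
gap-excluded; placements are uniform over the full chromosome. With
`n_sim` draws,

$$p_{\mathrm{over}} = \frac{\#\{t_{\mathrm{sim}} \ge t_{\mathrm{obs}}\} + 1}{n_{\mathrm{sim}} + 1},
\qquad
p_{\mathrm{under}} = \frac{\#\{t_{\mathrm{sim}} \le t_{\mathrm{obs}}\} + 1}{n_{\mathrm{sim}} + 1},$$

ties counting as extreme on both sides (the conservative convention for
empirical p-values). The two-sided p is `p_over + (1 − p_under)` when
fold > 1, `p_under + (1 − p_over)` when fold < 1, capped at 1, and
defined as 1 when fold is exactly 1 or undefined. Fold is
`observed / mean(sim)`; a degenerate state with mean 0 yields `NA`
(observed 0) or `Inf` (observed > 0) rather than an error, so sparse
states on toy genomes cannot abort a run.

For the sum rule the simulation loop counts coverage with prefix sums
over the merged state intervals (`findInterval` on interval starts), an
exact O(log n) per query replacement for per-pair overlap joins; a
5,000-simulation, 8-state run on a 10⁴-peak target takes under a minute
on one CPU. The `"max"` rule falls back to explicit overlap joins.

**Calibration and discreteness.** Because the statistic is an integer
count, empirical p-values are slightly super-uniform under the null: the
`+1` correction and the inclusion of ties both push mass upward, in
proportion to `P(t_sim = t_obs)`. The calibration suite therefore uses a
target large enough (3,000 peaks against a state covering roughly half
the genome) that the count's standard deviation is ~25 and tie mass is
small; with 200 independent runs at `n_sim = 99` the p-values pass a
Kolmogorov–Smirnov uniformity check and mean fold sits within a few per
mil of 1. With small targets (tens to hundreds of peaks) the same
p-values are visibly conservative — a property of +1-corrected discrete
empirical p-values generally, not of this implementation.

## Partitioned heritability

The estimator is a deliberately simplified stratified LD-score
regression, built to be exercised end to end on synthetic data rather
than to reproduce the published software numerically:

$$E[\chi^2_j] = N \sum_c \tau_c\, \ell(j,c) + 1, \qquad
\ell(j,c) = \sum_{k \in \mathrm{block}(j)} r^2(j,k)\, A_{kc},$$

with block-diagonal LD (reference r from per-block correlation matrices,
or squared Pearson correlations of dosages when only genotypes are
given), regression weights `1 / max(ℓ_base(j), 1)`, no MAF-stratified
reference weights and no weight iteration. The intercept is fixed at 1
(no confounding term) by default; `free_intercept = TRUE` estimates it.
Standard errors and the coefficient covariance come from a delete-one
block jackknife over contiguous SNP blocks (default 20 — enough blocks
that the coefficient Z-statistic is effectively normal while each block
still holds hundreds of SNPs at the 5,000-SNP scale).

Annotations are binary SNP memberships; column 1 is always the all-SNPs
base category. Peaks are extended by ±500 bp before SNP annotation
(`annotate_snps()`), the standard buffer for regulatory annotations in
this kind of regression. Enrichment is summarised per category as

$$\mathrm{fold} = \frac{\mathrm{prop}_{h^2}}{\mathrm{prop}_{\mathrm{SNPs}}},
\qquad
\mathrm{prop}_{h^2} = \frac{\sum_{j \in a} \sum_c \tau_c A_{jc}}{\sum_j \sum_c \tau_c A_{jc}},$$

with `prop_h2` clipped at 0 inside the fold (a noisy fit can drive it
slightly negative), the fold's SE from the same jackknife, and
significance reported as the coefficient Z-test against zero — the
conservative choice when both a fold p and a coefficient p are
available. The exact enrichment-p computation of the published SLDSR
software is not reproduced. Over a disjoint partition of SNPs the
`prop_h2` values sum to 1 by construction (tested). `bonferroni_threshold(0.05, 7)`
returns the display-rounded `.0071`.

**Precision at desk scale.** With 5,000 SNPs in 100 LD blocks, a single
simulated GWAS estimates a planted 5-fold enrichment with a standard
error near 3: the dominant noise is the finite number of causal-effect
draws, which no GWAS sample size can average away. The estimator is
unbiased for τ (checked directly), and the mean fold across 100
simulated GWAS lands within 10% of the planted truth; single-run fold
estimates should be read with their jackknife SE, exactly as in the
analysis script's output.

## SNP prioritization

Real GWAS publish loci; from summary statistics alone the package
reconstructs them by greedy distance clumping: repeatedly take the
smallest-p unassigned genome-wide-significant SNP as an index (ties by
leftmost position) and absorb unassigned significant SNPs within
±500 kb on the same chromosome. This is a documented deviation from
inheriting each GWAS's own locus definitions, which are not an input.
The r² filter is applied per locus against that locus's index; r² comes
from squared Pearson correlation of panel dosages (the panel choice
stands in for a reference-population choice). All three cutoffs are
strict inequalities — `p < 5e-8`, `r² > .8`, eQTL `p < 5e-5` — and
boundary values are excluded (tested). "Within an OCR" uses the
unextended OCR interval; the ±500 bp extension is a heritability-stage
convention only. SNPs absent from the LD panel cannot be scored and are
excluded with a message. For eQTL annotation, the best (minimum-p) eQTL
rows per SNP below threshold are reported with all implicated
transcripts, plus r² between the SNP and each transcript's top eQTL SNP
(computed over the full eQTL table, not just sub-threshold rows); no
reporting cutoff is applied to those r² values.

## The synthetic study generator

`generate_study(synthetic_config())` emulates the study design the
pipeline assumes, at desk scale:

* **Genome**: 3 × 2 Mb chromosomes. Real genomes are three orders of
  magnitude larger; nothing in the set logic depends on scale.
* **True peaks**: 300, lognormal lengths (median 400 bp, clipped to
  150–3,000 bp), placed on disjoint slots so truth recovery is
  unambiguous; a 5-region blacklist is placed first and excluded.
* **Replicates**: 3 biological replicates detect each true peak with
  probability 0.95 (the pooled call: 0.98), with uniform ±50 bp boundary
  jitter per side, plus 60 (pooled: 40) uniformly placed noise peaks.
  These rates mimic the reproducibility of FDR < 0.01 peak calls across
  good-quality replicates and make the two-of-three rule recover ≈97% of
  truth while admitting ≤1% false peaks.
* **NeuN fractions**: overlapping subsets of the bulk truth — 70% shared,
  15% private to each fraction — echoing the large shared fraction seen
  between sorted-nuclei maps.
* **Chromatin states**: eight states; each covers a true peak (fully,
  with margin) with probability 0.05, multiplied by 10 for Promoter and
  5 for Enhancer, on top of uniformly placed background regions. The
  planted multipliers are what the permutation stage should rank first.
* **LD panel**: 5,000 SNPs in 50-SNP compound-symmetric blocks
  (ρ = 0.6), dosages for 200 individuals via a Gaussian copula with
  MAF ~ U(0.1, 0.5); the true block correlation matrices travel with the
  panel so the heritability stage can be run well-specified.
* **GWAS**: per block, `β ~ N(0, Σ_c τ_c A_c)` and
  `z = √N · R β + ε, ε ~ MVN(0, R)`, N = 10,000. τ is solved by
  `tau_for_fold()` so the extended-peak annotation holds exactly a
  5-fold enrichment of a total h² of 0.5 given the realized SNP
  fraction; three 10% null covariate categories exercise the conditional
  Z-test.
* **Planted fine-mapping**: two loci on distinct chromosomes (both
  planted indexes carry the same p, so same-chromosome loci could merge
  under clumping and the absorbed causal SNP would fail the LD filter —
  distinct chromosomes remove the collision by construction). Each locus
  has an index SNP (p = 10⁻¹²), a causal SNP inside a true peak
  (p = 10⁻⁹) whose genotypes copy the index (r² = 1), eQTL records for
  two transcripts, and a mirrored-genotype top eQTL for the second
  transcript. Peaks hosting causal SNPs are detected in every replicate
  so the planted structure survives consensus calling.

A single master seed fans out deterministically to per-stage seeds
(`stage_seed()`), so the full bundle — including every file written by
`write_study()` — is byte-reproducible, and stages can be regenerated
independently.

**What the generator does not emulate**: read-level data (no FASTQ/BAM),
realistic human LD (no long-range structure, no MAF–LD coupling),
MAF-stratified genetic architectures, GC or mappability biases in peak
placement, and population stratification (no confounding intercept).
Passing tests therefore demonstrate the correctness and calibration of
the set logic and estimators under their stated models — not robustness
to the mis-specifications real data add. The simplified heritability
estimator in particular shares its model with the generator; on real
GWAS one would use the published SLDSR software with its full baseline
and reference panels.

## Numerical and testing choices

* Empirical p-values never reach 0 (`≥ 1/(n_sim+1)`) and two-sided
  p-values are capped at 1, which the additive two-sided rule can
  otherwise exceed by construction.
* The WLS normal equations are solved by QR; rank deficiency raises an
  error naming the collinear categories rather than silently dropping
  one.
* Jackknife pseudo-values are used for both τ and fold SEs; fold SEs
  inherit the clipping at 0.
* Problem sizes in the test suite — 1,000 random interval instances,
  200-run calibration at `n_sim = 99`, 100 simulated GWAS at 5,000
  SNPs — were chosen so the whole suite exercises every statistical
  contract in a few minutes on one CPU while keeping Monte-Carlo
  acceptance margins (10% on the mean fold, KS p > .01) well clear of
  their thresholds.
* Where an operation has two routes (package implementation vs per-base
  oracle, WLS vs `lm`, analytic vs simulated), tests always compare the
  two rather than re-asserting constants.
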