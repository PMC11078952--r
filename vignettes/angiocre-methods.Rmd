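---
title: "Methods: angiogenic cis-regulatory elements and cis-regulatory SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: angiogenic cis-regulatory elements and cis-regulatory SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, why the defaults are what they are, what the synthetic-data
generator does and does not capture, and the numerical choices that matter
for reproducing results.

## Coordinate model

All intervals are 0-based, half-open (`[start, end)`), the BED convention.
Two consequences are load-bearing:

- *Adjacency merges but does not overlap.* `[0, 10)` and `[10, 20)` merge
  into `[0, 20)` under `merge_intervals()` (their union is contiguous), but
  `overlaps_any()` is false for them — overlap requires at least one shared
  base. `min_gap = g` additionally bridges gaps of up to `g` bases.
- *SNP positions are 1-based*, as in VCF. A SNP at `pos` occupies 0-based
  base `pos - 1`, so a SNP is inside an element when
  `start <= pos - 1 < end`. `snps_in_elements()` and the candidate
  intersection both use this rule.

Merging and overlap testing delegate to `GenomicRanges::reduce()` and
`countOverlaps()` behind the tibble API; `reduce(min.gapwidth = min_gap + 1)`
reproduces the gap-bridging semantics exactly. Nearest-TSS distances are
signed (`midpoint - tss_pos`) and tie-break to the lexicographically smaller
gene id so results are order-independent.

## Element bank

Open-chromatin regions (OCRs) are the merged union of the two late-stage
DNase peak sets (H-4, H-12) — the stages at which stimulation-induced
elements are open. An OCR enters the element bank only if it overlaps an
H3K27ac peak (enhancer) or an H3K4me3 peak (promoter) in *any* late-stage
sample (marks are OR-combined across samples); OCRs with both marks are
bifunctional, and unmarked OCRs are excluded but counted
(`attr(bank, "n_unmarked")`). This yields the set identity
`n_elements = n_enhancer + n_promoter - n_bifunctional`, which `glance()`
reports and the tests assert.

Genomic categories are assigned exhaustively and exclusively with the fixed
priority promoter > UTR > exon > intron > intergenic (promoter means
overlapping a window of 3 kb around a TSS, strand-aware). TSS proximity uses
5 kb; a gene desert is > 500 kb from every gene. Region enrichment follows
the GREAT binomial model: each gene gets a basal domain (−5 kb/+1 kb around
the TSS, strand-aware) extended up to 1 Mb but clipped at the neighbouring
basal domains; enrichment of elements in a domain set is the binomial upper
tail with hit probability equal to the fraction of the genome covered.

## Transcriptome

Differential expression is a transparent negative-binomial Wald test rather
than a wrapped heavyweight estimator: median-of-ratios size factors,
a method-of-moments common dispersion pooled across within-stage replicate
scatter and floored at 0.01 (with two replicates a per-gene estimate is far
too noisy; the floor guards the near-Poisson regime), a Wald statistic on the
log fold change of normalised stage means, and Benjamini–Hochberg adjustment.
A gene is differentially expressed at |log2FC| ≥ 0.58 (1.5-fold) and
padj ≤ 0.01 — the conventional thresholds for this design. The per-gene
moment estimates are averaged rather than medianed because the sample
variance with n = 2 is strongly right-skewed and the median underestimates
dispersion.

Temporal profiles for clustering are stage means of
`log2(normalised count + 1)` using **median-of-ratios size factors, not
CPM**. This matters: with several hundred genuinely changing genes, total
library composition differs between stages, so per-million scaling shifts
*every* gene's profile by a per-stage offset and visibly bends the planted
monotone shapes; the median ratio tracks the non-changing majority and is
robust to asymmetric DE. Profiles are then row-wise z-scored
(`standardize_profiles()`), dropping zero-variance genes with a warning.

Clustering is classic fuzzy c-means (Bezdek updates) with c = 4 (the four
temporal patterns supported by a four-point time course: two monotone-down,
two monotone-up with convex/concave curvature) and fuzzifier m = 1.25 —
standardised four-point profiles are short vectors, and larger m (e.g. the
common 2) washes memberships toward uniform. The objective is non-convex and
a single random start can merge two same-direction clusters, so
`fuzzy_cmeans()` runs `n_init = 8` restarts on seeds derived deterministically
from `seed` and keeps the lowest-final-objective fit without empty clusters;
the final objective separates the good optimum from the merged one by a wide
margin on the reference design. If every restart leaves an empty cluster, one
extra re-seed is tried and then a warning is raised rather than silently
reporting a degenerate partition.

## Exome-wide association

QC order matters and is fixed: individuals with genotyping rate < 0.95 are
removed first; variants are then excluded (first matching reason reported) if
on a sex chromosome, call rate < 0.95, control MAF < 0.05, or control HWE
exact p < 1e-5. HWE uses the exact conditional test on the heterozygote
count given the allele counts, computed by the standard two-term recurrence
(numerically stable; no factorials of large numbers), with the plain
two-sided p (total probability of outcomes no more likely than observed).
The test is conservative by construction, which the type-I simulation in the
test suite confirms against the fully enumerated size.

Association is per-SNP additive logistic regression (no covariates — the
generator plants no confounding; stratification PCA is provided for
inspection) via IRLS with a tight convergence tolerance (`epsilon = 1e-12`),
so the estimates agree with a direct likelihood optimiser to well below 1e-6.
Monomorphic variants and separated/non-converged fits are reported with
`converged = FALSE` and p = 1 rather than a fabricated estimate.

LD r² comes from the standard EM over the double-heterozygote phase
ambiguity: only the (1,1) genotype cell is ambiguous, and the phase
{AB/ab} contributes exactly one AB haplotype per individual with posterior
weight `p11*p00 / (p11*p00 + p10*p01)`. Allele frequencies are observed
exactly from genotypes, so the EM fixed point is the maximum-likelihood
haplotype solution. Variants with fewer than 5 overlapping non-missing
individuals, or monomorphic in the overlap, return `NA`.

Clumping is greedy: the smallest-p exome-wide SNP (p < 1e-5) becomes a lead,
everything exome-wide at r² ≥ 0.6 with it is clumped away, and so on (p ties
break by snp_id). Expansion then collects all QC-passing SNPs within 1 Mb of
a lead at r² > 0.2; the associated set is leads plus expanded proxies.
Cross-chromosome r² is treated as 0 — LD is physical linkage.

## Motifs

JASPAR position frequency matrices are converted to log-odds with a total
pseudocount of 1 spread by the background:
`log2(((count + pc * bg) / (colsum + pc)) / bg)`. With the default uniform
background a single-base column of 100 counts scores
`log2((100.25 / 101) / 0.25) ≈ 1.9894` — the formula value is the contract
(see the tests), not any rounded presentation of it.

Scanning is exhaustive over both strands with offset-major tie-breaking:
among equal scores (within 1e-9, guarding against summation-order rounding),
the smallest forward offset wins, plus strand before minus at the same
offset. Element-level enrichment is a hypergeometric upper tail of hit
counts at a threshold of 80% of the consensus score, significant at
p < 1e-20. Allele-specific disruption builds ref and alt windows of L−1
flanking bases around the SNP (clipped at element edges and flagged `edge`),
considers only hits whose footprint covers the SNP, and calls `loss`/`gain`
when exactly one allele reaches the threshold. Both windows carry the
*stated* alleles, so swapping ref and alt flips the call exactly (delta
negates, loss ↔ gain); a mismatch between the stated ref and the genome base
warns but proceeds.

## Synthetic generator: realism and limits

Every stage's input is simulated with planted truth, and the defaults *are*
the reference study conditions (cohort of 78 cases / 100 controls, the
element-class counts, the four-stage design). Design choices:

- Seed streams are derived per generator (`seed + 101` genome, `+202` peaks,
  `+303` counts, `+404` DE fixture, `+505` genotypes, `+606` random DNA) and
  scoped with `local_seed()`, which restores the caller's RNG state — calling
  a generator never perturbs user randomness, and all derived seeds stay far
  below 2^31.
- Counts are NB around template means with a common dispersion (0.05);
  `nb_dispersion = 0` gives exactly rounded means, which the tests use to
  check shape preservation deterministically.
- Genotypes draw two block haplotypes per individual from a small founder
  pool, which induces realistic within-block LD and near-zero between-block
  LD; the causal block tilts haplotype draws by `OR^g`. Planted QC violators
  (two per filter) are appended with their reasons recorded in
  `truth$qc_plan`.
- Limits: no trans effects, no covariate confounding or population
  structure in the default cohort, a single planted motif/TF, uniform base
  composition outside the planted site, and no read-level noise (peaks are
  intervals, not pileups). These are deliberate: each omitted nuisance has a
  dedicated, separately testable surface elsewhere in the package.

## Numerical notes

- All p-value machinery (BH, hypergeometric, binomial) uses `stats`
  primitives; the HWE recurrence and the EM are the only hand-rolled
  iterative algorithms, and both are tested against independent oracles
  (full enumeration; direct likelihood optimisation).
- Determinism: `run_pipeline()` with the same `sim_config(seed)` writes a
  byte-identical `summary.json`; the fuzzy c-means restarts are seeded from
  the single `seed` argument.
- Wald p-values for near-separated logistic fits blow up before separation
  is detected; fits with |beta| > 15 are declared non-converged rather than
  reported.

## Limitations

The differential-expression test is a simplified Wald test: no shrinkage of
dispersions or fold changes, so it is anti-conservative at very low counts
relative to shrinkage estimators (the floor mitigates but does not remove
this). The association model fits no covariates; with real stratified
cohorts the genotype PCA coordinates should be added to the model, which
this implementation does not automate. Motif enrichment uses a fixed
threshold rather than score-distribution calibration per PWM. None of these
affect the planted-truth recovery properties asserted by the test suite, but
all would matter on real data.
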