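---
title: "Discovering prognostic ceRNA modules from bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering prognostic ceRNA modules from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernakit)
```

## The analysis in one paragraph

Competing endogenous RNAs (ceRNAs) are transcripts that share microRNA
response elements and therefore compete for a common pool of miRNAs: when a
long non-coding RNA sponges a miRNA, the miRNA's mRNA targets are
derepressed. The operational signature of a lncRNA--mRNA ceRNA pair is
therefore (i) both transcripts are dysregulated in tumors, (ii) they are
strongly *positively* co-expressed, and (iii) they share significantly more
targeting miRNAs than chance would allow. `cernakit` turns that signature
into a tested pipeline: stage-wise negative-binomial differential
expression against normal tissue, four-way intersection of the calls,
co-expression screening, a hypergeometric shared-miRNA test with FDR
control, tripartite network assembly, and prognostic evaluation of each
module with a Cox risk-score classifier. A synthetic cohort generator with
planted ceRNA triplets provides ground truth, so every stage's operating
characteristics (type-I error, sensitivity, false-discovery proportion,
survival power) are measured rather than assumed.

## Differential expression

Counts are normalized with median-of-ratios size factors computed over
genes with no zero count; the factors are rescaled to geometric mean 1.
The zero-free convention keeps the reference hand-computable and fails
loudly (rather than silently switching to a pseudo-count reference) when
no gene qualifies.

Genes are first screened for abundance: a gene is testable when its FPKM
exceeds a class-specific threshold (1 for mRNA and miRNA, 0.1 for lncRNA —
lncRNAs are systematically lower-expressed) in at least 10% of samples.
Filtering precedes testing so that the Benjamini--Hochberg correction only
counts genes that could have been called.

The test itself is a per-gene Wald test on normalized counts: the fold
change is `log2((mean_tumor + 0.5)/(mean_normal + 0.5))` (the pseudo-count
keeps it finite for one-sided zeros), and its standard error comes from
the delta method under a negative-binomial variance with a per-gene
method-of-moments dispersion, pooled across the two groups and floored at
`1e-8`. We deliberately do not reproduce the full DESeq2 machinery
(dispersion shrinkage, Cook's distance filtering, fold-change shrinkage):
the downstream ceRNA logic consumes significance calls and signs, not
shrunken effect sizes, and a transparent test whose null behavior we can
verify by simulation is easier to reason about. The test's type-I error is
checked on a 2,000-gene null cohort (20 vs 20 samples, dispersion 0.1) and
sits near the nominal 5%.

A *common* DEG must pass `|log2FC| >= 1` and `FDR < 0.01` in all four
stage-vs-normal comparisons **with the same sign**. The direction
requirement is our reading of what a per-direction Venn intersection does
implicitly; a gene that flips sign between stages is not a coherent
tumor marker.

## ceRNA module scoring

Candidate pairs are every (common-DEG lncRNA, common-DEG mRNA)
combination. Co-expression is Pearson correlation on
`log2(normalized + 1)` values over *all* samples (tumor and normal): the
tumor-vs-normal shift is part of the biological covariation the ceRNA
hypothesis predicts, and using all samples matches how the thresholds were
originally applied. The two-sided p-value uses the t transform with n − 2
degrees of freedom. Retention is strict and signed: `r > 0.8` and
`p < 0.05`; a strongly anti-correlated pair is *not* a ceRNA candidate.

For each retained pair the shared-miRNA enrichment is the hypergeometric
upper tail

$$P = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

where $N$ is the miRNA universe, $K$ and $n$ the numbers of miRNAs
targeting the mRNA and the lncRNA, and $c$ the overlap. Terms are
accumulated in log-gamma space (`lchoose`) so large universes cannot
overflow; the implementation is checked against exhaustive pmf enumeration
for every configuration with $N \le 15$. The universe is defined as the
differentially expressed miRNAs that appear in at least one interaction
after the table is restricted to DE genes. This choice makes $N$
self-consistent and reproducible from the inputs alone; defining $N$ from
an external annotation would make every P-value depend on a database
version the analysis never sees. BH correction runs across all tested
pairs and modules with `FDR < 0.05` (and at least `min_shared` shared
miRNAs, default 1) are kept. No constraint is placed on the miRNAs'
direction of change: observed ceRNA modules can contain both up- and
down-regulated miRNAs.

Each kept module contributes a lncRNA--miRNA and a miRNA--mRNA edge per
shared miRNA; edges are deduplicated across modules, node direction labels
come from the common-DEG sets, and hub RNAs are ranked by degree with a
lexicographic tie-break so the ranking is deterministic.

## Survival evaluation

Kaplan--Meier curves, the two-group log-rank test and Cox regression are
standard; Cox fits use Efron tie handling because day-resolution survival
times tie often. Per-RNA stratification uses the median cutoff with ties
assigned to the low group. The log-rank statistic is computed directly
from the pooled 2×2 tables (and is verified against
`survival::survdiff`); having it as a plain function matters below.

The module-level **risk score** is the linear predictor
$\sum_i \hat\beta_i x_i$ of a multivariate Cox fit on the module's three
z-scored expression vectors (standardization makes the betas comparable
across RNAs). Patients are split at the median risk score and the two
groups compared by log-rank. Because the score is fitted and evaluated on
the same patients, the *asymptotic* p-value of that log-rank test is
anti-conservative: the fit picks the direction in covariate space most
associated with outcome, which is a selection event the chi-square
reference does not know about. Cross-validated scores reduce but do not
remove the bias, because each fold's coefficients still depend on the
outcomes the pooled test reuses. We therefore report a **permutation
p-value**: the entire procedure (Cox fit, median split, log-rank
statistic) is recomputed under random permutations of the survival
outcomes (default 199), which makes the null distribution exact by
construction regardless of sample size or censoring pattern. The
asymptotic value is retained in the result (`pvalue_asymptotic`) for
comparison only. Survival analyses use tumor samples only; normals carry
no outcome.

## The synthetic cohort

The generator emulates the features of a TCGA-style tumor/normal cohort
that this pipeline actually exercises:

* **Sample design.** Defaults are 59 normal and 510 tumor samples with
  stages split 168/276/47/19. The full design is kept (only the gene
  space is scaled down, to 300 mRNAs / 100 lncRNAs / 60 miRNAs) because
  the smallest stage bounds the power of the four-way intersection; a
  cohort with eight T4 samples would test a different, underpowered study.
* **Counts.** Negative-binomial around log-uniform base means (5--2000)
  times a log-normal per-sample depth factor (so size-factor estimation is
  non-trivial). Dispersion defaults to 0.05, a typical value for
  moderately-to-highly expressed bulk RNA-seq genes; planted pairs carry
  substantial additional biological variance from the latent factor, so
  their total dispersion is far higher.
* **Differential genes** have their tumor means shifted by
  `planted_log2fc` (default 2) in one fixed direction across all four
  stages.
* **Planted co-expression.** Each planted lncRNA--mRNA pair shares a
  per-sample standard-normal latent factor that multiplies both genes'
  means by $\exp(a f_s - a^2/2)$. The loading is derived from the target
  correlation $r$ and the gene's own log-scale noise
  $\sigma^2 \approx 1/\mu + \phi$ as $a^2 = \frac{r}{1-r}\sigma^2$, which
  makes the expected log-expression correlation of the pair equal $r$
  (default 0.9); the achieved correlation is validated empirically rather
  than imposed exactly. Both members of a pair get the same DE direction —
  a pair that moves in opposite directions could not be positively
  co-expressed.
* **Interactions.** Each planted triplet receives
  `shared_mirnas_per_triplet` (default 5) common edges to miRNAs drawn
  from the DE miRNA pool, on top of independent Bernoulli background
  edges (default probability 0.02).
* **Survival.** Exponential with hazard
  $h_0 \exp(\beta \cdot \text{score})$ where the score is the
  standardized latent factor of the first planted triplet
  ($\beta = 0.8$, $h_0 = 1/730$ per day by default), with administrative
  censoring at the quantile of event times that yields the requested
  censoring fraction (default 0.3).

All draws come from R's Mersenne-Twister generator seeded once, so a
configuration plus a seed reproduces the cohort byte for byte.

The generator deliberately omits batch effects, a dispersion--mean trend,
gene-length bias in counts, isoform structure and read-level noise.
Passing the planted-recovery tests therefore shows the pipeline's logic is
correct and calibrated under its own model assumptions — not that the
thresholds are optimal for any particular real cohort.

## TF regulon scoring

For chosen transcription factors the package scores regulatory importance
per target gene with a random-forest regression (500 trees, all TFs
offered at every split, minimum node size 5): each TF's raw importance is
its share of the ensemble's impurity reduction. Raw shares are
uninformative on their own — a forest grown on pure noise still reduces
training variance — so shares are scaled by the forest's out-of-bag
$R^2$, floored at zero. The product is near zero for targets the TFs
cannot predict out of sample, and per-target importances always sum to at
most 1. Targets are standardized before fitting so the score is invariant
to affine rescaling, and samples are sorted by id before the forest is
grown so column order cannot change the result. Retention then requires
importance above 0.005 *and* Spearman correlation above 0.03 — a
deliberately permissive positive-correlation filter, exposed as a
parameter (the printed value is unusually low and may originate as a typo
for 0.3; we keep it as documented and configurable).

## Numerical and design details worth knowing

* Thresholds are applied with strict inequalities exactly as stated
  (`r > 0.8`, `p < 0.05`, `FDR < 0.01`, `FDR < 0.05`).
* The abundance filter computes `ceiling(min_fraction * n)` with a small
  epsilon guard so floating-point noise cannot change the sample count at
  exact boundaries.
* `bh_adjust` passes `NA` through and excludes it from the number of
  tests; all-zero genes get `NA` statistics and do not inflate the BH m.
* Collinear module triples (|r| > 0.999 between members) are rejected by
  name rather than silently producing an unstable Cox fit.
* Interaction tables are deduplicated on (miRNA, target) with a reported
  count; inconsistent target classes are an error, not a warning.
* Problem sizes in the test suite are desk-scale by design: gene spaces of
  tens to hundreds, the full 569-sample design where power matters, 200
  replicates for calibration checks, and 199 permutations for module
  p-values (smallest attainable p = 0.005).

## Limitations

Sequence-based miRNA-target prediction, cis-regulatory motif analysis and
pathway enrichment are out of scope: interactions arrive as an input
table, and the TF step stops at co-expression importance. The DE module
handles the two-group stage-vs-normal design only — no paired designs,
covariates or shrinkage estimators. The risk-score classifier evaluates
one module at a time; it does not adjust for clinical covariates.
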