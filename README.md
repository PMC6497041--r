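# cernakit

Discovery and prognostic evaluation of competing endogenous RNA (ceRNA)
modules from bulk RNA-seq.

## The problem

Long non-coding RNAs can act as miRNA sponges: by sequestering a miRNA
they derepress that miRNA's mRNA targets. A lncRNA–mRNA pair behaving
this way is (a) dysregulated in tumors relative to normal tissue,
(b) strongly positively co-expressed, and (c) shares more targeting
miRNAs than chance would allow. `cernakit` is for analysts who have
tumor/normal count matrices (mRNA, lncRNA, miRNA), per-sample staging and
survival metadata, and a miRNA→target interaction table, and who want to
go from those inputs to a ranked lncRNA–miRNA–mRNA network and a
survival assessment of each module — with every step testable at desk
scale against a synthetic cohort with known ground truth.

## The method

1. **Stage-wise differential expression.** Counts are normalized with
   median-of-ratios size factors; genes pass an FPKM abundance filter
   (threshold 1 for mRNA/miRNA, 0.1 for lncRNA, in ≥ 10% of samples);
   each tumor stage T1–T4 is compared to normal with a negative-binomial
   Wald test (method-of-moments dispersion). *Common* DEGs satisfy
   |log2FC| ≥ 1 and FDR < 0.01 in all four comparisons with a consistent
   sign.
2. **Pair screening.** Every DE lncRNA × DE mRNA pair is scored by
   Pearson correlation on log2-normalized expression; pairs with
   r > 0.8 and p < 0.05 are retained.
3. **Shared-miRNA enrichment.** For each retained pair, with N the DE
   miRNA universe, K and n the miRNAs targeting the mRNA and lncRNA and
   c the overlap,

   P = Σ_{i=c}^{min(K,n)} C(K,i)·C(N−K,n−i) / C(N,n),

   BH-corrected across pairs; modules with FDR < 0.05 form the network
   (one lncRNA–miRNA and one miRNA–mRNA edge per shared miRNA), and hubs
   are ranked by degree.
4. **Prognosis.** Each module's three RNAs are fit in a multivariate Cox
   model on z-scored expression; the risk score is the linear predictor
   Σβᵢxᵢ; patients are split at the median score and compared by
   log-rank test, with a permutation p-value (the asymptotic one is
   anti-conservative for a self-fitted score).
5. **TF regulons** (optional): random-forest importance of chosen TFs per
   target gene, gated by out-of-bag R² and a positive Spearman filter.

A synthetic cohort generator (`simulate_cohort()`) plants ceRNA triplets
with known co-expression, shared miRNAs and survival effect, so
sensitivity and false-discovery proportion of the whole pipeline are
measurable (`truth_report()`).

## Worked example

```r
library(cernakit)

co  <- simulate_cohort(sim_config(seed = 3))   # 59 normal + 510 tumor
res <- run_cerna_pipeline(co$counts, co$samples, co$lengths,
                          co$interactions)
res$modules[, c("module_id", "lncrna_id", "mrna_id", "N", "K", "n", "c",
                "pvalue", "fdr", "r")]
#>   module_id lncrna_id  mrna_id  N K n c   pvalue      fdr     r
#> 1      M001   LNC0005 MRNA0026 15 5 6 5 0.001998 0.003140 0.931
#> 2      M002   LNC0010 MRNA0030 15 6 6 5 0.010989 0.015110 0.926
#> 3      M003   LNC0013 MRNA0045 15 5 5 5 0.000333 0.000733 0.908
#> ...
truth_report(co$truth, res$modules)[c("sensitivity", "fdp")]
#> $sensitivity [1] 1      $fdp [1] 0
```

All eight planted triplets are recovered with no spurious module. Each
row is one candidate ceRNA pair: `c` of the lncRNA's `n` targeting
miRNAs are shared with the mRNA's `K`, out of a universe of `N` DE
miRNAs; `pvalue` is the hypergeometric tail, `r` the expression
correlation. `degree_ranking(res$network)` ranks hub RNAs. Evaluating
the first module's prognostic value:

```r
ms <- module_risk_score(exprs, tum$os_time, tum$os_event, seed = 1)
ms$logrank_chi2   #> 114.1
ms$pvalue         #> 0.005  (permutation, 199 permutations)
ms$direction      #> "negative"  (high-risk group fares worse)
```

where `exprs` holds the module's three log2-normalized expression rows
over the tumor samples (see `?module_risk_score` for the full
construction). A command-line front end with `simulate`, `de`, `cerna`,
`survive` and `tf` subcommands is installed at
`system.file("cli/cerna", package = "cernakit")`.

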