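# ithsig

Intratumor heterogeneity quadrants and sampling-bias-aware prognostic
gene signatures for multiregion tumor expression cohorts.

## The problem

Prognostic gene signatures are applied to a single biopsy, but tumors
are spatially heterogeneous: different regions of the same lesion can
express a signature's genes differently, so the high/low risk call a
patient receives may depend on which region was sampled.  `ithsig`
quantifies this failure mode and builds signatures that avoid it, for
studies where several tumor regions per patient were profiled
(multiregion microarray/RNA-seq designs, e.g. in esophageal squamous
cell carcinoma).

For each gene *g* the pipeline computes two scores over tumor samples:

* **intratumor heterogeneity** — the dispersion (SD by default) of
  the gene across each patient's regions, averaged over patients with
  ≥ 2 regions;
* **intertumor heterogeneity** — the dispersion across patients of
  one randomly drawn region per patient, averaged over 10 draws.

Thresholding both axes at their means partitions genes into quadrants;
**Q4** (high intertumor, low intratumor) contains genes that are
stable within a tumor but discriminative between patients — the
candidate pool for robust signatures.  Any linear signature
`score = Σ coefficient_i · expression_i` can be audited on a
multiregion cohort: regions are stratified at the cohort-median score,
and a patient whose regions disagree is *discordant*; a cohort with
> 50% discordant patients marks the signature as sampling-biased.
Signature construction from Q4 genes proceeds through a univariate Cox
screen (p < 0.05), lasso refinement with the penalty maximizing the
cross-validated Harrell C-index, and a multi-learner benchmark
(stepwise Cox ×3, ridge, elastic net, lasso, random survival forest,
gradient-boosted Cox) ranked by the average of internal
cross-validated and external-validation C-indexes.

A synthetic-cohort generator draws from the additive two-component
model `x = mu + b_patient + e_region` (`b ~ N(0, tau²)`,
`e ~ N(0, sigma²)`) with an exponential proportional-hazards outcome
driven by planted Q4-like genes, giving every stage a ground truth.

## Worked example

```r
library(ithsig)

# a synthetic multiregion cohort: 100 patients x 3 regions, four
# 250-gene archetype blocks, 10 planted prognostic genes
syn <- generate_cohort(synthetic_config(seed = 1))
syn$cohort
#> multiregion_cohort: 1000 genes x 300 samples
#>   patients: 100 | tumor samples: 300 | normal samples: 0
#>   survival: 100 patients, 66 events

# heterogeneity scores and quadrants
ht <- heterogeneity_table(syn$cohort, n_reps = 10, seed = 1)
ht
#> het_table: 1000 genes | metric SD | thresholds intra 0.5314, inter 0.9357
#> quadrant
#>  Q1  Q2  Q3  Q4 
#>   7 270 493 230

# audit two equal-sized signatures: one on stable-within (Q4-like)
# genes, one on noisy-within (Q1-like) genes
q4 <- gene_signature(grep("^Q4like", ht$gene, value = TRUE)[1:10], rep(1, 10),
                     name = "stable-within")
q1 <- gene_signature(grep("^Q1like", ht$gene, value = TRUE)[1:10], rep(1, 10),
                     name = "noisy-within")
audit_bias(syn$cohort, list(q4, q1))
#>       signature n_genes n_genes_used discordant_fraction biased mean_dispersion
#> 1 stable-within      10           10                0.13  FALSE       0.6024278
#> 2  noisy-within      10           10                0.73   TRUE       2.6932777
#>   score_variance
#> 1      13.252782
#> 2       9.981858
```

The noisy-within signature flips 73% of patients between risk classes
depending on the region sampled (`biased = TRUE` under the > 50%
rule) and its single-biopsy score moves by ±2.69 units between
regions of one tumor; the stable-within signature keeps discordance
at 13% with four-fold tighter per-patient scores and higher
between-patient score variance.

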