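# graftaxis

Serum–allograft axis discovery from matched kidney-transplant
transcriptomes and serum proteomes.

## The problem

After kidney transplantation, graft injury is usually detected late by
routine serum markers, while the informative readout — the allograft
transcriptome — requires an invasive biopsy. If the blood serum proteome is
biologically coupled to the graft's expression state, serum protein
signatures could act as peripheral reporters of allograft health. This
package implements the analysis chain needed to find and validate such
signatures in cohorts where biopsy RNA-seq and serum proteomics are
time-matched (serum drawn at the time of the biopsy):

1. **Coregulated gene networks.** Genes are prefiltered by coefficient of
   variation (CV = s/x̄, targeting ≈2,000 variable genes), z-scored across
   samples, embedded in 2-D with exact t-SNE (genes as points, samples as
   feature dimensions), and partitioned into networks with seeded k-means
   on the embedding. Network *activity* in a sample is the mean z-scored
   expression of its member genes.
2. **Cross-cohort reproducibility.** For two independently processed
   cohorts, each network of cohort A is mapped onto cohort B over their
   common variable genes; a network is *reproduced* when ≥ 80% of its
   common genes fall into one B-network.
3. **Serum axes.** Network activity is correlated with every serum protein
   (Spearman ρ, two-sided t-approximation p), and the similarity structure
   is ordered by hierarchical clustering (complete linkage on 1 − ρ).
   Annotated metabolic (MB) and inflammatory (INF) networks are pooled
   (gene-weighted) into two opposing axis activities.
4. **HEALTH / INJURY signatures.** Proteins are screened per axis at
   |ρ| > 0.6 and p < 0.05; HEALTH = MB-up ∪ INF-down, INJURY = MB-down ∪
   INF-up, ranked by their strongest qualifying |ρ|, top 10 kept.
5. **Validation.** A signature's *intrasignature correlation* (mean
   pairwise Spearman ρ of its proteins) must exceed every one of 10 random
   10-protein control sets, and its score (mean NPX of member proteins)
   must associate with kidney function (eGFR) — checked for the top-3,
   top-6 and top-10 truncations.

Because real patient cohorts cannot ship with the package, a first-class
synthetic cohort generator produces data with the exact structure the
method assumes — latent MB/INF factors (anti-correlated), gene modules
loading on them, proteins coupled to the factors at a configurable target
Spearman ρ via a Gaussian copula (Pearson parameter 2·sin(πρ/6)), and eGFR
coupled to the same factors — together with the ground truth needed for
recovery testing.

## Worked example

```r
library(graftaxis)

# reference-scale synthetic cohort: 15 patients, 2,600 genes in 15 planted
# modules (4 metabolic, 8 inflammatory, 2 ECM, 1 free), 159 serum proteins
# with 10 INJURY-like and 10 HEALTH-like planted couplings
run <- run_pipeline(list(synthetic = TRUE, k = 15L),
                    out_dir = "demo_out", seed = 1)
print(run$fit)
#> Serum-allograft axis fit
#>   cohort: 15 samples, 2600 genes (2000 variable), 159 proteins
#>   gene networks: k = 15 (CV threshold 0.2620)
#>   HEALTH signature (10): PRT016, PRT011, PRT012, PRT013, PRT015, PRT014, PRT018, PRT017, PRT151, PRT108
#>   INJURY signature (9): PRT002, PRT001, PRT003, PRT004, PRT006, PRT005, PRT024, PRT009, PRT010

print(run$validation)
#> validation_report (max rule, 10 null sets)
#>   top_3: intra rho 0.951 vs null -0.058 +- 0.093 -> exceeds: TRUE
#>   top_6: intra rho 0.827 vs null -0.011 +- 0.042 -> exceeds: TRUE
#>   top_9: intra rho 0.676 vs null -0.000 +- 0.046 -> exceeds: TRUE

ca <- run$fit$clinical_assocs$INJURY
ca[ca$variable == "egfr", ]
#>   variable   rho      p n_used slope intercept status
#> 1     egfr -0.55 0.0337     15 -14.8       125     ok
```

Reading the output: the planted INJURY-like proteins (`PRT001`–`PRT010`)
dominate the extracted INJURY signature and the HEALTH-like proteins
(`PRT011`–`PRT020`) the HEALTH signature, even at n = 15; the INJURY
signature is far more internally correlated than any random control set
(0.95 vs a null around 0 for the top-3 truncation); and its score falls
with kidney function (Spearman ρ = −0.55 against eGFR), the planted
direction. At this cohort size one or two noise proteins entering the tail
of a signature is expected behaviour, not a defect.

The model-object interface mirrors classic R modelling code:
`graft_axes()` is the fitting function; `print`, `summary`, `coef`
(per-protein axis correlations), `predict` (score a new serum panel with a
frozen signature — the external-validation operation) and `plot` (ordered
correlation heatmap) are available on the fit.

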