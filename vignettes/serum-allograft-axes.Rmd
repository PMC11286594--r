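---
title: "Methods: serum-allograft axis discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum-allograft axis discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic cohort generator does and does not emulate, the
numerical conventions, and the design decisions taken where the procedure
was genuinely open.

## The model

The analysis assumes a cohort of kidney-transplant patients in which a
graft biopsy transcriptome (bulk RNA-seq counts) and a serum protein panel
(relative, log-scale NPX units) were measured at the same time point, so
that per-sample quantities from the two layers may be correlated directly.
The working model is a latent-factor one: the graft's expression state
varies along a small number of coordinated programs, dominated by two
opposing axes — a metabolic/tubular program (MB) and an
inflammatory/immune program (INF) — and a subset of serum proteins tracks
those axes monotonically. Nothing in the fitting machinery enforces this
model; it is what the synthetic generator plants and what the method is
designed to detect when present.

### Gene networks

* **Normalization.** Raw counts are normalized with median-of-ratios size
  factors: the size factor of a sample is the median, over genes whose
  count is positive in every sample, of count / gene-wise geometric mean.
  Genes containing zeros do not vote on the factors but are rescaled. A
  matrix in which every gene has a zero somewhere has no reference set and
  is rejected (`NoReferenceGenes`).
* **Variable genes.** Genes are ranked by coefficient of variation
  (sample sd / mean, n−1 denominator; a zero-mean gene gets CV 0) and the
  top `target_count` are kept. The prefilter is expressed as a count
  (default 2,000, the "about two thousand variable genes" convention for
  this assay scale) rather than a CV cutoff, and the implied cutoff — the
  CV of the last included gene — is reported back. CV is computed on the
  linear normalized-count scale by default; a `log1p` option exists
  because the appropriate scale is assay-dependent and the original
  convention is not fixed by the procedure itself.
* **Embedding.** The z-scored gene × sample matrix is embedded in 2-D by
  exact t-SNE with the genes as points. At this scale (≈2,000–2,600
  points) the O(n²) exact gradient is affordable, fully deterministic
  given the seeded random initial layout, and avoids approximation
  parameters. Defaults: perplexity 30, 500 gradient iterations with early
  exaggeration 12 for the first 100, learning rate 200, adaptive gains,
  momentum 0.5 → 0.8 at iteration 250. Perplexity must satisfy
  n > 3 · perplexity.
* **Network calling.** Seeded k-means with 25 restarts on the 2-D
  coordinates, best within-cluster sum of squares kept. Clustering the
  *embedding* rather than the z-matrix is a deliberate choice: the
  networks of interest are the visual t-SNE islands, and clustering the
  coordinates reproduces exactly that semantics. k is a user parameter
  (the study-scale default is the fixed k the analyst chooses after
  inspecting the embedding); when no k is given, `choose_k()` scans a grid
  and takes the best mean silhouette width, ties resolving to the smallest
  k. Labels are renumbered canonically — network 1 is the largest,
  descending, size ties broken by smallest member gene id — so runs are
  diffable.
* **Activity.** Network activity per sample is the unweighted mean
  z-scored expression of the member genes; merging two networks therefore
  yields the size-weighted mean of their activities.

### Cross-cohort correspondence

Two cohorts are compared only through their labelings: variable genes are
selected in each cohort independently, the intersection is taken, and for
each A-network the fraction of its *common* genes in each B-network is
tabulated (row-stochastic by construction). A network "maps predominantly"
when its largest fraction reaches θ = 0.8 (configurable). The fractions
are computed over common genes only — an A-network may be well-defined yet
poorly covered by the intersection; such networks get an all-zero row, a
`FALSE` flag and a warning rather than an error, so every network stays
visible in the output.

### Serum axes and signatures

All correlation is Spearman's: Pearson on average ranks, two-sided p from
the t-approximation t = ρ·√((n−2)/(1−ρ²)), missing values deleted
pairwise, at least 3 complete pairs per cell. Similarity structure is
ordered by complete-linkage hierarchical clustering on the distance
1 − ρ; rows (networks) are clustered on their activity profiles and
columns (proteins) on their abundance profiles across samples.

Axis activity pools the member networks of an axis *gene-weighted*: the
axis row is the mean z-scored expression over all genes belonging to any
member network. Since network activity is itself a mean over genes,
pooling genes (not averaging network rows) is the consistent extension; a
network-weighted mean would up-weight small networks.

Signature extraction screens each protein per axis at |ρ| > `rho_min`
(default 0.6) and p < `p_max` (default 0.05, raw p-values; a
Benjamini–Hochberg option exists but is off by default because the screen
is descriptive, not inferential). The combined categories use union
semantics — INJURY = MB-down ∪ INF-up, HEALTH = MB-up ∪ INF-down — because
a serum protein may report one axis only and still belong to the
signature; intersection semantics would silently discard single-axis
reporters. Ranking is by the largest |ρ| among the conditions the protein
actually satisfies, descending, ties by protein id; the top `top_k`
(default 10) form the signature. The printed filter convention "> 0.6 or
≤ 0.6" that sometimes appears for such screens is implemented as
|ρ| > 0.6 with the sign deciding up versus down; a literal "≤ 0.6" branch
would admit arbitrarily weak negative correlations.

### Validation

The intrasignature correlation is the off-diagonal mean of the member
pairwise Spearman matrix. The null is 10 random sets of 10 panel proteins
(defaults configurable), drawn from the full measured panel *including*
signature members — the natural exchangeable control; an `exclude` option
supports sensitivity analysis. The default pass rule is strict dominance
(intra-ρ greater than *every* null draw), which with 10 null sets has an
exact false-pass probability of 1/11 under exchangeability; a
95th-percentile rule is available. Signature scores are plain means of
member NPX values; clinical association reports Spearman ρ/p plus the
least-squares line for XY plots, with per-variable pairwise deletion and a
non-fatal `too_few_pairs` status. An optional leave-one-protein-out
recomputation is reported alongside (never applied silently), because
outlier removal in small panels otherwise becomes an undocumented analyst
degree of freedom.

## The synthetic cohort generator

The generator is part of the package's testable surface, not a fixture.
It emulates precisely the structure the model assumes:

* Latent axis factors (MB, INF) are standard bivariate normal with
  correlation −0.7. The axes must oppose strongly: a protein jointly
  coupled at Spearman ±0.9 to both axes is only realisable when the
  factor correlation is ≤ −0.65 (the symmetric dual-coupling bound is
  √((1−c)/2)), and the strongest planted couplings in the reference
  scenario are ±0.9.
* Each module m carries a factor √w·g_axis + √(1−w)·u_m with w = 0.5, so
  same-axis module factors correlate at 0.5 — high enough that axis
  members group together in the similarity dendrogram, low enough that
  modules remain distinct embedding islands.
* Member-gene latents are loading·f_m + noise (reference loading 0.85,
  noise sd 0.3); counts are exp(log-baseline + 0.7·latent) with
  log-baselines uniform on [log 50, log 2000], i.e. log-normal
  "normalized counts" whose CV behaviour under the variable-gene filter
  is realistic. Background genes are pure noise and are therefore mostly
  removed by the CV filter, as intended.
* Proteins reach a target Spearman ρ with an axis factor through a
  Gaussian copula (Pearson parameter 2·sin(πρ/6) — exact rank-correlation
  control under normality). Dual couplings solve the two-factor linear
  system and reject unsatisfiable requests (`InfeasibleCoupling`). eGFR
  couples the same way (+0.6 MB / −0.6 INF in the reference scenario) and
  is then mapped through a strictly monotone transform, which preserves
  Spearman exactly.
* One master seed drives fixed, named sub-streams for factors, genes,
  proteins and clinical data, so enlarging the protein panel cannot
  perturb the gene matrix.

The reference scenario mirrors the study scale: 15 patients, 15 modules of
130 genes (4 MB, 8 INF, 2 ECM, 1 axis-free) plus 650 background genes
(2,600 total), 159 proteins with 10 planted INJURY-like (MB−/INF+,
|ρ| decreasing 0.9 → 0.7 with rank) and 10 HEALTH-like proteins.

What the generator does **not** emulate: library-size artifacts, batch
effects, count dispersion/dropout, assay detection limits, medication or
comorbidity structure, and histology labels beyond a factor-thresholded
rejection/nonrejection tag. Passing recovery tests therefore demonstrates
that the machinery detects the assumed structure when present at realistic
strength — not that real cohorts contain that structure, nor robustness to
the artifacts above.

## Numerical conventions

* Sample (n−1) standard deviations everywhere; z-scoring asserts no
  constant rows and is idempotent to 1e-10.
* Alignment orders samples lexicographically (determinism across input
  orders); boundary ties in gene selection and rank ties in signatures
  break lexicographically by id.
* Spearman p is clamped into (0, 1]: |ρ| = 1 returns the smallest
  positive double rather than 0.
* Matrix writers emit 17 significant digits so a write/read round trip is
  exact; missing expression values are a hard load error while missing
  clinical values are tolerated and deleted pairwise.
* t-SNE determinism comes from R-side seeded initialisation; the compiled
  gradient is deterministic. k-means restarts and null draws are seeded
  through the same mechanism.

## Validation experiments and problem sizes

The shipped tests and the acceptance script run, at sizes chosen to keep a
full pass in a few minutes on one CPU:

* Spearman against a brute-force rank-then-Pearson oracle (20 random
  vectors with ties, agreement to 1e-12).
* Module recovery on 5 reference-scale cohorts (2,600 genes, n = 15,
  k = 15): median adjusted Rand index ≈ 0.91 against the planted modules.
* INJURY signature recovery on n = 200 cohorts (10 seeds): the planted 10
  proteins recovered in the extracted top-10 (median 10/10). These runs
  compute axis activity from the planted module assignments — network
  recovery has its own experiment, and decoupling the two isolates what
  each one measures.
* Null calibration over 20 cohorts: planted signatures pass the
  exceeds-null rule in 100% of runs, random 10-protein sets in ≈5%
  (theoretical rate 1/11).
* Truncation monotonicity at n = 200: intra-ρ top-3 ≥ top-6 ≥ top-10 when
  planted couplings decrease with rank.
* Cross-cohort reproducibility on twin cohorts sharing the planted
  partition (6 modules, loading 0.9): all networks map predominantly at
  θ = 0.8.

## Known limitations

* With 15 samples the rank-based statistics are coarse (the smallest
  achievable two-sided p at |ρ| = 1 is bounded by the permutation count),
  and one or two noise proteins entering a top-10 signature is expected;
  the validation stage, not the screen, is the guard.
* Exact t-SNE memory is O(n²); beyond ~10,000 genes a Barnes–Hut or
  interpolation scheme would be needed.
* k-means on a 2-D embedding inherits t-SNE's known distortions of global
  geometry; the canonical numbering stabilises identity across runs but
  cluster *boundaries* on diffuse islands remain seed-sensitive.
* Axis membership of networks is user input by design (it encodes
  biological annotation); the majority-vote mapping from planted truth
  exists only for synthetic experiments.
* The package compares cohorts only through label structure; it does not
  attempt cross-platform expression harmonisation.
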