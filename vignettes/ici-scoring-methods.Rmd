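---
title: "Immune-infiltration scoring: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-infiltration scoring: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`icistrat` implements a tumor-immunology analysis chain for bulk
transcriptomes of gastric cancer (and structurally similar cohorts): estimate
the immune-cell composition of each sample, cluster the cohort by its immune
landscape, derive the gene programs that separate those clusters, compress
the programs into a single per-sample immune-cell-infiltration (ICI) score,
and ask whether that score stratifies survival, mutational burden, and
chemotherapy response. Every stage also runs on synthetic cohorts with known
ground truth, which is how the package validates itself.

```{r, eval = FALSE}
library(icistrat)
co  <- generate_cohort(sim_config(n_samples = 300, seed = 1))
res <- run_ici_pipeline(co$expression, co$signature_matrix, co$clinical,
                        mutations = co$mutations, seed = 1)
print(res)
```

# The analysis chain

## Deconvolution

`deconvolve_sample()` estimates cell-type proportions against a marker
signature matrix (genes × cell types). Two solvers are provided:

* `nnls` — non-negative least squares on the natural scale (Lawson–Hanson
  active set, compiled). In the noiseless regime this solver is exactly
  checkable: if the mixture is truly a non-negative combination of the
  signature columns, the recovered fractions are correct to numerical
  precision, and the tests exploit this.
* `nusvr` — linear-kernel ν-support-vector regression at
  ν ∈ {0.25, 0.5, 0.75} on z-scored data, keeping the fit with the lowest
  reconstruction RMSE. This mirrors the reference-based design used by
  the widely cited 22-cell-type deconvolution tool. The ν-SVR coefficients
  live on the column-standardized scale and are divided by each signature
  column's standard deviation before being clipped at zero and normalized
  to fractions; without that back-transform the fractions are biased by the
  ratio of column scales.

Both solvers return per-sample diagnostics (RMSE, Pearson correlation
between the reconstructed and observed mixture). `permutation_pvalue()`
deconvolves gene-label permutations of the mixture and reports the add-one
estimator `p = (1 + #{r_null ≥ r_obs}) / (n_perm + 1)`, so p is never zero;
`filter_effective()` keeps samples with p below a threshold (default 0.05,
the convention of the cited tool — the filter that reduces a raw cohort to
the "effective" samples). The signature matrix is a user input; no
third-party reference panel is bundled, and tests use the generator's
synthetic reference.

## Immune and stromal scores

`ssgsea_score()` is the single-sample rank-based running sum: genes are
ranked by expression (average ranks on ties), and the score is the summed
difference between the weighted in-set empirical CDF (weights `rank^alpha`,
`alpha = 0.25` per the single-sample enrichment literature) and the
unweighted out-of-set CDF. The statistic depends on expression only through
ranks, so it is exactly invariant under any strictly increasing transform —
a property the tests assert bit-for-bit.

One calibration note: for a *random* gene set the expected score is not
zero. The walk descends from high to low expression while the in-set
weights are largest at the top, so the in-set CDF systematically leads the
out-of-set CDF early in the walk. Random sets therefore form a positive,
stable null rather than a null at zero, and enrichment should always be
judged against that null (the test suite checks that top-ranked sets escape
it upward and bottom-ranked sets downward). No across-sample rescaling is
applied; the raw running sum is kept oracle-checkable.

## Consensus clustering

`consensus_cluster()` implements resampled consensus clustering with PAM
(k-medoids) as the base learner, used twice in the chain: on immune-fraction
profiles (three ICI clusters) and on DEG expression (two gene clusters).
Defaults follow the cited consensus-clustering tool: 500 subsampling rounds
at 80% of samples, Euclidean distance, final labels from Ward-linkage
hierarchical clustering of one minus the consensus matrix. Fractions are
clustered unscaled (they are already proportions); expression features are
z-scored per gene (`scale_features = TRUE`), since genes differ in scale.

PAM itself (`kmedoids()`) is compiled and deterministic. Instances with at
most 2000 candidate medoid sets are solved exactly by enumeration, because
the classical swap heuristic can stall in one-swap local optima even at
n ≤ 8 (the reference `cluster::pam` stalls in the same optima); larger
instances use BUILD + steepest-descent SWAP with cost ties broken by the
lowest candidate index, and the total cost is asserted non-increasing
across swap iterations. `select_k()` minimizes the proportion of ambiguous clustering
(PAC: off-diagonal consensus entries strictly inside (0.1, 0.9)), with ties
to the smaller k. The reproduction path fixes k = 3 for ICI clusters and
k = 2 for gene clusters, as callers may always override the PAC choice.
Pairs never co-sampled (vanishingly rare at 500 × 0.8) get consensus 0 and
are counted in `n_undefined`.

## Differential genes and gene signatures

`differential_genes()` tests every gene in every pairwise cluster contrast
with the two-sided Wilcoxon rank-sum test, adjusts with Benjamini–Hochberg
within each contrast, and computes `log2fc = log2(mean_a + 1) −
log2(mean_b + 1)`. A gene is selected when adjusted p < 0.05 and
|log2 fold-change| > 1. The fold-change cutoff is read on the log2 scale:
on the natural scale "fold-change > 1" excludes nothing, so the log2
reading (a two-fold change) is the only informative interpretation, and it
is applied symmetrically to both directions. The DEG union is the set
selected in at least one contrast. The Wilcoxon statistic was chosen over a
parametric model because merged multi-platform cohorts have heavy-tailed,
platform-shifted expression, and because it admits an independent oracle.

`gene_clusters()` consensus-clusters the *samples* (k = 2) on z-scored
log2 DEG expression. `split_signatures()` then correlates each DEG with the
gene-cluster membership indicator: positive correlation defines signature A,
negative defines signature B, zero-correlation or constant genes are
dropped. The rule is exactly label-symmetric — renaming the clusters swaps
A and B. Because the cluster labels coming out of any clustering are
arbitrary, the end-to-end driver anchors the orientation deterministically:
the cluster with the worse observed/expected mortality (from the log-rank
decomposition) is called gene cluster A, so a *high* ICI score always means
the poorer-prognosis program is up. Without an anchor the sign of the score
would flip from run to run and signed downstream statistics (such as the
score–TMB correlation) would be meaningless.

`boruta_select()` is the all-relevant feature selection: each iteration
pairs every feature with a permuted shadow copy, fits a random forest
(impurity importance, `ranger`), and credits features that beat the best
shadow. After `n_iter` iterations a two-sided binomial test at 0.01
classifies features as confirmed/rejected/tentative; tentative features are
resolved against the median shadow maximum. At least 8 iterations are
required — below that the binomial tail cannot reach 0.005 and no decision
is possible. Signatures A and B are reduced separately by default
(`jointly = TRUE` runs one joint reduction); a reduction that would empty a
signature is refused with a warning, keeping the pair usable.

## The ICI score

`pc1_scores()` restricts expression to a signature, applies `log2(x + 1)`,
centers and unit-scales each gene, and projects samples onto the first
principal component. Unscaled TPM PCA would be dominated by a handful of
high expressors, hence the transform. Sign indeterminacy of PCA is removed
by a fixed orientation rule: the component is flipped if the sum of its
loadings is negative (if exactly zero, the first nonzero loading decides).
Projections are centered by construction.

The per-sample score is `ici_score = PC1(signature A) − PC1(signature B)`.
The Σ of the originating formula is read as the per-patient projection onto
the first component of each signature — only PC1 is named in the source
construction, so only PC1 is used. Two exact identities pin the
implementation down: the score is identically zero when A = B, and swapping
A and B negates it exactly. `dichotomize()` splits at a cutoff (boundary to
"low"), normally the Youden-optimal cutoff below.

## Outcome analyses

Kaplan–Meier curves and log-rank tests delegate to the `survival` package
(`survfit`/`survdiff`), with hand-computed worked examples in the tests
pinning the conventions. `youden_cutoff()` scans midpoints of adjacent
sorted unique scores in both classification directions and maximizes
J = sensitivity + specificity − 1 against the death indicator — the only
binary outcome available, which is the one material interpretation of a
Youden cutoff in this design; ties resolve toward the median score. The
search is verified against exhaustive evaluation on every tested instance.
Note that optimizing the cutoff and testing survival on the same cohort is
optimistic; the driver reproduces this in-sample design deliberately and
this caveat should accompany any real-cohort report.

TMB is mutations per megabase: nonsynonymous counts (classes listed in
`nonsynonymous_classes`) divided by 38 Mb of interrogated exome — both
field-convention defaults, both arguments. `tmb_analyses()` bundles the
Wilcoxon of TMB between score groups, the signed Spearman correlation of
score and TMB (no directional assertion is built in), the median-split TMB
survival comparison, and the four-way TMB × score strata log-rank (df 3
when all four strata are populated; empty strata are dropped and the df
reported accordingly). Mandard tumor-regression grades map 1–2 to major and
3–5 to minor response, and `response_compare()` reports the two-sided
Wilcoxon with the direction of the median difference. Subgroup survival
splits at age 65 and early (I–II) vs advanced (III–IV) stage by default —
the conventional cuts, both exposed as arguments.

# The synthetic-cohort generator

`sim_config()`/`generate_cohort()` define the study conditions under which
the package demonstrates its properties; they are first-class, tested code.

The generative model, per sample:

* a latent immunophenotype cluster (uniform over `n_clusters = 3`) with a
  continuous latent score: cluster means equally spaced on [+1, −1], within-
  cluster jitter `latent_sd = 0.4`;
* cell-type fractions from a cluster-specific Dirichlet over the standard
  22-type immune panel. The default concentrations put weight 4 on a
  disjoint block of cell types per cluster and 1 elsewhere at total
  concentration 150 — clusters are well separated yet overlapping, roughly
  matching the within-phenotype spread of published deconvolution studies;
* marker expression `signature %*% fractions` (markers log-normal, 25-fold
  location shift in the owning type, 5 markers per type), plus a shared
  log-normal background (median 50);
* planted differential blocks: each cluster owns `n_de_genes_per_cluster =
  50` background genes whose expression is multiplied by
  `2^(de_log2fc × affinity)`, where affinity falls linearly from 1 at the
  owning cluster's latent mean to 0 at ¾ of the latent range. The planted
  log2 fold-change between a block's own cluster center and the farthest
  center is exactly `de_log2fc = 3`. The graded response (rather than a
  binary per-cluster shift) is deliberate: real immune expression programs
  vary along a hot–cold axis rather than switching per subtype, and with
  three equal, symmetric binary blocks the two-way gene clustering would
  have no preferred merge — the split would be decided by noise, and the
  score's monotone link to the latent axis (which downstream properties
  rely on) would be a coin flip;
* additive Gaussian noise (`noise_sd = 5` natural-scale units against a
  background median of 50, i.e. roughly 10% noise) truncated at zero, then
  TPM rescaling;
* exponential survival with per-cluster hazard ratios. The default spaces
  successive clusters a factor 2 apart (4, 2, 1 for three clusters), with
  the immune-hot, high-score cluster at the highest hazard, and baseline
  hazard 0.02/month (median survival ≈ 35 months for the reference
  cluster, a realistic advanced-GC scale). Censoring is independent
  exponential, calibrated per subject so each is censored with probability
  `censor_rate = 0.3`;
* mutation counts coupled to the latent score through a Gaussian copula at
  a target Spearman correlation (default −0.5; the Pearson parameter is
  back-transformed via `2 sin(πρ/6)`), quantile-mapped to Poisson with mean
  120, and written as MAF rows with Missense/Silent/Nonsense drawn at
  0.7/0.2/0.1 so the nonsynonymous TMB filter is genuinely exercised;
* a tumor-regression grade whose major-response probability decreases
  logistically in the standardized latent score.

All randomness derives from one seed through fixed per-component
substreams, so the same seed reproduces a cohort bit-for-bit and changing
one component's draws does not perturb the others.

What the generator does *not* emulate: batch effects between merged
platforms, expression subtypes (EBV/MSI/GS/CIN), copy-number structure,
gene–gene correlation beyond the planted programs, non-proportional
hazards, or informative censoring. Tests passing on these cohorts show the
machinery is correct and calibrated under its stated model — not that the
biological conclusions transfer to any real cohort.

# Numerical choices and degenerate inputs

* Duplicate gene rows collapse by mean on read (order-independent).
* No batch correction on merge by default; optional per-cohort gene-wise
  z-scaling sits behind `rescale = TRUE`, a deviation from silence rather
  than from any stated procedure.
* Expression is handled on the natural scale internally; `log2(x + 1)` is
  applied exactly where a contract says so (DEG clustering features, the
  signature split correlation, PCA).
* NNLS uses a relative gradient tolerance (10⁻¹² of the initial gradient
  scale) and guards the step-length division; PAM breaks all cost ties by
  lowest index; the permutation p-value can never be 0; zero-variance genes
  are dropped with warnings wherever a correlation or scaling would be
  undefined; constant scores refuse a Youden cutoff.
* Problem sizes in the validation suite: recovery experiments use cohorts
  of 60–300 samples and 500 genes; the stratification-power experiment runs
  100 independent 300-sample cohorts with 50 consensus resamples and
  20 Boruta iterations per cohort — enough resolution for the properties
  being asserted while keeping the whole suite comfortably reproducible on
  one CPU.

# Known limitations

* The Youden cutoff against the death indicator ignores time-to-event
  information; a time-dependent ROC cutoff is out of scope.
* In-sample cutoff optimization (above) inflates the apparent separation of
  the score groups; external validation is the user's responsibility.
* The deconvolution permutation filter calibrates on gene-label exchange,
  which ignores gene–gene correlation; on real data its null is
  approximate.
* Cox modelling is intentionally absent — the chain reports only
  KM/log-rank comparisons, matching its originating design.
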