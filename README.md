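# icistrat

Immune-cell-infiltration (ICI) scoring and survival stratification for bulk
tumor transcriptomes.

Solid tumors differ sharply in how much — and which — immune infiltrate they
carry, and in gastric cancer that landscape tracks prognosis and treatment
response. `icistrat` implements the full analysis chain that turns a bulk
expression cohort into a single prognostic immune score per patient, for
computational oncologists and translational researchers who want each stage
to be inspectable and testable:

1. **Deconvolution** — estimate 22 immune-cell fractions per sample against
   a marker signature matrix (NNLS or linear ν-SVR), with a permutation
   p-value filter for "effective" samples.
2. **Immune landscape clusters** — resampled k-medoids (PAM) consensus
   clustering of the fraction profiles into ICI clusters (k = 3), with PAC
   and CDF-area statistics for k selection; single-sample ssGSEA immune and
   stromal scores characterize the clusters.
3. **Gene signatures** — pairwise Wilcoxon differential genes between ICI
   clusters (BH-adjusted p < 0.05, |log2FC| > 1), two consensus gene
   clusters, a correlation-signed split into signatures A and B, and Boruta
   shadow-feature reduction.
4. **The ICI score** — per sample,

   `ICI score = PC1_A − PC1_B`

   the difference of the first-principal-component projections of the two
   signatures (log2, gene-standardized PCA with a deterministic sign
   convention).
5. **Stratification** — Youden-index optimal cutoff, Kaplan–Meier /
   log-rank survival comparison (overall and within clinical subgroups),
   tumor mutational burden from MAF (nonsynonymous / 38 Mb), the signed
   Spearman score–TMB correlation, four-way TMB × score survival strata,
   and chemotherapy response by Mandard tumor-regression grade
   (TRG 1–2 major, 3–5 minor).

A synthetic-cohort generator (`sim_config()` / `generate_cohort()`) draws
cohorts with known ground truth — cluster-linked cell-type mixtures,
planted differential programs along a latent immune axis, cluster-linked
exponential hazards, mutation loads rank-correlated with the latent score,
and TRG labels — so every stage of the chain is validated against
recoverable truth. See the methods vignette
(`vignettes/ici-scoring-methods.Rmd`) for the models, defaults, and design
rationale.

## Worked example

```r
library(icistrat)

co  <- generate_cohort(sim_config(n_samples = 300, seed = 1))
res <- run_ici_pipeline(co$expression, co$signature_matrix, co$clinical,
                        mutations = co$mutations, seed = 1)
print(res)
#> ICI scoring pipeline result
#>   samples analyzed: 300 (of 300 deconvolved)
#>   infiltration clusters: 3 | DEGs: 228 | signature A/B: 34/36
#>   score cutoff (Youden): -13.1940 (J = 0.069)
#>   score-group log-rank p: 3.046e-06
#>   Spearman(score, TMB): -0.243 | TMB Wilcoxon p: 0.1686
#>   response: median score major -9.868 vs minor 9.667 (p=8.326e-14)

head(res$scores, 3)
#>   sample_id      pc1_a     pc1_b  ici_score group
#> 1     S0001 -7.0578004  8.937890 -15.995691   low
#> 2     S0002 -4.8554240  3.145984  -8.001408  high
#> 3     S0003  0.4708591 -3.535692   4.006551  high
```

Reading the output: the cohort's immune-fraction landscape splits into
three infiltration clusters; 228 genes separate them, reduced by Boruta to
signatures of 34 (A) and 36 (B) genes. Each sample's score is its PC1
projection difference; the Youden cutoff dichotomizes the cohort, and the
high-score group (the poorer-prognosis program up, by the package's
orientation convention) dies faster — log-rank p ≈ 3×10⁻⁶ here, matching
the planted hazard ratio of 2 between successive latent clusters. The score
correlates negatively with mutational burden (planted ρ = −0.5; the
pipeline estimate passes through deconvolution, clustering, and signature
noise, so it attenuates), and major chemotherapy responders sit at markedly
lower scores than minor responders.

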