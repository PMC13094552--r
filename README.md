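# suctionmorph

Quantifying morphological specialization for suction feeding in toothed
whales (odontocetes), and testing whether that specialization is associated
with convergence in skull shape.

Specialized suction feeding evolved independently in several odontocete
lineages (sperm whales, beaked whales, monodontids, pilot whales, Risso's
dolphin). Whether a species captures prey by suction usually cannot be
observed directly — least of all in fossils — so ecologists infer it from
morphology. `suctionmorph` implements a complete analysis pipeline for that
inference problem, built around ordinal (0–3) scores of suction-related
morphological characters:

- **Suction specialization index (SSI).** For taxon *i* with scores
  *s<sub>ij</sub>* over *m* characters, SSI<sub>i</sub> = CharMean<sub>i</sub>
  = (1/m) Σ<sub>j</sub> *s<sub>ij</sub>*, with CharSum as the unaveraged
  variant and an **adjusted SSI** computed over the osteological/dentition
  characters only (excluding round mouth and throat grooves), which is what
  a fossil can provide.
- **Association with feeding mode.** Kruskal–Wallis rank-sum tests of each
  character (and the composites) between Suction and Other feeders;
  Blomberg's *K* phylogenetic signal with a tip-shuffling permutation test;
  and phylogenetic generalized least squares (PGLS) under Brownian motion,
  β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y with V the shared-branch-length covariance of the
  tree, alongside the matching OLS fit.
- **Predictive power.** Single-character and multivariate logistic
  classifiers evaluated on a stratified 75/25 train/test split: accuracy,
  precision, recall, F1, confusion matrix, Clopper–Pearson exact 95% CI,
  and a one-sided exact binomial test of accuracy against the
  no-information rate (NIR).
- **Morphospace convergence.** Standardized PCA of an independent
  skull-shape character block, phylomorphospace projection via
  maximum-likelihood Brownian ancestral states, and Stayton's convergence
  metric C1 = 1 − D<sub>tip</sub>/D<sub>max</sub> over all PCA axes, with
  significance from Brownian-motion simulations using the rate matrix
  estimated from the data.
- **Synthetic data with known truth.** A Yule-tree + threshold-liability
  generator plants suction-specialist clades with a tunable latent shift,
  so every stage is testable end-to-end without any data download.

## Worked example

```r
library(suctionmorph)

ds  <- generate_dataset(synth_config(seed = 42))   # 68 taxa, 10 + 25 characters
run <- run_pipeline(ds$suction, ds$labels, ds$tree, ds$skull,
                    config = analysis_config(seed = 42))
print(run)
```

```
pipeline run
  taxa: 68; top SSI: t43 (3.000)
  battery: NIR 0.7059, best accuracy 1.0000
  morphospace: PC1 18.2%, PC2 14.4%
  convergence: mean C1 0.0062, p 0.981
```

The top-ranked taxa are members of the planted specialist clades (SSI near
3 means every suction-related character is strongly expressed; the adjusted
SSI stays high because the shift is osteological too):

```r
head(run$ssi[order(-run$ssi$char_mean), c("taxon", "char_mean", "adjusted_ssi", "score_sd")], 3)
#>    taxon char_mean adjusted_ssi  score_sd
#> 62   t43       3.0        3.000 0.0000000
#> 63   t44       3.0        3.000 0.0000000
#> 60   t63       2.9        2.875 0.3162278
```

The classifier battery reports, per predictor, test-set accuracy with its
exact binomial CI and the p-value against the NIR:

```r
subset(run$battery$table,
       predictor %in% c("reduced_dentition", "CharMean", "multivariate_all"),
       select = c(predictor, accuracy, ci_low, ci_high, p_vs_nir))
#>            predictor  accuracy    ci_low   ci_high    p_vs_nir
#> 2  reduced_dentition 0.8235294 0.5656821 0.9620149 0.216926961
#> 12          CharMean 1.0000000 0.8049357 1.0000000 0.002681943
#> 14  multivariate_all 0.8235294 0.5656821 0.9620149 0.216926961
```

Here the composite index separates the classes perfectly on the held-out
taxa (accuracy 1, CI lower bound 0.805, p = 0.0027 against NIR = 0.706),
while the convergence stage finds what it should on non-convergent skull
data — a mean C1 indistinguishable from drift:

```r
print(run$convergence)
#> mean C1 = 0.0062 over 190 focal pairs; p = 0.981 (1000 BM simulations)
```

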