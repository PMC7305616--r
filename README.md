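# eigrad

Feature attribution for differentiable prediction models, with the
extensions that make integrated gradients usable on genomics-style tabular
models: nonlinear attribution paths, informed baselines, and a statistical
test that turns per-sample attributions into a defensible list of
class-level significant features. The motivating application is splicing-code
models — networks that predict cassette-exon inclusion (Ψ) and differential
inclusion (ΔΨ) from hundreds of regulatory sequence features — but any
scalar differentiable predictor works.

## The method

For a predictor *F* : ℝᵖ → ℝ, a sample *x* and a reference point *x′*, the
attribution of feature *j* is the line integral

attr_j(x) = ∫₀¹ ∂F(γ(α))/∂γ_j(α) · ∂γ_j(α)/∂α dα

along a path γ with γ(0) = x′, γ(1) = x. Classic integrated gradients take
the straight line in feature space from an all-zero baseline. This package
additionally provides:

- **Paths** that stay close to the data manifold: a straight line in the
  latent space of an encoder/decoder pair, decoded back to feature space
  (H-L); and shortest paths through a k-nearest-neighbor graph of training
  points in the original (O-N) or latent (H-N) space, found with Dijkstra's
  algorithm.
- **Baselines** beyond zero: the decoded zero latent vector (≈ the training
  mean), and group-specific choices from a designated baseline class —
  random points, k-means centroids, points nearest the class median, or
  points near the sample ("close").
- **Significance**: features (or *meta-features* — groups of |r| ≥ 0.8
  correlated features whose attributions are summed) are called significant
  for a class when their absolute attributions on the class exceed those on
  a similarly sized random event set, by a one-sided Welch t-test with
  Bonferroni correction.
- **Evaluation**: hypergeometric enrichment of reported features against a
  known feature set, and predictive-power curves retraining classifiers on
  increasing feature subsets.
- **Motif maps**: positional 3-mer frequency tracks around cassette-exon
  splice sites, sliding-window Fisher tests between regulated and
  non-regulated event sets, and PAR-CLIP crosslink-tag proximity enrichment.

Integrals are evaluated with the trapezoidal rule over discretised paths
(250 points by default) and every attribution carries a completeness
diagnostic |Σⱼ attr_j − (F(x) − F(x′))|.

Seeded synthetic generators (tabular data with correlated feature blocks
and planted discriminative features, digit-like images, splice-region
sequences with planted motifs) provide ground truth, so the whole pipeline
is testable offline.

## Worked example

Generate two-class data with 5 planted discriminative features among 40,
train the reference autoencoder + predictor, and test which meta-features
distinguish class B from median-of-class-A baselines along latent-linear
paths:

```r
library(eigrad)

d <- synth_tabular(n = 200, p = 40, n_informative = 5, seed = 7)
models <- train_reference_models(d$features, d$labels, seed = 7)

XA <- d$features[d$labels == "A", ]
XB <- d$features[d$labels == "B", ]
bl <- median_baseline(XA, m = 3)

attr_B <- class_attributions(models$model, XB[1:50, ], bl,
                             list(kind = "H-L", n_steps = 250,
                                  codec = models$codec))
attr_B
#> Attributions: 50 samples x 40 features [path H-L, baseline median]
#>   worst completeness gap: 0.07424

idx <- sample_random_set(nrow(d$features), 50, seed = 8)
attr_R <- class_attributions(models$model, d$features[idx, ], bl,
                             list(kind = "H-L", n_steps = 250,
                                  codec = models$codec))

map <- build_meta_features(d$features, threshold = 0.8)
sig <- significance_test(meta_attributions(attr_B, map),
                         meta_attributions(attr_R, map), fwer = 0.05)
sig
#> Significance over 40 meta-features (Bonferroni, FWER 0.05): 7 significant
#>  meta_feature mean_abs_G mean_abs_R    t        p    p_adj significant
#>           MF9      8.090      4.753 5.20 7.94e-07 3.18e-05        TRUE
#>          MF13      4.237      2.477 4.86 2.77e-06 1.11e-04        TRUE
#>           MF5      3.909      2.454 4.29 2.28e-05 9.14e-04        TRUE
#>          MF17      6.677      4.106 4.01 6.79e-05 2.72e-03        TRUE
#>          MF12      1.652      0.938 3.62 2.36e-04 9.45e-03        TRUE
#>           MF1      4.627      2.823 3.28 7.27e-04 2.91e-02        TRUE
#>          MF11      0.871      0.519 3.14 1.13e-03 4.53e-02        TRUE
```

`mean_abs_G` / `mean_abs_R` are the mean absolute meta-attributions on the
class of interest and on the random set; the top calls MF1, MF5, MF9, MF13
and MF17 are exactly the meta-features containing the five planted features
(`d$truth$informative` is `f1 f5 f9 f13 f17`), with two weaker extra calls.
The worst completeness gap (0.074 against logit differences of ~8) shows the
250-point quadrature is accurate to about 1%.

`run_pipeline()` wires the full chain (generate → train → attribute → test →
enrich → evaluate) from a validated `run_config()`; `run_motifmap()` does
the same for the sequence analyses. A thin command-line wrapper over these
lives in `inst/cli/eig.R`.

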