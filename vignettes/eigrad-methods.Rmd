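---
title: "Path-based attribution with eigrad: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based attribution with eigrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The attribution model

`eigrad` explains a scalar differentiable predictor $F:\mathbb{R}^p\to\mathbb{R}$
by distributing the prediction difference $F(x)-F(x')$ between a sample $x$
and a reference point $x'$ over the $p$ input features. The attribution of
feature $j$ is the line integral of $\partial F/\partial x_j$ along a path
$\gamma$ from $x'$ to $x$:

$$\mathrm{attr}_j(x) \;=\; \int_0^1
  \frac{\partial F(\gamma(\alpha))}{\partial \gamma_j(\alpha)}\,
  \frac{\partial \gamma_j(\alpha)}{\partial \alpha}\, d\alpha .$$

By the gradient theorem the attributions of any path sum to
$F(x)-F(x')$ (*completeness*), so the only modelling freedom is in the path
and the reference — and those two choices are the substance of the package.

Straight-line paths in feature space can cross regions far from any
training data, where a flexible model's gradients are unconstrained. Two
families of nonlinear paths keep the trajectory near the data:

* **Latent-linear (H-L)**: with an encoder/decoder pair
  $(\mathcal{E},\mathcal{D})$, walk the straight line between
  $z'=\mathcal{E}(x')$ and $z=\mathcal{E}(x)$ and decode it. Because
  reconstruction is imperfect, short linear bridges connect $x'$ to
  $\mathcal{D}(z')$ and $\mathcal{D}(z)$ to $x$, so endpoints are exact and
  completeness is preserved.
* **Neighbor paths (O-N / H-N)**: build the $k$-nearest-neighbor graph of
  the training points (in feature or latent space), attach $x'$ and $x$ to
  their $k$ nearest nodes, take the minimum-total-distance waypoint
  sequence (Dijkstra), and interpolate linearly between waypoints. Latent
  waypoint polylines are decoded and bridged like H-L paths.

References may be *group-agnostic* — the zero vector, or the decoded zero
latent vector, which for a codec trained on roughly centred data sits near
the training mean — or *group-specific*, drawn from a designated baseline
class: random members, $k$-means centroids, the members nearest the
coordinate-wise median (robust to outliers), or the members nearest the
sample itself (``close``, which discards the single nearest point as an
outlier guard and emphasises minimal distinguishing features).

## From attributions to significant features

Per-sample attributions do not answer the question practitioners ask —
*which features characterise this class?* The test implemented here
compares, for each feature, the absolute attributions over the class of
interest ($Set_G$) with those over a similarly sized random draw from all
classes ($Set_R$), using a one-sided Welch $t$-test for
$\mathrm{mean}(Set_G) > \mathrm{mean}(Set_R)$ and Bonferroni correction
over the number of tests. Correlated features (for instance several
variants of one RNA-binding-protein motif) are first merged into
*meta-features* by single-linkage grouping at $|r|\ge 0.8$, and a
meta-feature's attribution is the sum of its members' signed attributions —
summing before taking absolute values avoids inflating large groups.

Choices worth making explicit:

* **Welch, not pooled-variance**: the class set and the random set have no
  reason to share a variance.
* **FWER default 0.05** (configurable): a stricter 0.01 is equally
  defensible; 0.05 is what the package's own evaluation figures use.
* **Absolute value of the summed attribution** at test time; a
  rank-transform variant (`rank_transform = TRUE`) tests pooled ranks
  instead.
* **Random-set size** defaults to the size of the class of interest.

## The reference models

The attribution machinery only needs `evaluate` and `gradient`, so any
differentiable model can be wrapped with `prediction_function()` (an
analytic gradient if available, otherwise central finite differences with
step $10^{-5}\max(1,|x_j|)$). For self-contained experiments the package
trains its own small reference pair in base R: a tanh autoencoder
($p \to h \to q \to h \to p$, mean-squared reconstruction loss, full-batch
Adam) and a classifier head on the frozen encoder, so both the original and
the latent space of one model are available for path construction.

Two architecture decisions matter more than the layer sizes:

* **The attribution target is the pre-sigmoid logit.** Probability-scale
  gradients vanish in the sigmoid's tails and peak near the decision
  boundary. A path from a baseline-class reference to a class-of-interest
  sample crosses that steep region, while a path to a baseline-class sample
  does not; attributing the probability therefore inflates the absolute
  attribution of *every* feature — informative or not — for exactly the
  samples entering $Set_G$, which degrades the specificity of the
  significance test. The logit has no such saturation asymmetry.
* **The latent bottleneck is narrow by default** ($q \approx \sqrt{p}$).
  Beyond its role in path construction, the bottleneck is the model's main
  regularizer: with a wide latent space the head can load on idiosyncratic
  noise directions, and attributions then spread onto uninformative
  features. `nn_train()` also exposes decoupled weight decay for the same
  purpose, off by default.

The exact architectures of the splicing and digit models this framework is
aimed at are not reproduced; the contract that matters — a frozen encoder
feeding a prediction head, giving a differentiable map in both spaces — is.

Embedding robustness is a precondition for trusting latent paths:
`latent_stability()` computes the Spearman rank correlation of pairwise
latent distances across codecs trained with different seeds or
architectures, which should sit near 1 for stable embeddings.

## Numerical choices

* **Quadrature**: per-segment trapezoid in feature space — the gradient
  dotted with coordinate increments — which absorbs the
  $\partial\gamma_j/\partial\alpha$ term and is exact for linear models on
  any polyline. The default 250 path points gives completeness gaps well
  below 1% of $|F(x)-F(x')|$ on the smooth reference models; `refine_until()`
  doubles the resolution from 50 until both the completeness gap and the
  step-halving change drop below a relative tolerance.
* **Point allocation on polylines** is proportional to segment length with
  at least one point per positive-length segment (largest-remainder
  rounding), keeping integration error roughly uniform per unit length.
  Zero-length segments are dropped so the arc-length parameter is strictly
  increasing; a degenerate path ($x=x'$) keeps a uniform grid and yields
  zero attributions.
* **Path α** is normalized cumulative arc length, reported for export and
  plotting; the integral itself never needs it explicitly.
* **Ties** (equidistant baseline candidates, equal-length allocations) are
  broken by stable input order, so every result is bit-reproducible under a
  fixed seed.
* **k-NN graphs** default to $k=10$, Euclidean distance; duplicate points
  produce zero-weight edges, and a disconnected endpoint raises an error
  suggesting a larger $k$ rather than silently falling back to a straight
  line.
* **Exact tests**: hypergeometric tails and Fisher's exact test come from
  `stats::phyper` / `stats::fisher.test`; the test suite verifies both
  against direct binomial-coefficient summation at $10^{-12}$.

## Sequence analyses

The motif-map module works on splice-site-anchored regions (upstream-intron
end, cassette exon, downstream-intron start; RNA alphabet, T mapped to U).
Event sets are defined from junction ΔΨ values in percent: *regulated*
events need both an inclusion and an exclusion junction at $|\Delta\Psi|\ge
10$, split by the sign of the strongest inclusion junction; *non-regulated*
events have all junctions below 5; events between the thresholds stay
unassigned. Per-position motif frequencies count events with a motif
*starting* at the position (overlapping occurrences included), divided by
the events whose sequence covers it. Tracks are smoothed with a centred
20-nt running mean, truncated at the boundaries (no padding). Enrichment
between event sets uses Fisher's exact test on presence/absence within
20-nt windows at stride 1, reported two-tailed at $p<0.05$ without
multiple-testing correction across windows — the windows overlap and the
display is a positional map, not a discovery list. Crosslink-tag proximity
keeps transition sites with $\ge 2$ unique tags and calls an event bound if
a retained site falls within 300 nt upstream, the exon, or 300 nt
downstream (0-based half-open intervals).

The splicing-code target transforms are provided for completeness:
$T_\Psi = E[\Psi]$, $T_{\Delta\Psi,inc} = |\max(\epsilon, E[\Delta\Psi])|$,
$T_{\Delta\Psi,exc} = |\min(\epsilon, E[\Delta\Psi])|$ with $\epsilon$
uniform on $[0.01, 0.03]$, giving non-changing events small targets instead
of exact zeros. Note the asymmetry: for $E[\Delta\Psi]=0$ the inclusion
target is $\epsilon$ but the exclusion target is exactly 0 — that is what
the formulas say, and the package follows them.

## What the synthetic generators do and do not emulate

* `synth_tabular()` builds features from shared block factors
  ($x = \sigma(\sqrt{r}\,f_{block} + \sqrt{1-r}\,\varepsilon)$), which
  guarantees a positive-definite correlation structure at any $p$ and gives
  `build_meta_features()` real blocks to find; informative features (one
  per block while blocks last) are mean-shifted between classes. Defaults —
  $n=400$, $p=200$, 10 informative features, shift $3\sigma$, blocks of 4
  at $r=0.6$ — describe a clearly detectable but not trivial signal, the
  regime where comparing attribution methods is informative.
* `synth_images()` renders one stroke pattern per class plus Bernoulli flip
  noise; flip noise (rather than Gaussian) keeps pixels binary and makes
  the ground-truth mask exactly the symmetric difference of the patterns.
* `synth_sequences()` draws i.i.d. background nucleotides and plants one
  motif per selected event uniformly inside a positional window
  (default: rate 0.5 inside positions 180–220 of the downstream intron,
  mirroring the positional-enrichment signature the motif map is meant to
  detect), with matching synthetic crosslink tags.

What passing tests on these generators show: the integrator, paths,
baselines, test statistics and sequence scans behave as specified, and the
full pipeline recovers planted signal with controlled false calls under
known conditions. What they do not show: performance on real splicing
features, whose correlation structure is far from block-diagonal, whose
"truth" is unknown, and whose models are orders of magnitude larger. In
particular the planted-truth false-positive count conflates test
specificity with model quality — a model that genuinely overfits noise
features earns those features genuine attributions, and the test correctly
reports them; only the planted truth calls them false.

## A calibration caveat

Under the null (class set and random set exchangeable), each meta-feature's
one-sided $p$-value is marginally uniform, and on independent null features
the whole $p$-vector passes a Kolmogorov–Smirnov uniformity check. After
running data through a neural model, however, input gradients lie in the
column space of the first weight layer, so attribution columns — and hence
the 500 $p$-values of a null experiment — are strongly cross-correlated. A
joint KS test over correlated $p$-values rejects sporadically even when
every marginal is uniform. The package's null checks therefore assert KS
uniformity for the test applied to independent null features, and for the
model-based null assert the dependence-robust summary: zero Bonferroni
discoveries.

## Known limitations

* Neighbor paths cost one shortest-path search per sample/baseline pair and
  a $O(n^2)$ distance matrix for graph construction; they are meant for
  reference sets of at most a few thousand points.
* The reference networks are deliberately small, full-batch, and CPU-bound;
  they are contracts-plus-fixtures, not a deep-learning framework.
* Baselines are selected in the original feature space only.
* Multi-baseline attributions are combined by unweighted averaging before
  testing; pooling sample-baseline pairs into the test is a plausible
  alternative the current implementation does not expose.
* The problem sizes exercised throughout the tests (hundreds of samples,
  hundreds of features, 200 events per sequence arm) were chosen as the
  smallest at which every statistical property is comfortably measurable.
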