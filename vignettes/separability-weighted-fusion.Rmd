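---
title: "Separability-weighted ensemble fusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separability-weighted ensemble fusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elcdr)
```

## The problem

Crop leaf disease recognition is a multi-class image classification task in
which no single convolutional backbone wins everywhere: a network that
extracts good features for apple scab against a plain background may extract
poor ones for rice blast photographed in the field. Ensembling several
trained classifiers helps, but the two traditional fusion rules treat all
members as equals. Majority voting gives every model one vote and breaks
down entirely when all members disagree — no class reaches a plurality and
the vote is *invalid* for that image. Average weighting fuses the softmax
outputs with uniform weights $1/n$, so a model with weak features dilutes
the confident ones.

This package implements an alternative: weight each member by how well its
feature embedding separates the classes, measured on the training set alone,
and fuse softmax outputs by those weights. No retraining, no held-out
validation split, and no access to the networks themselves is needed — only
two tables per model (training feature vectors and evaluation softmax rows),
which any framework can export.

## The separability score and the fusion rule

Let model $g$ embed the $t$ training images, labeled with $k \ge 2$ classes,
as vectors $x_i \in \mathbb{R}^d$ (in the original setting these are
pooling-layer activations). Write $c_p$ for the centroid — the arithmetic
mean — of class $p$'s vectors. Two scalars summarize the geometry:

* the **in-category distance**, the mean distance of every vector to its own
  class centroid,
  $$\mathrm{icD} = \frac{1}{t}\sum_{p=1}^{k}\sum_{i \,:\, y_i = p}
    \lVert x_i - c_p \rVert_2 ,$$
* the **between-categories distance**, the mean distance over all
  $\binom{k}{2}$ unordered centroid pairs,
  $$\mathrm{bcD} = \binom{k}{2}^{-1} \sum_{p < q}
    \lVert c_p - c_q \rVert_2 .$$

The **feature-extraction performance** of model $g$ is the ratio

$$\mathrm{FEP}_g = \mathrm{bcD}_g / \mathrm{icD}_g,$$

large when clusters are tight and far apart — a Fisher-style separability
criterion built from centroid distances. Ensemble weights normalize the
scores,

$$w_g = \mathrm{FEP}_g \Big/ \sum_{i=1}^{n} \mathrm{FEP}_i,$$

and a new image's fused softmax row is $sf_{\mathrm{final}} = \sum_g w_g \,
sf_g$, with the predicted class its argmax. `elcdr()` computes the weights
from a list of labeled feature tables; `predict()` on the fit performs the
fusion. `fuse_average()` and `fuse_voting()` provide the two baselines, the
latter recording the sentinel `INVALID` when no strict plurality exists.

Because every row of every member table sums to one and the weights sum to
one, the fused row sums to one; this conservation, the equivalence of
average fusion with uniform weighted fusion, and the agreement of all three
strategies on unanimous samples are asserted as properties in the test
suite.

### Properties of the score

FEP is a pure shape statistic: it is invariant under any rigid transform of
the embedding (rotation and translation move centroids and vectors
together) and under uniform positive rescaling (both distances scale by the
same factor). It is *not* invariant under anisotropic rescaling or
per-feature normalization, which genuinely change the cluster geometry. No
normalization is applied to input vectors by default, and none was assumed
in the statistics this package desk-checks against.

A consequence worth noting when interpreting weights: FEP compares models
through their own embeddings, whose overall scales differ, but the ratio
form removes exactly that scale, which is what makes cross-model comparison
meaningful at all.

## Choices where the definitions are open

* **Centroid = mean.** The centroid is implemented as the class mean. A raw
  per-class sum would grow with class size, break the scale covariance of
  icD/bcD, and contradict the notion of a centroid; the mean is the only
  reading consistent with the reference statistics' magnitudes.
* **Argmax ties** are broken toward the lowest class index, deterministically.
* **Voting invalidity** is generalized from the three-model all-disagree case
  to "no strict plurality": whenever the top vote count is shared by two or
  more classes, the sample is `INVALID`. For scoring, `INVALID` counts as an
  incorrect prediction. `fuse_voting(..., fallback = "average")` (CLI flag
  `--voting-fallback average`) instead resolves such samples by average
  fusion.
* **Metric averaging.** `classification_metrics()` reports accuracy,
  precision, recall and F1 as percentages. Precision and recall are **macro**
  averages by default — each class weighted equally — which makes recall
  coincide with accuracy on class-balanced test sets, the behavior the
  reference results exhibit. F1 is the harmonic mean of the reported
  precision/recall pair. Micro and truth-frequency-weighted averaging are
  available via the `average` argument. Classes never predicted contribute
  precision 0; `INVALID` predictions sit in a dedicated confusion-matrix
  column, are never correct, and are excluded from real classes' precision
  denominators.
* **Degenerate geometry.** If every vector coincides with its class centroid,
  icD is zero and the ratio is undefined. This raises an error rather than
  silently producing an infinite weight. Numerically, a collapsed cluster
  yields icD at rounding level (~$10^{-16}$) rather than an exact zero, so
  the guard fires when $\mathrm{icD} < 10^{-12}\,\mathrm{bcD}$ — a threshold
  twelve orders of magnitude below any realistic embedding's ratio. Passing
  `icd_epsilon` (CLI `--icd-epsilon`) clamps icD from below instead, for
  pipelines that must proceed.
* **Input hygiene.** Softmax rows must sum to 1 within $10^{-6}$; offending
  rows are rejected, not silently fixed, unless `renormalize` is requested.

## The synthetic-data generator

The package must be exercisable without images or GPU training, so
`generate_ensemble()` simulates the whole multi-model setting. Each
simulated model's embedding is a set of $k$ isotropic Gaussian clusters:
class means are placed along random mutually orthogonal unit directions
(random unit directions when $d < k$, so any dimension works) scaled by a
per-model `separation`, and samples are drawn with standard deviation
`spread` per coordinate. Train and evaluation splits are fresh draws from
the same means — per-class counts stay exact — and the evaluation samples
share identifiers and true labels across models, each model seeing them
through its own embedding.

The simulated classifier head is a centroid-distance softmax
(`simulate_softmax()`): $p_j \propto \exp(-\lVert x - c_j \rVert /
\tau)$. This choice is deliberate: it hard-wires the premise under test,
that geometric separability and classification quality co-vary, so that a
model given a larger `separation` is both more separable *and* more
accurate. Passing tests therefore demonstrate that the estimator recovers
separability orderings and that separability-weighted fusion beats voting
*when the premise holds*; they cannot show that pooling-layer embeddings of
real CNNs satisfy the premise — that is an empirical claim about real data,
outside what synthetic fixtures can establish. Real embeddings are also not
isotropic Gaussians: they have anisotropic, class-dependent covariance and
nonconvex class regions, none of which the generator emulates.

Default study conditions — used by the test suite and the acceptance script —
are $k = 4$ classes, $d = 16$ dimensions, 50 training and 50 evaluation
samples per class, three models with separations $(6, 3, 1)$ at `spread` 1
and temperature $\tau = 1$. The trio mirrors a strong / middling / weak
backbone; separation 6 at unit spread gives near-perfect single-model
accuracy, separation 1 a model in the 70–80% range whose disagreements
generate invalid votes. With these sizes a replicate runs in well under a
second, and 20 seeded replicates recover the separation ordering of the
weights essentially always (the suite requires at least 19 of 20). All
generation is bit-reproducible: a configuration plus seed determines every
file byte, the caller's RNG stream is left untouched, and data files carry
no timestamps (the run manifest carries the only one).

## Numerical notes

* Distances use exact Euclidean norms; the centroid-distance softmax
  subtracts the row maximum before exponentiation (log-sum-exp guard).
* Desk checks against the reference per-crop statistics for VGG11, ResNet18
  and MobileNet_v3 (see `separability_reference()`) reconstruct, for each
  printed (icD, bcD) pair, a four-point one-dimensional geometry whose icD
  and bcD equal those values exactly, then let the package recompute FEP and
  the weights; agreement is required to $5 \times 10^{-6}$ relative — the
  values are printed to six significant figures.
* Weight vectors are validated to sum to 1 within $10^{-9}$; fused rows
  within $10^{-6}$ of the inputs' tolerance.

## A worked run

```{r worked}
ens <- generate_ensemble(synth_config(seed = 7))
fit <- elcdr(ens$train)
fit

pred <- predict(fit, ens$softmax)
vote <- fuse_voting(unname(ens$softmax))
cm <- confusion_matrix(ens$truth, vote$predicted, ens$class_ids)
m <- classification_metrics(cm)
c(elcdr = mean(pred$predicted == ens$truth) * 100,
  voting = m$accuracy, invalid = m$invalid_count)
```

The strong model (separation 6) takes the dominant weight, and voting loses
the samples its disagreeing members render invalid.

## Limitations

* The weights are only as good as the premise that training-set
  separability predicts test-time quality; a model that overfits its
  embedding to the training set earns an undeserved weight. Nothing in the
  score looks at held-out data.
* FEP summarizes each class by one centroid; multi-modal classes or heavily
  anisotropic clusters can separate well in a nearest-neighbor sense while
  scoring poorly, and vice versa.
* The fusion is a fixed linear rule; no stacking, calibration or per-class
  weighting is attempted (deliberately out of scope).
* Feature extraction itself is out of scope: the package consumes exported
  tables and never loads a network.
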