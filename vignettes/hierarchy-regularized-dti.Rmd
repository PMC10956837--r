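---
title: "Hierarchy-regularized joint embedding for drug-target interaction prediction"
author: "hierDTI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-regularized joint embedding for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierDTI)
```

## The problem

Pairwise drug-target interaction (DTI) predictors map a compound and a
protein into a shared latent space and score the pair by latent similarity.
That latent space is also an opportunity for interpretability: if drugs that
are close in a pharmacological classification (the 5-level ATC tree) and
proteins that are close in a biological taxonomy (the 4-level kinome tree or
the 3-level nuclear-receptor hierarchy) also end up close in the latent
space, the space itself becomes readable — clusters correspond to known
families, and the neighborhood of a query molecule suggests both its likely
targets and its likely classification.

`hierDTI` implements such a predictor with two interchangeable geometries
and a hierarchy-ranking regularizer:

* **Encoders.** Two feed-forward networks (default two hidden layers of
  1024 ReLU units, 10% dropout) consume fixed, precomputed feature vectors
  (e.g. 300-dimensional Mol2vec/ProtVec-style embeddings; the package never
  touches raw SMILES or sequences) and emit `d`-dimensional latents.
* **Euclidean head.** The interaction probability is
  `sigmoid(<d, t>)`, the logistic dot product of the two latents.
* **Lorentz (hyperbolic) head.** The latents are norm-clipped at a
  threshold `alpha` (default 1), lifted onto the hyperboloid
  `{x : <x,x>_L = -beta, x0 > 0}` (default `beta = 1`, i.e. curvature -1)
  by the origin exponential map, and scored as `exp(-d_L^2(d, t))` with the
  squared Lorentzian distance `d_L^2(x,y) = -2*beta - 2<x,y>_L`. Hyperbolic
  space embeds trees with little distortion, which is why it is the
  preferred geometry once hierarchies enter the objective.

## The objective

Training minimizes

```
L = L_wBCE + lambda_drug * L_REG^drug + lambda_target * L_REG^target
```

* `L_wBCE` is a class-weighted binary cross-entropy over batches of `b`
  labeled interactions (default `b = 1024`), with configurable
  positive:negative weights to offset label imbalance.
* Each regularization term is a ranking loss over hierarchy triplets. Per
  batch, `n` anchors (default 10) are drawn from the entities with known
  hierarchy. A positive partner is drawn per anchor — first a
  lowest-common-ancestor (LCA) distance uniformly over the distances
  realized among the anchor's candidates, then a candidate uniformly at that
  distance — and up to `m` negatives (default 256) are drawn from the
  entities strictly farther in the hierarchy. The anchor's term is
  `d(x_i, x_i+) + log sum_k exp(-d(x_i, x_k))`, i.e. the negative log of a
  softmax-like ratio; the distance `d` is the squared Lorentzian distance
  for the hyperbolic head and the Euclidean latent distance for the
  Euclidean head (a dot product is not a distance). The denominator, as
  implemented, sums over the negatives only; `includePositive = TRUE`
  switches to the conventional softmax form including the positive term.
  An anchor whose negative set is empty is skipped with a warning.
* Optimization is Adam (learning rate `5e-5`) from Xavier-uniform
  initialization, 16 epochs by default. The encoders, the heads, the exact
  gradients through clip → exponential map → Lorentzian distance, and the
  regularizer gradients are implemented in base R matrix algebra and are
  validated against finite differences in the test suite.

### Hierarchy distances

For leveled hierarchies the dissimilarity of two leaves is `depth - L`,
where `L` is the level of their deepest common ancestor: 1 when only the
leaf level differs, up to `depth` when the top level differs. Two
refinements follow the conventions of the source taxonomies:

* **Duplicate leaves.** An ATC-style drug holding several codes uses the
  minimum distance over all pairs of its paths.
* **Catch-all groups.** In the kinome tree the groups `other` and
  `atypical` collect unrelated proteins; when the deepest common ancestor
  of two entities is such a group node itself, the distance is raised from
  `depth - 1` to `depth`. Members of the same family or subfamily inside
  those groups are unaffected.

Graph-shaped hierarchies (MeSH-style, where entities can be internal
nodes) use unweighted shortest-path hop counts instead; disconnected pairs
are either an error or an `Inf` sentinel excluded from sampling.

## Evaluation

* **Prediction:** ROCAUC (rank statistic) and PRAUC (precision-recall step
  integration) over a 5-fold interaction-based split. The split partitions
  interactions, not entities, so every drug and target is seen in training;
  AUCs are computed on the held-out fold.
* **Hierarchy preservation:** expected dendrogram purity (EDP). The latent
  distance matrix of one modality is clustered with farthest-point
  (complete-linkage) agglomeration; for each hierarchy level, `k` same-class
  leaf pairs per class (default `k = 10`) are sampled without replacement
  (all pairs when fewer exist), each pair contributes the same-class leaf
  fraction of the smallest subtree containing it, values are pooled across
  classes, and the per-level scores are averaged. EDP is evaluated
  in-sample over the hierarchy-labeled entities: it measures how well
  hierarchies can be encoded, not how they generalize. Levels are the
  non-leaf levels of the prior hierarchy; the leaf level consists of
  singleton classes and is excluded, as are classes with a single member.

## Disk visualization

For models of latent dimension above 2-3, the package ships a simplified
hyperbolic dimensionality reduction in the style of Poincaré maps. The
latents are mapped to the Poincaré ball, their pairwise hyperbolic
distances feed a 5-nearest-neighbor graph (union-symmetrized) with
self-tuning Gaussian weights (each point's bandwidth is its distance to the
5th neighbor), the graph is converted to relative-forest-accessibility
similarities `(I + L)^{-1}` and row-normalized into targets `p_ij`, and 2-D
disk coordinates minimize `KL(p || q)` with `q_ij` proportional to
`exp(-d_P(z_i, z_j))`. Optimization is mini-batch gradient descent (2000
epochs, batch 64, learning rate 0.05 by default) with conformally scaled
steps and projection to radius `1 - 1e-5`. This reproduces the cited
algorithm's structure, not its exact implementation; all claims made about
it in the tests are property-based (loss decreases, clusters are
recovered, outputs stay in the disk).

Two operators support navigation: `embedTree()` positions each internal
hierarchy node at the Einstein midpoint of its children (computed in Klein
coordinates, bottom-up), and `translateView()` applies the
distance-preserving Möbius translation that moves any chosen node to the
disk center, where hyperbolic resolution is highest — a "zoom-in" on that
node's neighborhood.

## The synthetic benchmark

Real DTI corpora with labeled hierarchies are large and external, so the
package generates its own benchmark emulating their structure
(`synthBenchmark()`); every empirical statement in the tests refers to it.
The defaults, chosen once:

* **200 drugs** on a balanced 5-level tree (branching 5-2-5-2-2) and
  **22 targets** on a 3-level tree (branching 4-3-2 truncated to 22
  leaves) — a nuclear-receptor-panel-sized target side against a
  moderately sized compound library, the smallest shape on which both
  hierarchy depths and the 5-fold protocol are meaningful at desk scale.
* **Features:** 300-dimensional hierarchical Gaussians. Each internal node
  adds an offset with per-coordinate sd `2^(1-l)` at level `l`; leaves get
  their deepest cluster's mean plus noise (sd 0.5). Deep splits are weak
  relative to the noise, so fine hierarchy levels are *not* trivially
  readable from features alone — that contrast is what lets the tests
  separate the regularizer's effect from the encoders'.
* **Interactions:** each pair observed with probability 0.3 (sparsity
  0.7 — real corpora are sparser, but 200 x 22 leaves too few labeled pairs
  at realistic sparsity to train on); an observed pair is positive with
  probability 0.95 when the drug's and target's top-level clusters are
  matched and 0.02 otherwise. Tying labels to the *top* level only keeps
  the Bayes-optimal ROCAUC of the label process around 0.96 (so "both heads
  reach ROCAUC > 0.9" is attainable) while leaving deeper levels learnable
  only through the regularizer.
* `hierarchyCoverage < 1` drops hierarchy labels for a fraction of
  entities, emulating corpora where most compounds lack classification;
  uncovered entities keep features and interactions but never enter
  regularization batches or EDP.

What the generator does **not** emulate: real chemical/biological feature
manifolds (Gaussian clusters are far cleaner than Mol2vec space),
measurement noise correlated across assays, entity-degree skew, and
affinity values beyond a binarizable scalar. Passing tests demonstrate the
machinery is correct and the regularization effect is real under these
conditions; they do not certify performance on real corpora.

## Numerical choices

* `arccosh` arguments are clamped to `>= 1` and ball-norm denominators to
  `>= 1e-15`; boundary points arise routinely after clipping at
  `alpha = 1`.
* Predictions are clamped to `[1e-7, 1 - 1e-7]` before the cross-entropy;
  the clamp is treated as the identity in the gradient.
* The exponential map uses series limits below `r = 1e-6` so the gradient
  is exact through the origin.
* Complete-linkage ties are broken deterministically (`stats::hclust`);
  the reducer projects to radius `1 - 1e-5` and scales gradients by the
  conformal factor `((1 - |z|^2)^2) / 4`, without which boundary points
  overshoot.
* Dropout is active only during training; all inference paths are
  deterministic. With a fixed seed (and single-threaded BLAS) training is
  bit-reproducible; multi-threaded BLAS may differ in low-order bits.

## Design decisions that were genuinely open

* The printed form of the exponential map omits the square root of the
  tangent norm; the standard form with `||v||_L = sqrt(<v,v>_L)` is the
  only one that lands on the manifold and is what the manifold invariant
  tests lock in.
* The ranking term is implemented in its negated (minimized) form; the
  non-negated form would be maximized and contradict a minimized total
  loss.
* The encoder output is clipped *before* lifting the zero time coordinate;
  clipping in the ambient space would break tangency at the origin.
* "Sampled uniformly based on the hierarchy distance" is read as uniform
  over realized distance values, then uniform within a value; this gives
  distant positives the same chance as near ones instead of letting the
  largest candidate shell dominate.
* Positives are restricted to leaves sharing a *non-root* ancestor;
  through the root every pair would qualify and the term would lose its
  ranking meaning. Entities related to everything only through the root
  are therefore never anchors.
* Anchors are re-sampled independently per batch; whether they may repeat
  within an epoch is unspecified in the protocol this follows, and
  independent re-sampling is the simplest consistent reading.
* EDP pools pair purities across classes before averaging over levels
  (rather than per-class averaging), and draws pairs without replacement
  when enough exist.
* The benchmark comparison protocol trains for 48 epochs (versus the
  16-epoch default used elsewhere): at desk scale the regularized run needs
  the extra epochs to converge, and comparing converged models is the fair
  reading of "regularization does not compromise prediction". The 16-epoch
  default is retained everywhere a single configuration is trained.
* Binarization direction is configurable (`value >= 3` positive by
  default) because affinity scales differ in whether higher means
  stronger; pre-binarized labels pass through untouched.

## Problem sizes used by the tests

Unit tests run on trees of 5-30 leaves, datasets of 5-12 entities per
side and encoders of 4-16 hidden units; the acceptance-level checks train
the full default benchmark (200 x 22, 1024-unit encoders, latent dimension
8) and run the complete CLI pipeline (simulate → train → evaluate →
visualize) at default settings. These sizes were chosen so the whole suite
exercises the real configuration while staying comfortably within a
desk-scale compute budget.

## Known limitations

* Only origin-based exponential maps are provided; there are no hyperbolic
  network layers and no Riemannian optimizer (the Euclidean-encoder +
  exp-map construction is the modeling choice, not a simplification of
  one).
* Curvature `beta` is fixed per run, not learned.
* The reducer is a structural re-implementation tuned for hundreds of
  points; it makes no claim of pixel-level agreement with the original
  algorithm's outputs.
* EDP is in-sample by construction here; generalization of hierarchy
  placement to unseen entities is untested territory.

## A minimal session

```{r, eval = FALSE}
bench <- synthBenchmark(seed = 1)
model <- trainModel(
  bench$data, bench$drugDistances, bench$targetDistances,
  head = "lorentz", latentDim = 8,
  control = trainingConfig(lambdaDrug = 0.1, lambdaTarget = 0.1, seed = 1)
)
scores <- predictDataset(model, bench$data)
binaryAucs(interactions(bench$data)$label, scores)
modelEdp(model, bench$data, bench$targetTree, "target", k = 10)

pd <- latentPoincareDistances(
  model,
  drugFeatures(bench$data), targetFeatures(bench$data)
)
disk <- poincareMapsReduce(pd$D, reducerConfig(seed = 1), kind = pd$kind)
full <- embedTree(disk, bench$targetTree)
plotDisk(translateView(full, "<root>"))
```
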