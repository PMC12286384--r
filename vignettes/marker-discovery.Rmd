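---
title: "Row-sparse autoencoder marker discovery: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Row-sparse autoencoder marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseae)
```

## The problem

Bulk transcriptomes of breast tumours span tens of thousands of genes, yet
the clinically used subtypes — triple-negative (TNBC), HER2-enriched,
luminal A and luminal B, defined by ER/PR/HER2 receptor status — are driven
by far smaller gene programs. `sparseae` implements a marker-discovery
pipeline built around a shallow autoencoder whose encoder weights carry an
ℓ2,1 (row-sparsity) penalty. Trained on the expression matrix of a single
subtype, the network must reconstruct every gene's expression through a
narrow bottleneck; the Euclidean norm of encoder row *i* then measures how
much gene *i* contributes to the learned representation, and the top-scoring
genes are candidate markers of that subtype.

## Model

For a class matrix $X \in \mathbb{R}^{n_v \times d}$ (samples × genes,
min–max scaled per gene to $[0,1]$), the network is

$$\hat X = \mathrm{ReLU}(\mathrm{ReLU}(X W^{(1)})\, W^{(2)}),$$

with $W^{(1)} \in \mathbb{R}^{d \times h}$, $W^{(2)} \in
\mathbb{R}^{h \times d}$ and $h \ll d$. The training objective is

$$J(\Theta) = \frac{1}{2 n_v}\,\lVert X - \hat X\rVert_F^2 +
  \lambda\,\lVert W^{(1)}\rVert_{2,1},
  \qquad
  \lVert W\rVert_{2,1} = \sum_i \lVert w_i \rVert_2 .$$

Penalising the sum of encoder-row norms drives whole rows toward zero, so a
gene either earns its place in the representation or is dropped entirely.
The per-gene score is $s_i = \lVert w_i \rVert_2$. A `sum_of_squares`
penalty variant (the same quantity without the square root) is available;
it changes the objective but not the score *ranking*, which is what
selection uses.

Biases are off by default, matching the pure matrix-product definition
above; `use_bias = TRUE` enables them, and the small-cohort preset uses
them (see below). The ReLU subgradient at 0 is taken as 0.

Optimisation is mini-batch Adam (defaults: step 1e-3, β₁ = 0.9,
β₂ = 0.999, ε = 1e-7, batch 64). An internal validation split
(`val_fraction`, default 20%) is monitored every epoch and the weights of
the latest best model are checkpointed; `ae_train()` returns that
checkpoint, not the final epoch. On real cohorts the reference settings are
$h = 500$, 35 epochs, and λ of 1e-5 (TNBC), 1e-4 (HER2-enriched), 1e-6
(luminal A/B).

## Stability selection

A single training run is stochastic (initialisation, batch order, internal
split). The consensus protocol of `consensus_markers()` therefore:

1. seeds the generator once per *seed block* and runs
   `runs_per_seed` train → score → top-*k* cycles without reseeding, so
   replicate runs differ through the advancing generator state;
2. intersects the per-run top-*k* sets within each block;
3. intersects the block consensuses across `n_seeds` blocks.

Reference scale: 30 runs × 16 seeds with $k = 3000$. Reseeding *between*
runs would make all runs of a block identical and the intersection
uninformative, which is why the single-seeding reading is used. Strict
intersection is deliberately conservative: it keeps only genes selected in
*every* run, so the consensus is much smaller than $k$ and its size shrinks
(weakly) as runs or seeds are added.

## Validation by classification

Marker sets are validated by multiclass random-forest classification on the
union of the per-subtype marker sets, with an 80/20 stratified split.
Because receptor-labelled cohorts are imbalanced, trees are grown with
class-weighted Gini impurity, with weights inversely proportional to class
frequency, $w_v = n/(k\,n_v)$. `weighted_gini()` implements the literal
form $G_u = 1 - \sum_v w_v\, p_{u,v}^2$ (weight outside the squared
proportion); note this differs from the conventional reweighting of the
proportions themselves, which is what mature forest libraries implement.
`fit_rf()` therefore defaults to ranger's standard class-weighted impurity
and exposes `impurity = "eq6"`, a small bundled bagged-tree grower that uses
the literal form, practical for small marker panels. Hyperparameters are
chosen by 10-fold cross-validated grid search (depth {unlimited, 10, 20} ×
mtry {√p, log₂p} × leaf {1, 5} by default). Evaluation reports accuracy,
support-weighted precision/recall/F1, per-class one-vs-rest ROC curves with
trapezoidal AUC (via pROC), and the support-weighted mean AUC.

## Network modules

`build_graph()` induces a STRING-style interaction graph on a marker set,
keeping edges with confidence strictly above 0.7 (raw 0–1000 scores are
rescaled), dropping self-loops and keeping the maximum score of duplicate
edges. `mcl_cluster()` is a from-scratch Markov clustering: self-loops of
weight 1 are added, the adjacency is column-normalised, and expansion
(matrix squaring) alternates with inflation (elementwise power 2.5,
column renormalisation) and pruning (entries < 1e-5) until the flow matrix
changes by less than 1e-6 or 100 iterations pass (non-convergence returns
the current partition with a warning). Clusters are read off attractors;
a node joins the attractor holding the largest mass in its column, ties to
the lowest id. Modules with more than two genes are the reported ones.
Merging modules into functional "super-modules" is interpretive curation
and stays out of scope.

## The synthetic cohort generator

`simulate_expression()` generates the cohorts every stage is tested on,
emulating the salient features of an FPKM matrix:

* **Baseline**: gene $g$ has log-normal expression with
  $\mu_g \sim N(1.4, 0.4)$ and within-class log-sd 0.15. The log-normal
  matches the non-negative, right-skewed, zero-bounded character of FPKM
  (typical values a few units, upper quartiles near 7–8). The within-class
  spread is deliberately modest: it represents a relatively homogeneous
  subtype background against which planted effects are detectable at the
  small simulated sample sizes.
* **Classes**: four subtypes with imbalanced sizes 30/15/60/25, echoing the
  strong imbalance of receptor-labelled cohorts.
* **Markers**: each class has 50 class-exclusive marker genes. A marker is
  bimodally dysregulated in its class: each sample independently draws a
  log-shift of `effect_size` × 3 (probability ½) or `effect_size` × (−1),
  so the mean log-shift is exactly `effect_size` while the on/off split
  makes the marker *high-variance* within the class. This is the property
  the method detects: per-gene min–max scaling removes any purely
  multiplicative shift, so a marker that was only mean-shifted would be
  invisible to a within-class autoencoder. Marker strengths are tiered
  (multiplier graded 1.2 → 0.8, mean 1) to mimic panels that mix strong
  and moderate markers. With `effect_size = 0` markers follow the base
  distribution exactly, which gives the null cohort its meaning.
* **Zero inflation**: Bernoulli masking at 2% per entry by default
  (configurable per gene). After the 75%-zeros gene filter, expressed genes
  in real data are mostly detected; entries of exactly zero remain a
  distinctive feature the generator retains.
* **Outlier genes**: 10 genes receive a +4 baseline log-shift, placing
  their means far outside the band of the outlier filter so that stage has
  real work to do without clipping the markers themselves.

What the generator does **not** emulate: gene–gene correlation beyond the
planted markers, batch effects, library-size artefacts, heavy-tailed
technical noise, or marker programs shared across subtypes (an option
exists for overlapping marker blocks). Passing tests on this generator
shows the machinery is correct and the protocol recovers planted structure
under favourable, known conditions; it does not show that markers found on
a real cohort are biologically right.

## Small-cohort training preset

Training a 500→16→500 network on 15–60 samples is a different numerical
regime from the reference cohort, and the preset `ae_config_small()`
encodes the choices that make it reliable:

* **Positive hidden-bias start** (`b1_init = 1`): with non-negative inputs
  and symmetric small weights, roughly half the hidden ReLU units start
  inactive and are prone to dying permanently; at width 16 losing ten units
  is fatal. Starting the biases at +1 keeps every unit initially active.
* **Small initial weights** (`init_scale = 0.03`): from small
  initialisation the gradient dynamics of the (near-linear) network align
  to the leading variance directions in order, which makes the learned
  subspace — and hence the selected gene set — much more reproducible
  across random restarts.
* **Penalty warm-up** (`lambda_warmup = 0.3`): the row-sparsity weight is
  ramped linearly over the first third of training. The network first
  learns a dense reconstruction in which every informative gene holds
  encoder weight; the ramp then prunes rows by reconstruction value.
  Growing a sparse solution from scratch instead leaves the choice of
  which correlated gene to read to initialisation noise.
* **Late step-size anneal** (`lr_decay` over the last 30%): constant-step
  Adam ends in a noise ball whose radius scales with the step size, which
  blurs the row norms used for scoring; annealing from 5e-3 down by 10×
  sharpens them.
* **No internal validation split** (`val_fraction = 0`): with 15–30
  samples a 20% split wastes scarce rows and makes the checkpoint depend
  on a 3–6 sample validation loss; training loss is monitored instead.
* 8000 epochs, full batch (`batch_size = 64` ≥ n). With the compiled
  training core a run takes a few seconds.

## Numerical and degenerate-input choices

* Zero-fraction filter: "more than 75%" is strict — a gene zero in exactly
  75% of samples is kept.
* Outlier filter: operates on the distribution of per-gene means with the
  population SD convention and strict inequality; zero spread removes
  nothing (warning). The rule is applied after the zero filter, in that
  order, by `preprocess_subtypes()`.
* Min–max scaling: per gene, fit on the fitting set only; constant genes
  map to 0; out-of-range values on new data are not clipped.
* Stratified splits: per-class floor of the train fraction, remainders
  assigned by largest fractional remainder (ties by class name), so the
  split is deterministic given the seed.
* Top-*k* selection breaks score ties by ascending gene id.
* ℓ2,1 subgradient on an all-zero row is 0; ReLU subgradient at 0 is 0.
* Empty consensus is returned with a warning, not an error.
* MCL: prune 1e-5, tolerance 1e-6, cap 100 iterations; fully pruned
  columns fall back to a self-loop.

## Problem sizes used in the test-suite studies

The suite and the acceptance script run entirely on generated cohorts at
the generator's default scale (130 samples × 500 genes; 50 markers per
class), with the consensus protocol at 3 seed blocks × 5 runs and
$k = 60$, and a 100-tree forest for the end-to-end classification study.
These sizes exercise every code path of the reference protocol (which uses
30 × 16 runs, $k = 3000$, 1000 trees) while each full study stays in the
minutes range on one CPU.

## Known limitations

* Strict intersection across 15 replicate runs is severe: a marker missed
  by a single run is lost. On the default synthetic cohort the per-run
  top-60 recall of the planted 50 markers is about 0.9, and the 15-fold
  intersection retains roughly 30–37 genes — almost all of them true
  markers (precision ≈ 0.95–1.0) but only ~60–70% of the planted set.
  This mirrors the reference protocol's own funnel, where each run keeps
  3000 genes and the 480-run intersection keeps only a few hundred. The
  consensus should be read as a high-precision core, not an exhaustive
  marker list.
* The bundled eq6 tree grower is O(n²·features) per split candidate scan
  and is intended for small panels only.
* The autoencoder trainer is deterministic given a seed but, like any
  non-convex fit, different seeds give different solutions; all downstream
  guarantees are therefore phrased through the consensus protocol.
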