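---
title: "Invertible dynamic graph convolutional networks for brain connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invertible dynamic graph convolutional networks for brain connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idgcn)
```

## The problem

Functional connectivity — the matrix of Pearson correlations between the
resting-state time courses of atlas-defined brain regions (ROIs) — is a
standard substrate for classifying clinical populations such as autism
spectrum disorder cohorts. Deep models on connectivity beat linear
baselines, but most of them are black boxes: the features that drive the
decision cannot be traced back to specific connections, which is exactly
what a biomarker study needs. `idgcn` implements an architecture designed
around that constraint: every transformation before the final classifier
is *exactly invertible*, so any subset of the network's output features can
be mapped back — not approximately, but algebraically — to the input
connectivity features that produced it.

## The model

### Graphs and spectral convolution

Each subject contributes an $N \times N$ correlation matrix $X$ whose rows
are node feature vectors. Two sparse graphs are built per subject:

* a **functional graph** keeping, for every node, its $k$ neighbours with
  the largest absolute correlation (edge weight $|X_{ij}|$), and
* a **spatial graph** whose skeleton keeps the $k$ nearest neighbours by
  Euclidean distance between ROI centroids, again weighted by $|X_{ij}|$.

Both are symmetrised by union, so every node retains at least $k$
neighbours. From the adjacency $A$ we form the normalized Laplacian
$L = I - D^{-1/2} A D^{-1/2}$ and its rescaling
$\tilde L = \tfrac{2}{\lambda_{\max}} L - I$, whose spectrum lies in
$[-1, 1]$. A graph convolution layer is a degree-$(K{-}1)$ Chebyshev
polynomial in $\tilde L$,

$$X^{(l)} = \sigma\!\Big(\sum_{k=0}^{K-1} T_k(\tilde L)\, X^{(l-1)} W_k\Big),
\qquad T_0 = I,\; T_1 = \tilde L,\; T_k = 2\tilde L T_{k-1} - T_{k-2},$$

with one trainable $F \times F$ weight matrix per order and $\sigma$ a
ReLU. This polynomial form is mathematically identical to filtering in the
Laplacian eigenbasis; the package carries an independent eigendecomposition
implementation (`spectralOracleForward()`) purely so the equivalence can be
asserted in tests rather than assumed.

### Additive invertible blocks

Two Chebyshev GCNs — $\phi$ on the spatial graph and $\omega$ on the
functional graph — are coupled additively:

$$y_1 = x_1 + \phi(x_2), \quad y_2 = x_2 + \omega(y_1), \quad
z_1 = \tfrac{1}{2}(y_1 + y_2), \quad z_2 = \tfrac{1}{2}(y_2 - y_1).$$

The inverse is exact for *any* $\phi$ and $\omega$ (they need not be
invertible themselves): $y_1 = z_1 - z_2$, $y_2 = z_1 + z_2$,
$x_2 = y_2 - \omega(y_1)$, $x_1 = y_1 - \phi(x_2)$. The network stacks
three such blocks; the first receives the input features twice, $(x, x)$,
and each later block consumes its predecessor's $(z_1, z_2)$. That wiring
is the only one that keeps the whole pre-classifier map invertible, which
is why we chose it — with $(y_1, y_2)$ forwarding the composition would
still be invertible per block but the averaging step would be skipped
between blocks, and the final representation would no longer match the
averaged form the inverse expects. All inversion arithmetic runs in double
precision; round-trip error for the 3-block stack is at the $10^{-13}$
level in practice and is asserted below $10^{-9}$ in the test suite.

### Features, screening, classifier

The input features of node $r$ are its correlations with the other ROIs.
Because only a minority of connections plausibly carry disease signal,
each ROI's feature row is reduced *individually*: a random forest
(impurity importance, `ranger`, seeded, single-threaded) is fitted per ROI
on its $N-1$ static correlation features, and the top $M$ columns are
kept; the same procedure on the per-edge temporal variability of
sliding-window correlations keeps $J$ dynamic columns. We read
"per-ROI reduction" literally — one forest per ROI — rather than slicing a
single global forest's importances, because it guarantees exactly $M$
features per ROI by construction. Screening is always refitted inside each
cross-validation fold on the training subjects only.

Dynamic features: a rectangular window of `windowLength` time points
slides with step `stride`; each window yields a correlation matrix and the
per-edge *population* standard deviation over windows is the auxiliary
feature. Window length 30 and stride 10 are common dynamic-connectivity
practice; the underlying method does not pin them down, so both are
surfaced in the configuration. The standard deviation (rather than
variance or coefficient of variation) is likewise our reading of "temporal
variation"; downstream stages only rank and select these features, so the
choice is monotone-equivalent for screening.

The screened $N \times (M+J)$ matrix passes through the invertible stack;
$z_1$ and $z_2$ are flattened and concatenated with a one-hot acquisition
site covariate (absorbing additive multi-centre offsets), and a fully
connected softmax layer produces the two class probabilities. Training
minimises mean cross-entropy with Adam (learning rate $10^{-3}$, 100
epochs, full batch at the cohort sizes we target); gradients are analytic
(hand-derived backpropagation through the coupling and the Chebyshev
layers) and are verified against central differences in the test suite.

### Identity-anchoring regularisation

A design point we consider essential, found while implementing the
interpretation module: if the block weights are free to grow, the trained
pre-classifier map drifts far from feature-aligned — the correlation
between $z_1$ and the input drops toward zero — and although the network
remains exactly invertible, *attribution* through it degrades: the class
signal becomes distributed over the whole output and no unit selection can
concentrate on the truly informative inputs. The package therefore applies
L2 weight decay (default `weightDecay = 0.05`) to the block weights
**only**; since the coupling is additive, decaying $\phi, \omega$ towards
zero anchors the stack near the identity map $z_1 \approx x$,
$z_2 \approx 0$, while the unpenalised classifier layer carries the
decision. On planted-effect cohorts this takes recovery of the planted
edges by the reconstruction analysis from near-chance to essentially
always, at no cost in classification accuracy.

### Interpretation

*Edge importance.* Each pre-classifier output unit is scored by its
class-discriminative contribution: the absolute difference of its two
classifier weight-row entries times its mean absolute activation. (Weight
difference alone is scale-confounded — the $z_2$ channel has small
activations and correspondingly inflated weights, and under that scoring
the planted edges of synthetic cohorts are never recovered.) The top
`topFraction` (default 10%) of units are kept, the rest zeroed, and the
masked output is pulled back through the exact stack inverse; absolute
reconstructed magnitudes, averaged over subjects, are scattered onto
connectivity edges via the screening map and symmetrised by max. With
`topFraction = 1` the reconstruction returns the inputs exactly — the
importance signal comes entirely from the masking, and the test suite
asserts this limit.

*Node importance.* Each ROI is lesioned in turn: its feature row is
zeroed, every other ROI's feature slots that source from it are zeroed
(otherwise its correlations leak back through its partners' rows and the
node is not actually excluded), and its edges are removed from both graphs
before the Laplacians are rebuilt. The per-fold models are retrained under
the lesion with the baseline fold assignment; the node score is the drop
in mean cross-validated accuracy.

## The synthetic-cohort generator

`simulateCohort()` provides ground-truth cohorts so that every stage is
testable without clinical data. Each planted edge $(i, j)$ receives a
shared latent signal with weight $\sqrt{\rho}$, giving population
correlation $\rho$ between the two ROIs; class 1 shifts $\rho$ by
`staticEffect`. Nonstationarity is produced by multiplying the latent
component, in class-1 subjects only, by a slow sinusoidal amplitude
normalised to unit RMS power — static correlations are thereby preserved
while windowed correlations fluctuate more, so the dynamic features carry
class signal exactly when `dynamicEffect > 0`. The modulation period
defaults to 100 time points: with a 30-point window the modulation must be
slow relative to the window or it averages out within each window and the
planted dynamic contrast vanishes (this is also the realistic reading of
slowly switching connectivity "states"). Sites are assigned round-robin
with a small constant offset ($0.1 \times$ `noiseSd` per site step); ROI
centroids are drawn uniformly in a $140 \times 170 \times 140$ mm box
(only relative distances matter for the spatial graph). Measurement noise
of standard deviation `noiseSd` (default 0.1) attenuates all correlations
by $1/(1 + \mathrm{noiseSd}^2)$.

What the generator does *not* emulate: haemodynamic response shapes,
autocorrelated BOLD noise, head motion, or realistic site covariance
structure. Passing tests on these cohorts therefore demonstrate that the
machinery recovers the structure it assumes, not that it will reach any
particular accuracy on clinical data.

## Numerical choices and degenerate inputs

* Negative correlations: edge weights use $|r|$ (non-negative degrees are
  required by $D^{-1/2}$), and functional neighbours are ranked by $|r|$,
  keeping strong anti-correlations.
* Ties in neighbour selection and in screening importances break towards
  the lower ROI index, making every construction deterministic.
* $\lambda_{\max}$ is computed exactly per graph by a symmetric
  eigensolver; a degenerate edgeless graph (where $L = I$) falls back to
  $\lambda_{\max} = 2$, making $\tilde L$ the zero operator.
* A zero-variance ROI gets a zero correlation row/column (with a warning)
  so feature shapes stay stable across subjects; an isolated node keeps
  $L_{ii} = 1$.
* Predicted probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside
  the cross-entropy; AUC is the normalised Mann–Whitney rank statistic.
* Cross-validation folds are stratified by class with overall fold sizes
  differing by at most one; all randomness (generator, forests,
  initialisation, folds) is derived from explicit integer seeds, and
  repeated runs are bit-identical.

## Problem sizes used in validation

The test suite and the acceptance script work at reduced scale — cohorts
of 50–200 subjects, 10–20 ROIs, 100–200 time points, $M$ of 4–8 and $J$ of
0–10 — chosen so the full suite exercises every stage, including 5-fold
retraining and per-node lesion retraining, within a desk-scale compute
budget. The architecture defaults (`M = 48`, `J = 10`, `K = 3`, `k = 3`,
three blocks, 5-fold CV) match the published study setting and are what
`runConfig()` provides for real-data use at atlas scale (about 110 ROIs).

## Known limitations

* The sliding-window summary compresses dynamics to one dispersion number
  per edge; connectivity state sequences are not modelled.
* Screening uses impurity importance, which at small samples has known
  biases towards correlated predictor groups; the null-cohort uniformity
  of selections is checked in the acceptance tests at the sizes used here.
* Lesion analysis retrains $(N+1) \times \mathrm{folds}$ models and grows
  linearly in $N$; at atlas scale it is an overnight computation rather
  than an interactive one.
* Site handling is a one-hot covariate into the classifier — additive site
  effects only; no harmonisation of higher-order site differences.
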