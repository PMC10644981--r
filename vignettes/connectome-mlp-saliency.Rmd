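---
title: "Classifying structural connectomes with a perceptron and ranking edges by input gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying structural connectomes with a perceptron and ranking edges by input gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A structural connectome summarizes a participant's white-matter wiring as a
weighted undirected graph: nodes are the regions of a brain parcellation and
an edge weight measures the tractography streamline mass connecting two
regions. On the 84-region Desikan-Killiany (DK) parcellation (68 cortical,
14 subcortical and 2 cerebellar labels) this is a symmetric, non-negative,
zero-diagonal 84 x 84 matrix. Clinical questions of the form "does group
membership leave a signature in the connectome, and *where*?" — for example
distinguishing focal-epilepsy patients from controls, or patients whose
focal seizures do or do not generalize to the opposite hemisphere — can be
posed as a binary classification problem followed by an attribution
problem: which edges and nodes drove the correct classifications?

`connectomlp` implements that pipeline end to end: vectorization and
normalization of connectome matrices, a small multilayer perceptron (MLP)
classifier trained under repeated-seed stratified 5-fold cross-validation,
and per-group gradient scores that rank edges and nodes by their
contribution to correct classification. Because clinical connectome data
are rarely shareable, the package also ships a synthetic-cohort simulator
with *planted*, fully known group effects; all of the package's empirical
claims are statements about recovering those planted effects, verified in
the test suite.

## Input representation

Since the matrix is symmetric with a zero diagonal, only the strict upper
triangle carries information: n(n-1)/2 unique edges, 3486 for n = 84. The
canonical flattening is row-major over pairs (i, j) with i < j, fixed and
documented so that saliency scores are comparable across runs and emitted
tables. `edge_index()` / `edge_pair()` expose the bijection.

Edge weights from tractography are on an arbitrary, participant-dependent
scale (total streamline mass varies with brain volume and seeding). Each
participant's edge vector is therefore min-max rescaled to [0, 1]:

  x_k' = (x_k - min(x)) / (max(x) - min(x)).

Normalization is **per participant**, not cohort-wide: it removes
inter-subject scale while using no statistic of any other participant, so
no test-set information can leak into training through the scaling. A
cohort-wide variant would additionally preserve between-subject scale
differences, but those are dominated by nuisance factors in practice, and
the leakage-free choice is the safer default (`normalize` key in the
pipeline config).

Loading applies validation rules matched to what connectome builders emit:
non-negative entries, symmetry within a relative tolerance of 1e-6
(asymmetry below tolerance is averaged away; larger asymmetry is treated
as file corruption and refused), and any non-zero diagonal (self-connection
counts from some builders) is zeroed with a warning that is surfaced in
pipeline reports.

## The classifier

The model is a four-layer perceptron with 1024, 256, 64 and 2 units — the
two outputs representing the two groups — taking the 3486-vector as input.
Layer widths are the model's defining hyperparameters and are kept fixed;
the input width adapts to n(n-1)/2 for other parcellations. Choices the
architecture itself does not pin down are set as follows:

* **Activation**: rectified linear units after each hidden layer, the
  standard default for MLPs of this size.
* **Loss**: mean cross-entropy of the true labels, via a numerically
  stabilized log-sum-exp softmax.
* **Optimizer**: full-batch Adam (learning rate 1e-3, beta 0.9/0.999,
  epsilon 1e-8) for 100 epochs. Cohorts here are a few dozen
  participants, so a full batch is natural and removes batch-order
  nondeterminism: training is a pure function of (data, seed, config).
  The training-loss trajectory is recorded on every fit and exposed.
* **Initialization**: fan-in-scaled Gaussian weights (sd = sqrt(2/fan_in),
  the rectifier-matched scaling) and zero biases, drawn deterministically
  from an integer seed. The init seed is the unit of replication in
  repeated experiments.

The training kernel runs in single precision, the standard working
precision for neural-network training, with the Adam update fused into one
pass per parameter block. Prediction and all gradient analyses run in
double precision in R against the stored parameters; the analytic
input-gradient path is checked against a central finite-difference oracle
in the test suite (relative agreement better than 1e-4 on small networks).

## Repeated cross-validation

Participants are split into k = 5 folds, stratified so each fold's class
counts are within one of the cohort proportion — without stratification,
cohorts of a few dozen can produce single-class test folds, for which
accuracy per class is undefined. Members of each class are shuffled and
dealt cyclically across folds, the second class continuing the deal where
the first stopped, so fold sizes also differ by at most one.

One *experiment* trains a freshly initialized network per fold on the
out-of-fold participants and predicts the held-out fold; every participant
is predicted exactly once, and the pooled accuracy is the exact rational
(correct predictions)/N. Experiments are repeated over many init seeds
(1000 by default in the pipeline config) with the fold split held fixed —
only the initial network weights are re-randomized, which is what the
seeds control; a `refold_per_seed` flag re-randomizes the split per seed
for sensitivity analyses, without a claimed default. The *best model* is
the seed with maximal pooled accuracy, ties broken toward the lowest seed
for determinism. Per-fold init seeds are derived from the experiment seed
through R's RNG so the whole run is reproducible from (data, split seed,
init seeds, config).

## Gradient saliency

For interpretation the package asks, for each group, which input edges
push the classifier toward that group. After each experiment, every
participant that was **correctly predicted as a held-out test case**
contributes the gradient of its true-class output with respect to its
input edges, taken under the model of the fold in which it was held out —
the cross-validation predictions are what "correctly predicted" refers
to, and no all-data model is ever fitted. Samples are pooled over all
(seed, participant) combinations and averaged per class into edge
gradient scores; node scores sum the scores of incident edges (node
strength), which forces the handshake identity
sum(node scores) = 2 x sum(edge scores), a cheap internal consistency
check that is asserted in the tests.

The gradient target is switchable:

* `probability` (default): d p_c / d x. With two classes p_0 + p_1 = 1,
  so the class-0 and class-1 gradients on the same input are *exact*
  negatives — the package computes them to be bitwise so. This is the
  mode under which a positive score for one group mechanically implies a
  negative score for the other.
* `logit`: d z_c / d x, unsaturated but not normalized.
* `margin`: d (z_c - z_{1-c}) / d x, antisymmetric by construction.

Aggregation is likewise switchable: `per_class` (default) averages each
class's own correctly predicted participants, so the two classes' scores
come from disjoint samples and their sign duality is an empirical
finding; `shared` averages both class gradients over the union of correct
participants, under which the duality is exact by construction. Both are
exposed because the distinction matters when interpreting score signs.

Rankings (`top_k_nodes`, `top_k_edges`) sort by score with ties broken by
ascending index for determinism, and `cross_hemisphere_count` counts
ranked edges whose endpoints carry different lateral hemisphere codes
(midline regions never count as crossing) — the quantity of interest when
a clinical hypothesis concerns propagation between hemispheres.

## The synthetic cohort generator

The simulator emulates the *data model* of a SIFT2-weighted DK connectome
study, not tractography itself. A cohort is built as:

1. **Backbone**: one mean matrix shared by all subjects. A region pair is
   connected with probability 0.35 within a hemisphere and 0.15 across
   hemispheres (structural connectomes are markedly denser within
   hemispheres), and present edges draw log-normal weights (meanlog 3,
   sdlog 1) — positive and right-skewed, like streamline-mass weights.
2. **Subjects**: the backbone times i.i.d. log-normal noise per present
   edge (sdlog 0.3, a moderate inter-subject variability), keeping
   matrices non-negative by construction.
3. **Group effect**: group-1 subjects have a planted edge set multiplied
   by 1 + effect_size. Defaults plant 20 edges, 2 of them
   cross-hemisphere, with effect_size 2, in a 20 vs 28 cohort — the
   shape of a small case-control study with a contralateral-propagation
   subgroup signature. The planted set and multiplier are recorded as
   ground truth.

Seeding is layered: the backbone uses the master seed, subject s uses
master + s (so any subject is reproducible independent of cohort size),
and the planted-edge draw uses master + N + 1. The hemispheric two-block
backbone is deliberately the *only* topological structure: it is the
minimum needed to make cross-hemisphere detection meaningful. Real
connectomes additionally show distance-dependent connectivity, modular and
hub structure, and spatially correlated noise; none of these are modelled,
so passing recovery tests demonstrates that the pipeline can find planted
multiplicative effects of the stated size under log-normal noise — not
that it will find disease effects of any particular clinical kind.

## Numerical and degenerate-input choices

* Constant edge vectors (max = min) cannot be normalized and are treated
  as degenerate connectomes (error).
* Asymmetry tolerance 1e-6 relative; write/read round-trips hold to 1e-9.
* Single-class training sets are refused; stratification requires at
  least k members per class.
* Ties in rankings and in argmax predictions resolve toward the lower
  index, making every reported artifact deterministic.
* Checkpoints serialize parameters as JSON at 17 significant digits
  (agreement within one unit in the last place on reload).

## Problem sizes used in validation

The test suite validates behaviour at the full 84-node scale where the
claim depends on it, and at 10-16 nodes where it does not: null
calibration uses a 200-subject null cohort with 10 init seeds of 5-fold
CV (mean pooled accuracy within 3 binomial SE of chance); separability
uses a 40-subject strong-effect cohort with 5 seeds (best accuracy
reaches 100%); planted-edge recovery uses five replicate 60-subject
cohorts with 20 planted edges and 20 seeds each, plus five intra-
hemisphere contrast cohorts at 5 seeds each for the cross-hemisphere
check (the contrast only feeds a directional comparison, so fewer
repeats suffice there). These sizes
give stable pass/fail behaviour under the planted-effect magnitudes
while keeping a full run of the suite practical on a single CPU; the
scaled-down cross-validation runs use the same code path as the
full-scale pipeline configuration.

## Known limitations

* The simulator's simplifications listed above; in particular, planted
  effects are multiplicative on single edges, not correlated subnetworks.
* Repeated experiments vary only the weight initialization by default;
  fold-split variability is available but not folded into the default
  summaries.
* Gradient saliency is a first-order, single-model attribution; no
  statistical significance is attached to individual node or edge scores,
  and no comparison with other attribution methods is attempted.
* Accuracy estimates from pooled 5-fold CV on small cohorts have wide
  sampling variability; the package reports exact per-seed accuracies and
  leaves uncertainty quantification to the analyst.
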