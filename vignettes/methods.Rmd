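---
title: "Predicting drug-disease associations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease associations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`repoforest` scores candidate drug-disease pairs for drug repositioning.
Its inputs are a binary association matrix $A$ (rows: diseases, columns:
drugs), a drug-drug structural similarity matrix (e.g. Tanimoto scores
on chemical fingerprints, precomputed), and MeSH tree numbers for the
diseases. This vignette explains each stage of the model, the tunable
parameters, and the design decisions that were genuinely open.

## Similarity construction

**Logistic rescaling.** Raw structural or semantic similarities carry
little signal in their mid-range. Each off-diagonal entry $x$ passes
through
$$L(x) = \frac{1}{1 + e^{c x + f}}, \qquad c = -15,\; f = \ln 999,$$
which pins $L(0) = 0.001$ and $L(1) \approx 0.9997$: values below about
0.3 are crushed towards 0 and values above 0.6 saturate towards 1. The
constants are exposed (`c`, `f` in `pipeline_config()`) but the defaults
are the published calibration and we do not refit them.

**Cohesive-cluster enhancement.** Drugs that share diseases form a
weighted network (edge weight = number of shared diseases). A greedy
ClusterONE-style search grows overlapping clusters from high-degree
seeds, scoring a candidate set $V$ by its cohesion
$$C(V) = \frac{W_{in}(V)}{W_{in}(V) + W_{bound}(V) + P(V)},$$
with $P(V) = 2\,|V|$ a per-node penalty (the convention of the original
cohesive-clustering algorithm; the penalty discourages vacuous small
sets). Growth applies the single add-or-remove step that most increases
cohesion until none does; clusters below cohesion 0.3 or size 3 (2 on
graphs with fewer than 6 nodes) are dropped, and pairs with overlap
score $|V_1 \cap V_2|^2 / (|V_1||V_2|) > 0.8$ are merged. Ties always
break towards the lowest node index, so clustering is deterministic.
Pairs co-resident in a cluster get their similarity multiplied by
$(1 + C(V^\*))$, where $V^\*$ is the most cohesive shared cluster; any
product reaching 1 is replaced by 0.99 so the matrix stays inside the
unit interval. Growth may occasionally discard its own seed node; the
seed is marked processed regardless, which keeps the seeding loop
finite.

The same rescale-cluster-enhance treatment is applied to the disease
semantic similarity, using the disease-shared-drug network.

**Disease semantic similarity.** MeSH tree numbers induce an ancestor
DAG by prefix truncation (`C04.588.945` contributes `C04`, `C04.588`,
`C04.588.945`). A disease's own node contributes 1 and each ancestor $b$
contributes $\max_{b'} \psi\, D(b')$ over its children $b'$ in the
closure, with decay $\psi = 0.5$ (the convention of the MeSH-similarity
literature; the source model leaves it unset). Two diseases are then
compared by
$$SV(i,j) = \frac{\sum_{s \in N_i \cap N_j} \left(D_i(s) + D_j(s)\right)}
  {DV(i) + DV(j)},$$
the shared fraction of their total semantic value. Diseases missing
from the MeSH file fall back to similarity 0 against everything (with a
warning); this is a conservative choice the inputs do not dictate.

**GIP kernels.** The Gaussian interaction profile kernel compares
binary association profiles:
$$GE(i,j) = \exp\!\left(-\theta \lVert V(i) - V(j)\rVert^2\right),
\qquad \theta = \theta' \Big/ \tfrac1n \sum_u \lVert V(u)\rVert^2,$$
with $\theta' = 0.5$ on both axes. The bandwidth normalization by the
mean squared profile norm makes the kernel scale-free in the number of
associations.

**Fusion.** A drug with no known association has a zero profile, for
which the GIP kernel is uninformative (it no longer depends on the
partner). Pairs where both profiles are non-zero keep the GIP value;
all other pairs fall back to the enhanced structural (drugs) or
semantic (diseases) similarity.

## Pair representation and feature learning

A pair (drug $r$, disease $d$) is described by concatenating row $r$ of
the fused drug similarity and row $d$ of the fused disease similarity:
$n_{drugs} + n_{diseases}$ features (906 for a 593-drug, 313-disease
dataset; 1072 for 663/409).

A single-hidden-layer sparse autoencoder (sigmoid activations both
layers) compresses this to 100 dimensions. Its loss is mean halved
squared reconstruction error plus a sparsity penalty
$\gamma \sum_t KL(\rho \,\|\, \hat\rho_t)$, where $\hat\rho_t$ is the
mean activation of hidden unit $t$ and
$KL(\rho\|\hat\rho) = \rho \ln \frac{\rho}{\hat\rho} +
(1-\rho)\ln\frac{1-\rho}{1-\hat\rho}$. Defaults: $\rho = 0.05$ (a small
target near zero), $\gamma = 10^{-6}$ (reading the published weight
"10e-7" as $10 \times 10^{-7}$; `gamma` is a knob in case $10^{-7}$ was
intended), 100 epochs of mini-batch (64) gradient descent with adadelta
per-parameter steps (decay 0.95, $\epsilon = 10^{-6}$). $\hat\rho_t$ is
computed per mini-batch to keep stochastic-gradient semantics; a
`full_batch_rho` option averages over the whole training set instead.
The reconstruction cost contains no weight-decay term. Training is
deterministic given a seed: initialization (uniform in $\pm\sqrt{6/(d_{in}+S_2)}$,
zero biases) and the per-epoch shuffles are drawn in R and passed to
the compiled loop, whose arithmetic mirrors the exported `sae_cost()`
reference step for step.

PCA (centered, no scaling) then reduces the 100 hidden units to 84
components, sign-fixed so each component's largest loading is positive.
Whether the upstream study fit the autoencoder and PCA once or per
cross-validation fold is not documented; this package fits both per
fold, on training pairs only.

## Rotation forest

Each of 139 trees receives the data after a block-diagonal rotation:
the 84 features are randomly partitioned into $\min(K, d)$ subsets,
and each subset's block is the full PCA basis fitted on a 75% row
subsample. Trees are Gini-impurity decision trees grown without a depth
cap, searching all features at every split; the ensemble score is the
mean of the trees' leaf probabilities (soft voting, which keeps ROC
curves smooth).

Two consequences of the published setting $K = 200$ deserve honesty.
First, $K$ exceeds the 84 available features, so it is clamped to $d$
and every subset is a singleton — the "rotation" of a single column is
just a sign, and the sign convention makes it exactly the identity. The
package reports this clamp with a message. Second, with identity
rotations and a common training set, all 139 trees are deterministic
copies of one another, so the "ensemble" is algebraically a single
overfit tree with degenerate 0/1 scores. Each tree therefore
fits on its own 75% instance subsample, drawn without replacement —
the same fraction the rotation PCA uses, and the standard bagging
remedy. Setting `bootstrap_fraction = 1` disables the subsample, which
also makes a single-tree forest with one full subset exactly equal to a
plain tree on globally PCA-rotated data (a property the tests check).
With singleton subsets the model is a bagged Gini forest and is fitted
in one `ranger` call; non-trivial blocks fit one tree per rotation.

## Evaluation protocols

Pairs are assembled with all known associations as positives and an
equal number of negatives sampled uniformly from unknown cells (the
1:1 ratio matches the near-80% accuracies a thresholded classifier
reports in the source experiments; the original negative-sampling
scheme is undocumented). Stratified 10-fold cross-validation reports
accuracy, precision, recall, F1 (threshold 0.5) and AUC per fold, with
mean and standard deviation. AUC comes from a tie-aware threshold
sweep with trapezoidal integration, which equals the Mann-Whitney
$U/(n_+ n_-)$ statistic.

Two fidelity modes exist because the upstream protocol computes all
similarities once from the full matrix before folding, which lets
test-fold associations inform the GIP kernels of their own test pairs
(a transductive, optimistic design). `paper_mode = TRUE` reproduces
that protocol. The default instead re-derives the GIP kernels, cluster
enhancements and fusion per fold with the test fold's positives zeroed
out. On the synthetic benchmark below the difference is material: mean
AUC ≈ 0.87 in paper mode versus roughly 0.72–0.74 leakage-safe — worth knowing
when interpreting published transductive results.

The case-study ranking mode removes every association of a query
disease, rebuilds similarities from the masked matrix, trains on the
remaining pairs (the query's unknown pairs are excluded from negative
sampling, since they are the very candidates being scored), and
returns the top-20 drugs by score, ties broken by drug identifier.

## The synthetic benchmark

`generate_dataset()` plants one latent grouping (4 groups over 80 drugs
and 60 diseases) that drives all three similarity channels at once:
associations are Bernoulli(0.25) within matched groups and
Bernoulli(0.01) otherwise; structural similarity is 0.7 within / 0.2
across groups plus truncated Gaussian noise (sd 0.05); each group's
diseases hang off a common tree-number spine at least two segments
deep, so they share a non-root ancestor. A block model is the right
minimal emulation because every similarity source the pipeline
consumes is a group-coherence signal. What it does *not* emulate: the
heavy-tailed degree distributions, correlated fingerprint structure
and uneven MeSH topology of real pharmacological data — so passing
tests demonstrate correct mechanics and end-to-end signal recovery,
not clinical performance. The 80 x 60 default keeps a full 10-fold CV
round to roughly a minute on one core, which is what the test suite
and acceptance script exercise (reproducing the published large-scale
numbers requires the external 593 x 313 / 663 x 409 datasets).

## Numerical details and degenerate inputs

* Similarity matrices must be symmetric within $10^{-9}$ (readers
  average away asymmetries up to $10^{-6}$) and inside $[0,1]$ with a
  $10^{-9}$ clipping allowance.
* $\hat\rho_t$ is clipped to $[10^{-12}, 1 - 10^{-12}]$ before the KL
  terms, so saturated hidden units cannot produce infinities.
* A zero-variance feature subset inside a rotation block keeps an
  orthonormal completion (identity directions), so rotations are always
  norm-preserving.
* Cluster growth requires a strict cohesion increase ($>10^{-15}$),
  which with a finite state space guarantees termination.
* An all-zero association matrix (no bandwidth for the GIP kernel), a
  single-class fold, and a disease absent from the matrix all fail fast
  with explicit errors rather than propagating NaNs.
* All randomness flows from explicit integer seeds; sub-seeds for
  folds, trees and retries are derived arithmetically and stay below
  $2^{31}$.

## Known limitations

* The clamp of $K$ means the published rotation-forest setting cannot
  rotate anything on 84 features; what $K = 200$ controlled in the
  original experiments cannot be determined from its description.
* Semantic similarity of diseases missing from MeSH defaults to zero,
  which underestimates their relatedness.
* The leakage-safe mode masks test positives from the features but
  still samples training negatives from cells that include other
  test-fold negatives; unknown-cell negatives are inherently noisy
  labels in this problem.
* Single-layer autoencoder only; no denoising, stacking, or early
  stopping.
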