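---
title: "Nested tree-structured gene co-expression modules: model and methods"
author: "gemtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested tree-structured gene co-expression modules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single cell's transcriptome is a mixture of transcriptomic programs: broad
lineage programs shared across many cell types, and specialized programs
expressed by narrow subpopulations. Flat topic models (LDA, NMF) recover
such gene co-expressing modules (GEMs) but treat them as unrelated, so the
shared/specialized structure — a myeloid program sitting above separate
monocyte, dendritic-cell and platelet programs, say — has to be
reconstructed by hand. `gemtree` instead lays the modules out on a preset
tree: each node k carries a gene distribution $\beta_{k\cdot}$ on the
simplex, and each cell d carries loadings $\theta_{d\cdot}$ over nodes, with
high levels absorbing broad signals and leaves absorbing specialized ones.

## The generative model

The model is the finite-tree specialization of a nested hierarchical
Dirichlet process topic model. A tree is preset by a branching vector (e.g.
`5-4-3`: five top-level GEMs, four children each, three grandchildren each —
85 nodes). Per cell, the generative story is:

1. choose a top-level node by stick breaking over siblings, with breaks
   $\pi_i \sim \mathrm{Beta}(1, \tau)$ taken in node-id order;
2. at each internal node, descend to a stick-breaking-chosen child with
   probability $\gamma$ (the *switching parameter*) or stop;
3. distribute the cell's loading over the resulting root-to-end path by
   stick breaking (the root takes the first stick);
4. draw UMI counts $C_{dg} \sim \mathrm{Poisson}(L_d \sum_k \theta_{dk}
   \beta_{kg})$ with log-normal library sizes $L_d$.

`simulate_planted_tree()` implements exactly this story, so planted-truth
recovery experiments test the same process the model assumes.
The truncation of all stick-breaking constructions at the preset tree is
deliberate: the tree is a modelling choice, not an inferred quantity, and
dynamic tree growth is out of scope.

## Inference

Inference is penalized EM on the multinomial mixture, the coordinate-ascent
specialization of variational Bayes for this finite model:

* **E step.** Per-token responsibilities $r_{dgk} \propto \theta_{dk}
  \beta_{kg}$, computed in sparse triplet form with dense per-chunk
  probability blocks capped near 5e6 entries so memory stays flat.
* **M step.** $\theta_{d\cdot} \propto n_{d\cdot} + a$ and
  $\beta_{k\cdot} \propto m_{k\cdot} + \eta$, where $n$ and $m$ are expected
  token counts and $a_k = \tau\, q_k(\gamma, \tau)$ is the tree-occupancy
  prior: unit mass flowed down the tree, each internal node keeping
  $1-\gamma$ of what arrives and passing $\gamma$ to its children split by
  expected stick weights. $\sum_k q_k = 1$, so $\tau$ is the total prior
  pseudo-count per cell.

The recorded epoch objective is the penalized log-likelihood
$\sum_{dg} C_{dg} \log \sum_k \theta_{dk}\beta_{kg} + \eta \sum_{kg} \log
\beta_{kg} + \sum_{dk} a_k \log \theta_{dk}$, evaluated at the parameters
entering the epoch. In `one-batch` mode every epoch is exact EM, so this
trace is provably non-decreasing — the package treats that as a tested
invariant, not an aspiration. In `mini-batch` mode the gene-distribution
statistics follow stochastic natural-gradient updates with a constant
learning rate (default 0.01) over seeded random batches; the trace is then
only approximately monotone, as expected of stochastic variational
inference.

The switching parameter acts through $a_k$: lowering $\gamma$ moves prior
pseudo-counts from deep nodes to high levels, a conservative search that
keeps loading mass on broad programs. Because the prior carries $\tau$
pseudo-counts against hundreds of observed tokens per cell, the effect on
$\theta$ is deliberately gentle at realistic library sizes — it biases
ambiguous tokens (genes shared between a parent and its children) rather
than overriding the data. Held-out cells are handled by *fold-in*
(`infer_loadings()`): the same per-cell EM with $\beta$ frozen.

### Tree initialization

Good starting values matter for a model with dozens of related topics.
`initialize_gem_tree()` builds them top-down:

1. normalize each cell's counts to proportions;
2. cluster the (seeded subsample of) cells into the top-level nodes with
   **L1 k-medians** — assignments minimize L1 distance, centroids are
   element-wise (weighted) medians, the exact L1 minimizer, with
   kmeans++-style seeding adapted to L1 and three seeded restarts. L1 is
   used because sparse proportion vectors make squared-error clustering
   chase outliers;
3. **break the information**: for each cell, remove what its node centroid
   explains. With centroid $\hat\Theta$ renormalized to the simplex and
   overlap coefficient $c = \sum_g \min(x_g, \hat\Theta_g)$, the residual is
   $\max(0, x - c\hat\Theta)$, renormalized. This is the package's concrete
   reading of the breaking step — it removes exactly the mass the centroid
   can explain and keeps the residual non-negative — and is the single most
   consequential interpretation in the codebase;
4. cluster each node's residualized cells into its children and recurse to
   the leaves. Children clusterings weight each cell by its *unexplained
   mass* (the raw residual total before renormalization, accumulated across
   levels): a cell fully explained by its parent carries only noise about
   the children, and renormalization would otherwise inflate that noise to
   full weight. This weighting measurably improves leaf recovery.

The outer loop is a single top-down pass: levels are processed once, in
order, because residualization makes re-passing ill-defined. A `sweeps`
analogue is intentionally not exposed. A parent with fewer assigned cells
than children initializes its children by seeded perturbation of the parent
centroid (logged). Centroids get `smoothing` (default 1e-6) added before
renormalization so all downstream logarithms are finite.

### Transfer learning

`warm_start()` maps a trained model onto a new gene vocabulary: shared genes
keep their weights, unseen genes enter every row at the $\eta$-smoothed
minimum, rows renormalize, and the result seeds `fit_gem()`. On data drawn
from the pretraining model's distribution a warm start typically reaches the
convergence criterion in no more epochs than a cold start. The ordering can
occasionally invert on easy corpora — the relative-change criterion rewards
a cold start that stalls early in a worse optimum — which is why the
package asserts the ordering, never the epoch counts.

## Evaluation metrics

* **Held-out perplexity** $\exp(-L_{test}/\sum C_{dg})$ with $L_{test} =
  \sum_{dg} C_{dg}\log\sum_k \theta_{dk}\beta_{kg}$, $\theta$ from fold-in.
  A uniform model scores exactly the vocabulary size, a useful sanity
  anchor; lower is better.
* **PMI topic coherence**: the sum of pairwise pointwise mutual information
  over a GEM's top 50 genes, with presence probabilities estimated as cell
  frequencies of nonzero counts (the standard document-frequency
  convention; the training corpus by default) and 1e-12 smoothing against
  log 0. The score is a raw sum over pairs, so comparisons must share
  `top_n`.
* **Cosine similarity** between top-gene lists (as binary indicator vectors
  over the union vocabulary) and marker sets, or GEM x GEM.
* **Recovery score**: mean cosine between fitted and planted gene
  distributions under an optimal one-to-one Hungarian matching
  (`mean_matched_cosine()`), so duplicated fitted rows cannot double-count.

## Synthetic data

`simulate_splatter_like()` emulates the core of splatter-style count
simulation — Gamma gene means, log-normal library sizes, Poisson counts —
because only the count *marginals* matter for protocol-level experiments.
It deliberately omits dropout modelling, batch effects and DE factors, so
passing tests say nothing about robustness to those. Defaults give a median
library of ~2000 UMIs. `make_beta_true()` plants hierarchical gene
distributions (disjoint top-level anchors; each node mixing `parent_share`
of its parent with a node-specific sparse profile on reserved genes), and
`split_train_test()` reproduces the evaluation protocol of one held-out
test set plus nested training sets of increasing size, replicated
independently.

## Study conditions used by the tests and the acceptance script

All experiment sizes are fixed in code, chosen once:

* **Recovery**: tree `3-2-2` (21 GEMs), 2000 cells, 1500 genes,
  `parent_share = 0.3`, three seeds; pass bar: mean matched cosine >= 0.8.
* **Training-size trend**: tree `3-2-2`, 2500 genes, 5000 simulated cells,
  library ~300 UMIs, training sizes 500/1000/2000/4000 with a 500-cell
  held-out set. The vocabulary deliberately exceeds the smaller training
  sizes so estimation error is visible, mirroring evaluation regimes where
  genes outnumber training cells; the trend is asserted as a majority of
  non-increasing adjacent comparisons, not strict monotonicity, since
  single-corpus perplexity differences at adjacent sizes sit near sampling
  noise.
* **Warm start**: 1500-cell pretraining and target corpora from one planted
  model, 800 genes.
* **Switching parameter**: fold-in with the planted gene distributions at
  $\gamma \in \{0.9, 0.5, 0.1\}$ on a fixed 1000-cell corpus; mean level-1
  loading mass must increase as $\gamma$ falls.

## Defaults and numerical choices

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | global DP concentration (kept for model provenance) |
| `tau` | 1 | per-cell prior strength and stick concentration |
| `eta` | 0.01 | Dirichlet pseudo-count per gene per GEM |
| `gamma_switch` | 0.75 | descend probability; 0.5 is the "shallow" preset |
| `learning_rate` | 0.01 | constant mini-batch step size |
| `batch_size` | 512 | cells per mini-batch |
| `conv_tol` | 1e-4 | relative objective change at convergence |

Ties in top-gene ranking break by input gene order (stable); ties in
responsibilities resolve toward the lowest node id through the deterministic
linear algebra. All randomness flows from one seed per entry point, saved
and restored around each call, so identical inputs give bit-identical
results. An optional Robbins–Monro decay for the mini-batch learning rate
was considered and rejected: the constant rate is the documented baseline
behaviour and decays add a second tuning knob the experiments do not need.

## Limitations

* The tree is preset; the model cannot add or remove nodes.
* $\beta$ rows at different levels share no support constraint: nothing
  forces a child's genes to nest inside its parent's support, and none is
  imposed.
* The switching parameter is fixed per fit, not learned.
* Coherence and perplexity are computed on raw counts; normalization or
  batch correction upstream of the model is the user's responsibility, and
  batch-confounded transfer learning will degrade silently.
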