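---
title: "Graph- and label-regularized semi-supervised pLSA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph- and label-regularized semi-supervised pLSA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcc)
```

## The problem

Functional annotation of proteins (and many analogous node-labeling
problems) presents three difficulties at once: labels are scarce — often
below 10% of nodes; labels are *multi*-labels with real correlation
structure; and the most informative signal is relational — interacting
proteins tend to share function. `smcc` treats this as a single estimation
problem rather than a pipeline: one generative model over the attribute
counts, with the scarce labels entering as hard constraints and the
network and label correlations entering as smoothness penalties.

## Model and objective

Attribute counts $n(x_i, w_j)$ follow a pLSA mixture whose latent
components are the $K$ classes:

$$L = \sum_{i=1}^N \sum_{j=1}^M n(x_i, w_j)\,
      \log \sum_{k=1}^K P(w_j \mid c_k)\, P(c_k \mid x_i).$$

The fitting objective is $O = L - \alpha R - \beta H$ with

$$R = \sum_{i,s=1}^N D(\mathbf z_i, \mathbf z_s)\, E_{is}, \qquad
  H = \sum_{k,l=1}^K D(\mathbf r_k, \mathbf r_l)\, F_{kl},$$

where $D(p, q) = \tfrac12\left[\mathrm{KL}(p\|q) +
\mathrm{KL}(q\|p)\right]$ with natural logarithms, $\mathbf z_i$ is row
$i$ of $P(c|x)$, $\mathbf r_k$ is column $k$, $E$ is the (possibly
weighted) graph, and $F_{kl}$ is the cosine similarity of the labeled
indicator vectors of classes $k$ and $l$ (unit-Euclidean scaling, zero
row/column for classes without labeled positives, diagonal fixed at 1).
Both double sums run over *ordered* pairs, so each undirected edge
contributes twice; the $\tfrac12$ inside $D$ makes this equivalent to the
half-prefactored expansion of the objective.

Two deliberate reading choices are worth recording:

* **Columns $\mathbf r_k$ are used raw.** They are not distributions over
  nodes (they do not sum to 1), and the label penalty applies the
  KL-shaped sum to them exactly as written, after flooring at `eps` but
  *without* renormalizing. Renormalizing would change what is being
  compared — the relative allocation of a class across nodes rather than
  its absolute profile — and the symmetric form remains nonnegative
  either way, so the literal form is kept.
* **Zeros are floored, then (for rows) renormalized.** Clamping labeled
  rows creates exact zeros that would make the KL terms infinite. All KL
  computations floor probabilities at `eps` (default $10^{-12}$);
  row-distributions are renormalized after flooring, raw columns are not.

## Supervision: clamping

A labeled node $x_i$ with $l_x$ known labels has its row of $P(c|x)$
fixed to $1/l_x$ on those labels and 0 elsewhere — at initialization and
again after every M-step. This is the only place observed labels enter;
they then propagate through the likelihood (via $P(w|c)$) and through
both regularizers.

## EM algorithm

The E-step and the $P(w|c)$ M-step are the standard pLSA updates. The
posterior tensor is never materialized: both M-steps read their weighted
sums from the $N\times M$ count/mixture ratio, and only cells with
$n(x_i,w_j) > 0$ ever contribute (a cell with a fully zero mixture falls
back to a uniform posterior, with a warning).

The $P(c|x)$ M-step comes from the stationarity conditions of the
Lagrangian-augmented expected complete-data log-likelihood under the
first-order approximation $\log x \approx 1 - 1/x$ (valid as smoothing
drives ratios of neighboring probabilities toward 1). In class-major
stacking $y = [y_1; \dots; y_K]$ this yields the sparse symmetric system

$$\big(\Omega + \alpha\,(I_K \otimes L_E) + \beta\,(L_F \otimes I_N)\big)\, y = Z,$$

where $Z_k[i] = \sum_j n(x_i,w_j)\,P(c_k|x_i,w_j)$, $\Omega$ repeats the
per-node total counts $\rho_i = \sum_j n(x_i, w_j)$ across the $K$
blocks (an identity asserted at run time, since the posterior sums to 1
over classes), and $L_E$, $L_F$ are the graph and label-affinity
Laplacians — both positive semidefinite, so the system matrix is positive
definite whenever every node has counts. The textual description of the
label-side operator as node-major blocks is internally inconsistent with
the class-major stacking of $Z$ and $y$; the package resolves it as
$L_F \otimes I_N$, which is the unique reading that mixes the $K$ entries
belonging to each node with weights from $F$.

Numerical details:

* The system is solved with `Matrix::solve` (sparse Cholesky).
* The approximation does not guarantee a nonnegative solution; entries
  are floored at `eps` and rows renormalized before re-clamping.
* A node with an all-zero count row and no graph coupling makes its
  equations singular; such rows are pinned to their previous value.
* Convergence is declared when the relative objective change drops below
  `tol` (default $10^{-4}$), capped at `max_iter` (default 50). The
  approximate M-step means $O$ is not provably monotone; in practice the
  synthetic fixtures converge in 10–25 iterations, and the full
  per-iteration $(O, L, R, H)$ trace is returned for inspection.

### Initialization

$P(w|c) \propto n(w_j, c_k) + s$ where $n(w_j, c_k)$ sums the counts of
$w_j$ over labeled positives of $c_k$ and $s$ defaults to $1/M$ — enough
to keep rare classes' columns strictly positive without drowning the
signal. Unlabeled rows of $P(c|x)$ start at the labeled class prior;
labeled rows are clamped. A class with no labeled positive gets a uniform
column (with a warning) and a zero prior: the model cannot predict a
class it has never seen, which is the honest behavior.

## Label decisions

Scores are converted to relevant sets by the largest-gap rule: sort a
node's $K$ scores in decreasing order, find the largest difference
between successive values, and threshold at the midpoint of that pair.
The top label is always retained. Ties in the gap search go to the first
(highest-scoring) gap and score ties break by class order, so the rule is
deterministic.

## Latent graphs and the ensemble

* **ppi** — the interaction network itself.
* **rwr** — even-step random walk with restart: form the two-step counts
  $EE$, column-normalize to $\hat P$, accumulate
  $\sum_{t=1}^{T} a(1-a)^t \hat P^t$ (defaults $a = 0.1$, $T = 10$; the
  restart probability is unrelated to the regularization weight
  $\alpha$). Even steps keep the walk on one side of bipartite-like
  structure and reward triangle-closing neighbors. The accumulated matrix
  is not exactly symmetric, while the network regularizer assumes a
  symmetric weight; it is symmetrized as $(R + R^\top)/2$, which
  preserves column mass on symmetric inputs and changes nothing when the
  walk matrix is already symmetric.
* **predsim** — one-vs-rest probabilistic classifiers trained per class
  on labeled attribute rows score every node; the per-node confidence
  vectors are unit-scaled, pairwise cosine similarity is computed, and a
  binary kNN graph is kept under the symmetric "or" rule
  ($\hat E_{ij} = 1$ iff $i \in N_k(j)$ or $j \in N_k(i)$; default
  $k = 10$), which guarantees degree $\ge k$. The dense cosine weights
  are discarded after sparsification. The default base classifier is a
  ridge-penalized logistic regression (penalty parameter 1.0) — a linear
  probabilistic classifier chosen for exact reproducibility; an SVM
  wrapper with Platt-scaled probabilities is provided under the same
  contract, and any object with `train`/`predict` elements is accepted.

`egmsmcc()` fits one model per graph and averages the probability tables
elementwise (a mean of row-stochastic tables is row-stochastic), then
thresholds once; averaging raw probabilities and deciding labels at the
end keeps the components exchangeable. A "mean-graph" mode averages the
weight matrices and fits a single model instead. Components that fail to
converge are dropped from the average (with a warning) as long as one
remains.

## Evaluation metrics

Coverage (mean depth in the score-sorted label list needed to cover all
true labels, 0-based), ranking loss (fraction of positive–negative label
pairs wrongly ordered, *ties count as losses*, rows lacking either a
positive or a negative are excluded since the formula's normalizer is
undefined there), macro-F1 (per-label F1 averaged over labels, 0 when
precision + recall = 0), and single-label accuracy (top label vs. the one
true label). Rank ties break by class order. In experiment mode, metrics
are computed on the unlabeled nodes only.

## The synthetic generator

`smcc_simulate()` produces the statistical structure the regularizers
assume, not a replica of any particular biological dataset:

* **Labels** — independent single labels, or a Gaussian-copula threshold
  scheme for correlated multi-labels (thresholds set from
  `cardinality_mean`; empty draws are repaired to the highest latent
  class, which biases cardinality slightly upward).
* **Features** — each class has a Dirichlet(1) count profile over the
  `M` features; a node draws multinomial counts (length ~ Poisson(20))
  from a `feature_signal`-weighted blend of the uniform distribution and
  the mean profile of its classes. `feature_signal = 0` removes all
  attribute information.
* **Edges** — each of the `mean_degree · N / 2` edges joins a
  label-sharing pair with probability `homophily`, otherwise a
  non-sharing pair (sampled without replacement within each pool).
* **Mask** — a uniform `label_ratio` fraction of nodes keeps its labels.

The reference fixture (`smcc_sim_config()` defaults) is
$N = 300$, $K = 6$, $M = 40$, homophily 0.9, mean degree 6, 5% labeled,
single-label, feature signal 1 — sized so that a full fit takes on the
order of a second and multi-seed comparisons run in minutes. The
correlated companion fixture used for the label-regularizer checks is
$K = 4$, copula correlation 0.9, cardinality 2, feature signal 0.3
(weak features, so the ranking improvements must come from the label
structure). What the generator does *not* emulate: degree heterogeneity
(hubs), assortativity beyond label sharing, hierarchical label
structure, missing-at-random attribute noise, or the specific categorical
schema of real annotation datasets — so passing tests demonstrate correct
mechanics and the expected qualitative behavior of the regularizers, not
field performance on real interactomes.

## Known limitations

* The $\log x \approx 1 - 1/x$ M-step is a fixed-point approximation:
  the objective can plateau or wobble at the $10^{-4}$ level rather than
  increase monotonically; convergence is monitored, not guaranteed.
* Classes with no labeled positives are unreachable by design.
* The NK×NK solve is sparse but direct; very dense latent graphs at
  $N \gtrsim 10^4$ would need an iterative solver.
* Binary-relevance decomposition inside the prediction-similarity graph
  ignores label correlation; that graph is intentionally a *different*
  view, not a better single model.
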