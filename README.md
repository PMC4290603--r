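# smcc — semi-supervised multi-label collective classification on networks

`smcc` predicts the classes of nodes in a partially labeled, attributed
network. The motivating application is protein function prediction: given a
protein–protein interaction network, categorical protein attributes, and
functional annotations for only a few percent of the proteins, assign each
unannotated protein a ranked set of functional classes. The same machinery
applies to any networked dataset where instances carry count/indicator
features, labels are multi-label and scarce, and linked instances tend to
share labels (homophily).

## The model

Node attribute counts n(x_i, w_j) follow a pLSA mixture whose latent
components are pinned to the K classes:

    L = Σ_i Σ_j n(x_i, w_j) log Σ_k P(w_j | c_k) P(c_k | x_i)

Learning maximizes a regularized objective

    O = L − α R − β H

where

* **R** (network regularizer) is the symmetric Kullback–Leibler divergence
  between the class distributions z_i = P(·|x_i) of connected nodes,
  summed over ordered node pairs weighted by the (possibly weighted)
  adjacency: R = Σ_{i,s} D(z_i, z_s) E_is;
* **H** (label regularizer) is the symmetric-KL-shaped divergence between
  the per-class probability profiles r_k = (P(c_k|x_1), …, P(c_k|x_N)),
  weighted by the label affinity F_kl — the cosine similarity of the
  labeled indicator vectors of classes k and l: H = Σ_{k,l} D(r_k, r_l) F_kl.

Labeled nodes are *clamped*: their row of P(c|x) is fixed to the uniform
distribution over their known labels at initialization and after every
M-step, so supervision propagates outward through the likelihood and the
two smoothness terms. The EM algorithm keeps the standard pLSA E-step and
P(w|c) M-step; the P(c|x) M-step solves a sparse symmetric NK×NK linear
system combining the per-node total counts, the per-class graph Laplacian
(scaled by α), and the per-node label-affinity Laplacian (scaled by β).

Relevant labels are extracted per node by the largest-gap rule: sort the
scores, cut at the midpoint of the largest drop, keep everything above it.

The ensemble variant (`egmsmcc()`) fits one model per *latent graph* — the
interaction network itself, an even-step random-walk-with-restart graph
(which rewards triangle-closing and level-2 neighbors), and a kNN graph
over class-confidence vectors from a base classifier trained on labeled
attributes — and averages the fitted probability tables.

## Worked example

```r
library(smcc)

sim <- smcc_simulate(smcc_sim_config(seed = 42))
sim
#> Synthetic fixture (seed 42):
#> Networked dataset: 300 nodes, 900 edges, 40 features, 6 classes
#>   labeled: 15 (5.0%)
#>   measured homophily 0.891, mean label cardinality 1.00

fit <- gmsmcc(sim$dataset, alpha = 3, beta = 0)
fit
#> GM-SMCC fit (graph: ppi )
#>   N = 300 nodes, M = 40 features, K = 6 classes, 15 labeled
#>   alpha = 3, beta = 0; 20 EM iteration(s), converged
#>   objective -26114.7082 = loglik -21807.4361 - alpha*1435.7574 - beta*0.0000

predict(fit)
#> Score table: 300 nodes x 6 classes
#>        c1     c2     c3     c4     c5     c6 relevant
#> v1 0.5146 0.1100 0.1132 0.1003 0.0723 0.0896       c1
#> v2 0.1265 0.2076 0.0938 0.1592 0.2433 0.1695    c2;c5
#> v3 0.4552 0.1971 0.0877 0.0748 0.0828 0.1024       c1
#> ... 297 more rows

test <- !sim$dataset$labeled_mask
ml_accuracy(fitted(fit)[test, ], sim$truth[test, ])
#> [1] 0.9368421
ml_accuracy(fitted(gmsmcc(sim$dataset, alpha = 0, beta = 0))[test, ],
            sim$truth[test, ])
#> [1] 0.4877193
```

With only 15 labeled nodes, the pure attribute model (α = 0, plain
semi-supervised pLSA) reaches 0.49 test accuracy; switching on the network
regularizer at α = 3 nearly doubles it to 0.94 on this highly homophilous
fixture — the smoothing term is doing the collective-classification work.

A command-line interface wrapping the same functions lives at `exec/smcc`
(`smcc fit`, `smcc eval`, `smcc simulate`); see the header of that script
for flags, and `vignettes/gm-smcc-methods.Rmd` for the modeling details
and parameter guidance.

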