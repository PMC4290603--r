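#' Symmetric Kullback-Leibler divergence between two distributions
#'
#' Computes `(D(p||q) + D(q||p)) / 2` with natural logarithms after flooring
#' both vectors at `eps` and renormalizing — the distance used to smooth
#' class distributions over network edges and over correlated labels.
#' Flooring makes the divergence finite in the presence of the exact zeros
#' that labeled-node clamping creates.
#'
#' @param p,q nonnegative numeric vectors of equal length summing to 1
#'   (within 1e-6).
#' @param eps positive floor applied before renormalization.
#' @return a nonnegative scalar; 0 iff `p == q` after flooring.
#' @examples
#' symmetric_kl(c(0.8, 0.2), c(0.2, 0.8))  # 0.6 * log(4)
#' @export
symmetric_kl <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (!all(is.finite(p)) || !all(is.finite(q))) stop("non-finite input")
  if (any(p < 0) || any(q < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  stopifnot(eps > 0)
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  0.5 * sum((p - q) * (log(p) - log(q)))
}

## pLSA log-likelihood L = sum_ij n_ij log sum_k P(w_j|c_k) P(c_k|x_i).
## Cells with n_ij = 0 contribute nothing; a zero mixture under a positive
## count is floored at eps.

#' Regularized pLSA model components
#'
#' The three pieces of the fitting objective `O = L - alpha * R - beta * H`:
#' the count log-likelihood `L`, the network regularizer `R` (symmetric-KL
#' distance between the class distributions of connected nodes, summed over
#' ordered node pairs weighted by the graph), and the label regularizer `H`
#' (symmetric-KL-shaped distance between per-class probability profiles,
#' summed over ordered class pairs weighted by the label affinity). The
#' label profiles — columns of `P(c|x)` — enter the KL-shaped sum as
#' written, without renormalization; they are not distributions over nodes.
#'
#' @param dataset a [networked_dataset()].
#' @param p_w_given_c column-stochastic `M x K` matrix `P(w_j | c_k)`.
#' @param p_c_given_x row-stochastic `N x K` matrix `P(c_k | x_i)`.
#' @param graph a [latent_graph()] or symmetric nonnegative `N x N` matrix.
#' @param affinity symmetric nonnegative `K x K` label affinity (see
#'   [label_affinity()]).
#' @param alpha,beta nonnegative regularization weights for `R` and `H`.
#' @param eps positive probability floor.
#' @return `smcc_objective`: named numeric `c(objective, loglik, network,
#'   label)`. The component functions return scalars.
#' @seealso [gmsmcc()] which maximizes this objective by EM.
#' @export
smcc_objective <- function(dataset, p_w_given_c, p_c_given_x, graph,
                           affinity, alpha, beta, eps = 1e-12) {
  stopifnot(alpha >= 0, beta >= 0)
  L <- plsa_log_likelihood(dataset, p_w_given_c, p_c_given_x, eps = eps)
  R <- network_regularizer(p_c_given_x, graph, eps = eps)
  H <- label_regularizer(p_c_given_x, affinity, eps = eps)
  c(objective = L - alpha * R - beta * H, loglik = L, network = R, label = H)
}

#' @rdname smcc_objective
#' @export
plsa_log_likelihood <- function(dataset, p_w_given_c, p_c_given_x,
                                eps = 1e-12) {
  n <- dataset$counts
  mix <- p_c_given_x %*% t(p_w_given_c)  # N x M mixture P(w_j | x_i)
  pos <- n > 0
  if (!any(pos)) return(0)
  bad <- pos & mix <= 0
  if (any(bad)) {
    warning(sum(bad), " zero mixture cell(s) under positive counts floored")
    mix[bad] <- eps
  }
  sum(n[pos] * log(mix[pos]))
}

#' @rdname smcc_objective
#' @export
network_regularizer <- function(p_c_given_x, graph, eps = 1e-12) {
  w <- graph_weights(graph)
  z <- pmax(p_c_given_x, eps)
  z <- z / rowSums(z)
  if (nrow(w) != nrow(z)) stop("graph dimension does not match P(c|x)")
  lz <- log(z)
  deg <- Matrix::rowSums(w)
  # sum over ordered pairs of D(z_i, z_s) w_is; the 1/2 of the symmetric KL
  # cancels against the two orientations of each edge
  as.numeric(sum(deg * rowSums(z * lz)) - sum(z * (w %*% lz)))
}

#' @rdname smcc_objective
#' @export
label_regularizer <- function(p_c_given_x, affinity, eps = 1e-12) {
  f <- as.matrix(affinity)
  r <- pmax(p_c_given_x, eps)  # raw columns, floored, not renormalized
  if (ncol(r) != nrow(f)) stop("affinity dimension does not match P(c|x)")
  lr <- log(r)
  fdeg <- rowSums(f)
  sum(colSums(r * lr) * fdeg) - sum(r * (lr %*% f))
}

#' Label affinity from the labeled nodes
#'
#' Cosine similarity between the labeled-node indicator columns of each pair
#' of classes: `F_kl = Yhat_k' Yhat_l` with each column scaled to unit
#' Euclidean length. Classes with no labeled positive get a zero row and
#' column; every diagonal entry is set to 1 by convention.
#'
#' @param dataset a [networked_dataset()].
#' @return symmetric `K x K` matrix with entries in `[0, 1]`.
#' @export
label_affinity <- function(dataset) {
  y <- dataset$labels[dataset$labeled_mask, , drop = FALSE]
  norms <- sqrt(colSums(y^2))
  yhat <- sweep(y, 2, pmax(norms, 1), "/")  # zero-support columns stay zero
  f <- crossprod(yhat)
  diag(f) <- 1
  dimnames(f) <- list(dataset$class_names, dataset$class_names)
  f
}

## accept either a latent_graph or a bare matrix
graph_weights <- function(graph) {
  if (inherits(graph, "latent_graph")) graph$weights else graph
}
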