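#' Configuration for the synthetic network generator
#'
#' Describes a partially labeled attributed network with controllable
#' homophily, label correlation and feature signal — the statistical
#' structure the model's regularizers assume (connected nodes share
#' labels; correlated labels have similar per-node profiles). Defaults
#' describe the package's reference fixture: a 300-node, 6-class,
#' 40-feature single-label network with homophily 0.9, mean degree 6 and
#' 5% of nodes labeled.
#'
#' @param n_nodes,n_classes,n_features problem dimensions (N, K, M).
#' @param homophily probability in `[0, 1]` that an edge joins two nodes
#'   sharing at least one label.
#' @param mean_degree target mean node degree (must be `< n_nodes`).
#' @param label_correlation symmetric `K x K` latent-Gaussian correlation
#'   matrix driving correlated multi-label draws; `NULL` means independent
#'   labels.
#' @param feature_signal nonnegative separation of class-conditional
#'   feature-count profiles; 0 makes all classes indistinguishable from
#'   features.
#' @param label_ratio fraction of nodes whose labels are observed, in
#'   `(0, 1]`.
#' @param cardinality_mean expected number of labels per node (`>= 1`);
#'   1 gives single-label data.
#' @param doc_length mean total attribute count per node (Poisson).
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   dataset exactly.
#' @return an object of class `smcc_sim_config`.
#' @export
smcc_sim_config <- function(n_nodes = 300L, n_classes = 6L,
                            n_features = 40L, homophily = 0.9,
                            mean_degree = 6, label_correlation = NULL,
                            feature_signal = 1, label_ratio = 0.05,
                            cardinality_mean = 1, doc_length = 20,
                            seed = 1L) {
  stopifnot(n_nodes >= 2, n_classes >= 1, n_features >= 1,
            homophily >= 0, homophily <= 1,
            mean_degree > 0, label_ratio > 0, label_ratio <= 1,
            cardinality_mean >= 1, cardinality_mean <= n_classes,
            feature_signal >= 0, doc_length > 0)
  if (mean_degree >= n_nodes)
    stop("mean_degree must be smaller than n_nodes")
  if (!is.null(label_correlation)) {
    label_correlation <- as.matrix(label_correlation)
    stopifnot(nrow(label_correlation) == n_classes,
              isSymmetric(label_correlation))
  }
  structure(as.list(environment()), class = "smcc_sim_config")
}

#' Generate a synthetic partially labeled attributed network
#'
#' Samples per-node label sets (independent, or through a Gaussian-copula
#' threshold scheme when `label_correlation` is given), class-conditional
#' attribute counts (multinomial draws from profiles mixed toward each
#' node's classes by `feature_signal`), and edges that join label-sharing
#' node pairs with probability `homophily`, until the target mean degree
#' is reached. All but a `label_ratio` fraction of nodes are masked.
#'
#' @param config a [smcc_sim_config()].
#' @return list of class `smcc_sim` with `dataset` (a
#'   [networked_dataset()] whose unlabeled rows are zeroed), `truth` (the
#'   full binary `N x K` label matrix) and `config`.
#' @examples
#' sim <- smcc_simulate(smcc_sim_config(n_nodes = 50, n_classes = 3,
#'                                      n_features = 10, seed = 7))
#' sim$dataset
#' measure_homophily(sim)
#' @export
smcc_simulate <- function(config) {
  stopifnot(inherits(config, "smcc_sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_nodes; K <- config$n_classes; M <- config$n_features

  ## --- labels --------------------------------------------------------------
  if (config$cardinality_mean == 1 && is.null(config$label_correlation)) {
    lab <- sample.int(K, n, replace = TRUE)
    truth <- matrix(0, n, K)
    truth[cbind(seq_len(n), lab)] <- 1
  } else {
    sigma <- config$label_correlation %||% diag(K)
    z <- matrix(stats::rnorm(n * K), n, K) %*% chol(sigma)
    tau <- stats::qnorm(1 - config$cardinality_mean / K)
    truth <- 1 * (z > tau)
    empty <- rowSums(truth) == 0
    if (any(empty))
      truth[cbind(which(empty), apply(z[empty, , drop = FALSE], 1,
                                      which.max))] <- 1
  }

  ## --- features ------------------------------------------------------------
  profiles <- matrix(stats::rgamma(K * M, 1), K, M)
  profiles <- profiles / rowSums(profiles)
  mix <- (truth / rowSums(truth)) %*% profiles  # per-node class profile
  s <- config$feature_signal
  p <- (matrix(1 / M, n, M) + s * mix) / (1 + s)
  len <- pmax(1L, stats::rpois(n, config$doc_length))
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, len[i], p[i, ])[, 1],
                     integer(M)))

  ## --- edges ---------------------------------------------------------------
  share <- tcrossprod(truth) > 0
  ut <- upper.tri(share)
  same_pool <- which(ut & share)
  diff_pool <- which(ut & !share)
  target <- round(config$mean_degree * n / 2)
  n_same <- stats::rbinom(1, target, config$homophily)
  if (config$homophily == 1) n_same <- target
  if (config$homophily == 0) n_same <- 0L
  n_same <- min(n_same, length(same_pool))
  n_diff <- min(target - n_same, length(diff_pool))
  picks <- c(if (n_same > 0) sample(same_pool, n_same),
             if (n_diff > 0) sample(diff_pool, n_diff))
  adj <- matrix(0, n, n)
  adj[picks] <- 1
  adj <- adj + t(adj)

  ## --- labeled mask --------------------------------------------------------
  n_lab <- max(1L, round(config$label_ratio * n))
  mask <- rep(FALSE, n)
  mask[sample.int(n, n_lab)] <- TRUE
  labels <- truth
  labels[!mask, ] <- 0

  dataset <- networked_dataset(adj, counts, labels, mask)
  dimnames(truth) <- dimnames(dataset$labels)
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "smcc_sim")
}

#' @export
print.smcc_sim <- function(x, ...) {
  cat("Synthetic fixture (seed ", x$config$seed, "):\n", sep = "")
  print(x$dataset)
  cat(sprintf("  measured homophily %.3f, mean label cardinality %.2f\n",
              measure_homophily(x), mean(rowSums(x$truth))))
  invisible(x)
}

#' Fraction of edges joining label-sharing nodes
#'
#' @param x a `smcc_sim` object, or a [networked_dataset()] when `truth`
#'   is supplied.
#' @param truth binary `N x K` full label matrix (ignored for `smcc_sim`).
#' @return scalar in `[0, 1]`.
#' @export
measure_homophily <- function(x, truth = NULL) {
  if (inherits(x, "smcc_sim")) {
    truth <- x$truth
    x <- x$dataset
  }
  adj <- as.matrix(graph_weights(if (inherits(x, "networked_dataset"))
    x$adjacency else x))
  edges <- which(upper.tri(adj) & adj != 0)
  if (length(edges) == 0) stop("no edges in the graph")
  share <- tcrossprod(truth) > 0
  mean(share[edges])
}
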