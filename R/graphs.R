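#' Latent graphs for the ensemble
#'
#' A latent graph is a symmetric nonnegative `N x N` weight matrix over the
#' dataset's nodes, tagged with its construction (`kind`). Three
#' constructors are provided:
#' * [ppi_graph()] — the interaction network itself;
#' * [rwr_graph()] — an even-step random walk with restart over the
#'   two-step transition structure, which favors triangle-closing and
#'   level-2 neighbors;
#' * [predsim_graph()] — a kNN graph over per-node class-confidence vectors
#'   from a probabilistic base classifier trained on the labeled nodes.
#'
#' @param weights symmetric nonnegative finite `N x N` matrix; zero diagonal
#'   required for kinds `ppi` and `predsim`.
#' @param kind one of `"ppi"`, `"rwr"`, `"predsim"`.
#' @param params list of construction parameters kept for provenance.
#' @return an object of class `latent_graph`.
#' @export
latent_graph <- function(weights, kind = c("ppi", "rwr", "predsim"),
                         params = list()) {
  kind <- match.arg(kind)
  weights <- Matrix::Matrix(weights, sparse = TRUE)
  if (!isSymmetric(unname(as.matrix(weights)), tol = 1e-12))
    stop("latent graph weights must be symmetric")
  weights <- methods::as(methods::as(weights, "generalMatrix"),
                         "CsparseMatrix")
  if (any(!is.finite(weights@x)) || any(weights@x < 0))
    stop("latent graph weights must be finite and nonnegative")
  if (kind %in% c("ppi", "predsim") && any(Matrix::diag(weights) != 0))
    stop("kind '", kind, "' requires a zero diagonal")
  structure(list(weights = weights, kind = kind, params = params),
            class = "latent_graph")
}

#' @export
print.latent_graph <- function(x, ...) {
  cat("Latent graph (", x$kind, "): ", nrow(x$weights), " nodes, ",
      sum(x$weights != 0), " nonzero entries\n", sep = "")
  invisible(x)
}

#' @rdname latent_graph
#' @param dataset a [networked_dataset()].
#' @export
ppi_graph <- function(dataset) {
  latent_graph(dataset$adjacency, "ppi")
}

#' Even-step random-walk-with-restart latent graph
#'
#' Forms the two-step reachability counts `EE` from the adjacency `E`,
#' column-normalizes them into a transition matrix `Phat` (zero columns are
#' left zero, with a message), accumulates
#' `R = sum_{t=1..T} restart * (1 - restart)^t * Phat^t`, and symmetrizes
#' the result as `(R + R') / 2` so it can feed the symmetric network
#' regularizer. Restricting the walk to even steps keeps it on the same
#' side of bipartite-like structures and rewards triangle-closing
#' neighbors.
#'
#' @inheritParams ppi_graph
#' @param restart restart probability in (0, 1); default 0.1.
#' @param steps number of accumulated walk steps `T >= 1`; default 10.
#' @return a [latent_graph()] of kind `"rwr"`.
#' @export
rwr_graph <- function(dataset, restart = 0.1, steps = 10L) {
  stopifnot(restart > 0, restart < 1, steps >= 1)
  e <- as.matrix(dataset$adjacency)
  p <- e %*% e  # two-step walk counts
  csum <- colSums(p)
  zero <- csum == 0
  if (any(zero)) {
    message(sum(zero), " node(s) unreachable by two-step walks; ",
            "their columns stay zero")
    csum[zero] <- 1
  }
  phat <- sweep(p, 2, csum, "/")
  acc <- matrix(0, nrow(e), ncol(e))
  pt <- diag(nrow(e))
  for (t in seq_len(steps)) {
    pt <- phat %*% pt
    acc <- acc + restart * (1 - restart)^t * pt
  }
  w <- (acc + t(acc)) / 2
  dimnames(w) <- dimnames(e)
  latent_graph(w, "rwr", params = list(restart = restart, steps = steps))
}

#' Prediction-similarity kNN latent graph
#'
#' Trains one one-vs-rest probabilistic classifier per class on the labeled
#' nodes' attribute counts, scores every node, scales each node's
#' confidence vector to unit length, and connects `v_i` and `v_j` when
#' either is among the other's `k` nearest neighbors by cosine similarity
#' (a symmetric "or" rule). The resulting adjacency is binary with zero
#' diagonal. Classes whose labeled nodes are all positive or all negative
#' get a constant confidence equal to the labeled prior (with a message).
#'
#' @inheritParams ppi_graph
#' @param k number of nearest neighbors (`1 <= k < N`); default 10.
#' @param classifier a base classifier contract as returned by
#'   [ridge_classifier()] or [svm_classifier()]: a list with
#'   `train(x, y)` returning a model and `predict(model, x)` returning
#'   positive-class probabilities.
#' @return a [latent_graph()] of kind `"predsim"`.
#' @export
predsim_graph <- function(dataset, k = 10L, classifier = ridge_classifier()) {
  n <- length(dataset$node_ids)
  stopifnot(k >= 1, k < n)
  x <- dataset$counts
  mask <- dataset$labeled_mask
  conf <- sapply(seq_len(ncol(dataset$labels)), function(kk) {
    y <- dataset$labels[mask, kk]
    if (length(unique(y)) < 2) {
      message("class ", dataset$class_names[kk],
              " has one-sided labels; constant confidence = labeled prior")
      return(rep(mean(y), n))
    }
    fit <- tryCatch(classifier$train(x[mask, , drop = FALSE], y),
                    error = function(e) NULL)
    if (is.null(fit)) {
      message("base classifier failed for class ", dataset$class_names[kk],
              "; constant confidence = labeled prior")
      return(rep(mean(y), n))
    }
    as.numeric(classifier$predict(fit, x))
  })
  norms <- sqrt(rowSums(conf^2))
  flat <- norms == 0
  if (any(flat)) {
    message(sum(flat), " node(s) with all-zero confidences; set uniform")
    conf[flat, ] <- 1
    norms[flat] <- sqrt(ncol(conf))
  }
  sim <- tcrossprod(conf / norms)
  diag(sim) <- -Inf  # exclude self from neighborhoods
  # N_k(j): k largest similarities, ties broken by node order
  nn <- apply(sim, 1, function(s) order(-s, seq_along(s))[seq_len(k)])
  adj <- matrix(0, n, n)
  adj[cbind(rep(seq_len(n), each = k), as.vector(nn))] <- 1
  adj <- 1 * ((adj + t(adj)) > 0)  # i in N_k(j) OR j in N_k(i)
  diag(adj) <- 0
  latent_graph(adj, "predsim", params = list(k = k))
}

#' Base classifiers for the prediction-similarity graph
#'
#' Both return the caller-supplied classifier contract consumed by
#' [predsim_graph()]. `ridge_classifier()` (the default) is a ridge-penalized
#' logistic regression — a linear probabilistic classifier with penalty
#' parameter `cost` — and is fully deterministic. `svm_classifier()` wraps a
#' linear-kernel SVM with Platt-scaled probability outputs (requires the
#' `e1071` package).
#'
#' @param cost penalty parameter of the linear classifier; default 1.
#' @return list with elements `train(x, y)` and `predict(model, x)`.
#' @export
ridge_classifier <- function(cost = 1) {
  list(
    train = function(x, y) {
      suppressWarnings(  # small labeled sets are the normal regime here
        glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                       alpha = 0, lambda = 1 / (cost * length(y)),
                       standardize = FALSE))
    },
    predict = function(model, x) {
      as.numeric(stats::predict(model, newx = x, type = "response"))
    })
}

#' @rdname ridge_classifier
#' @export
svm_classifier <- function(cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("svm_classifier() requires the e1071 package")
  list(
    train = function(x, y) {
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = cost, probability = TRUE)
    },
    predict = function(model, x) {
      pr <- attr(stats::predict(model, x, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    })
}
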