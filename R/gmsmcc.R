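#' Fit a graph- and label-regularized semi-supervised pLSA model
#'
#' `gmsmcc()` fits the generative collective-classification model: node
#' attribute counts follow a pLSA mixture
#' `P(x_i, w_j) = P(x_i) sum_k P(w_j | c_k) P(c_k | x_i)` whose latent
#' components are the `K` functional classes, and the class-membership
#' table `P(c|x)` is smoothed over the network (weight `alpha`) and over
#' correlated labels (weight `beta`). Labeled nodes are clamped to the
#' uniform distribution over their known labels at initialization and after
#' every M-step, so supervision propagates to unlabeled nodes through the
#' likelihood and the regularizers.
#'
#' The EM alternates the pLSA E-step, the standard M-step for `P(w|c)`, and
#' a regularized M-step for `P(c|x)` obtained from the stationarity
#' conditions under the first-order approximation `log x ~ 1 - 1/x`: a
#' sparse symmetric `NK x NK` linear system
#' `(Omega + alpha (D - B) + beta (U - R)) y = Z`, where `Omega` holds the
#' per-node total counts, `D - B` is the per-class graph Laplacian and
#' `U - R` the per-node label-affinity Laplacian. Iteration stops when the
#' relative change of the objective falls below `tol`.
#'
#' @param dataset a [networked_dataset()].
#' @param graph network to smooth over: a [latent_graph()] or symmetric
#'   nonnegative matrix; defaults to the dataset's own interaction network.
#' @param alpha nonnegative network-regularizer weight (default 3).
#' @param beta nonnegative label-regularizer weight (default 0.1).
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations,
#'   stop when `|O(t+1) - O(t)| / |O(t)| < tol`.
#' @param eps probability floor used in the likelihood, the KL terms and
#'   when repairing the linear-system solution (the approximation does not
#'   guarantee nonnegativity).
#' @param smoothing additive smoothing for the `P(w|c)` initialization
#'   counts; defaults to `1/M`.
#' @param keep_history if `TRUE`, stores the parameter tables after every
#'   iteration (for diagnostics; memory grows with `max_iter`).
#' @param verbose print the objective per iteration.
#' @return An object of class `gmsmcc` with components `p_w_given_c`
#'   (`M x K`, column-stochastic), `p_c_given_x` (`N x K`, row-stochastic,
#'   labeled rows clamped), `trace` (data frame of per-iteration objective,
#'   log-likelihood and regularizer values), `converged`, `n_iter`, the
#'   weights, the affinity, and the call. Methods: `print`, `summary`,
#'   `coef`, `fitted`, `predict`, `logLik`, `plot`.
#' @examples
#' sim <- smcc_simulate(smcc_sim_config(n_nodes = 60, n_classes = 3,
#'                                      n_features = 12, seed = 1))
#' fit <- gmsmcc(sim$dataset, alpha = 3, beta = 0)
#' fit
#' head(fitted(fit))
#' @export
gmsmcc <- function(dataset, graph = NULL, alpha = 3, beta = 0.1,
                   max_iter = 50L, tol = 1e-4, eps = 1e-12,
                   smoothing = NULL, keep_history = FALSE, verbose = FALSE) {
  stopifnot(inherits(dataset, "networked_dataset"),
            alpha >= 0, beta >= 0, max_iter >= 1, tol > 0, eps > 0)
  graph <- graph %||% ppi_graph(dataset)
  w <- graph_weights(graph)
  if (nrow(w) != length(dataset$node_ids))
    stop("graph does not match the dataset's node set")
  smoothing <- smoothing %||% (1 / ncol(dataset$counts))
  affinity <- label_affinity(dataset)

  params <- init_params(dataset, smoothing = smoothing)
  lap_graph <- laplacian(w)
  lap_label <- laplacian(affinity)
  rho <- rowSums(dataset$counts)

  trace <- matrix(NA_real_, max_iter, 4,
                  dimnames = list(NULL, c("objective", "loglik",
                                          "network", "label")))
  history <- if (keep_history) vector("list", max_iter)
  converged <- FALSE
  obj_prev <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    post <- e_step(dataset, params)
    pwc <- m_step_pwc(dataset, post)
    pcx <- m_step_pcx(dataset, post, lap_graph, lap_label, rho,
                      alpha = alpha, beta = beta, eps = eps)
    params <- list(p_w_given_c = pwc, p_c_given_x = pcx)
    o <- smcc_objective(dataset, pwc, pcx, w, affinity, alpha, beta,
                        eps = eps)
    if (!all(is.finite(o)))
      stop("non-finite objective at iteration ", it,
           " (O = ", o[["objective"]], ")")
    trace[it, ] <- o
    if (keep_history) history[[it]] <- params
    if (verbose)
      message(sprintf("iter %2d  O = %.6f  L = %.6f  R = %.6f  H = %.6f",
                      it, o[1], o[2], o[3], o[4]))
    if (it > 1 &&
        abs(o[["objective"]] - obj_prev) / abs(obj_prev) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- o[["objective"]]
  }

  structure(
    list(p_w_given_c = params$p_w_given_c,
         p_c_given_x = params$p_c_given_x,
         trace = as.data.frame(cbind(iteration = seq_len(it),
                                     trace[seq_len(it), , drop = FALSE])),
         converged = converged, n_iter = it,
         alpha = alpha, beta = beta, tol = tol, eps = eps,
         affinity = affinity, graph_kind = graph_kind(graph),
         dataset = dataset,
         history = if (keep_history) history[seq_len(it)],
         call = match.call()),
    class = "gmsmcc")
}

graph_kind <- function(graph) {
  if (inherits(graph, "latent_graph")) graph$kind else "custom"
}

## --- EM internals ----------------------------------------------------------

## Clamp labeled rows of P(c|x) to the uniform distribution over the node's
## known labels; unlabeled rows untouched. Idempotent.
clamp_labeled <- function(p_c_given_x, dataset) {
  idx <- which(dataset$labeled_mask)
  y <- dataset$labels[idx, , drop = FALSE]
  p_c_given_x[idx, ] <- y / rowSums(y)
  p_c_given_x
}

## Initialize P(w|c) from smoothed labeled class-conditional counts and
## P(c|x) from the labeled class prior; clamp labeled rows.
init_params <- function(dataset, smoothing) {
  n <- dataset$counts
  y <- dataset$labels
  mask <- dataset$labeled_mask
  K <- ncol(y)
  yl <- y * mask  # zero out unlabeled rows
  nwc <- t(n) %*% yl  # M x K: counts of w_j over labeled positives of c_k
  empty <- colSums(yl) == 0
  if (any(empty))
    warning(sum(empty), " class(es) without labeled positives; ",
            "their P(w|c) column is uniform after smoothing")
  pwc <- nwc + smoothing
  pwc <- sweep(pwc, 2, colSums(pwc), "/")

  prior <- colSums(yl) / sum(yl)
  pcx <- matrix(prior, nrow(n), K, byrow = TRUE)
  pcx <- clamp_labeled(pcx, dataset)
  dimnames(pwc) <- list(dataset$feature_names, dataset$class_names)
  dimnames(pcx) <- list(dataset$node_ids, dataset$class_names)
  list(p_w_given_c = pwc, p_c_given_x = pcx)
}

## E-step: posterior P(c_k | x_i, w_j) = P(w_j|c_k) P(c_k|x_i) / mix_ij.
## The N x M x K tensor is never materialized; the object carries the
## count/mixture ratio from which both M-steps read their weighted sums,
## and posterior_at() evaluates single cells on demand.
e_step <- function(dataset, params) {
  pwc <- params$p_w_given_c
  pcx <- params$p_c_given_x
  mix <- pcx %*% t(pwc)  # N x M
  ratio <- dataset$counts / mix
  ratio[dataset$counts == 0] <- 0  # only cells with n > 0 are consumed
  degenerate <- which(dataset$counts > 0 & mix <= 0, arr.ind = TRUE)
  if (nrow(degenerate)) {
    warning(nrow(degenerate), " cell(s) with zero posterior denominator; ",
            "uniform posterior used there")
    ratio[degenerate] <- 0  # their n_ij / K mass is re-added by the M-steps
  }
  structure(list(p_w_given_c = pwc, p_c_given_x = pcx, ratio = ratio,
                 mix = mix, degenerate = degenerate,
                 counts = dataset$counts),
            class = "smcc_posterior")
}

## Posterior vector over classes at cell (i, j); uniform if degenerate.
posterior_at <- function(post, i, j) {
  num <- post$p_w_given_c[j, ] * post$p_c_given_x[i, ]
  s <- sum(num)
  if (s <= 0) {
    warning("zero posterior denominator at cell (", i, ",", j,
            "); uniform posterior used")
    return(rep(1 / length(num), length(num)))
  }
  num / s
}

## M-step for P(w|c): P(w_j|c_k) oc sum_i n_ij post_ijk; columns normalized.
m_step_pwc <- function(dataset, post) {
  num <- post$p_w_given_c * (t(post$ratio) %*% post$p_c_given_x)  # M x K
  if (nrow(post$degenerate)) {
    K <- ncol(num)
    for (r in seq_len(nrow(post$degenerate))) {
      cell <- post$degenerate[r, ]
      num[cell[2], ] <- num[cell[2], ] + post$counts[cell[1], cell[2]] / K
    }
  }
  tot <- colSums(num)
  empty <- tot <= 0
  if (any(empty)) {
    warning(sum(empty), " empty class(es) in M-step; column(s) left unchanged")
    num[, empty] <- post$p_w_given_c[, empty]
    tot[empty] <- 1
  }
  sweep(num, 2, tot, "/")
}

## Graph Laplacian diag(rowSums) - W as sparse symmetric matrix.
laplacian <- function(w) {
  w <- methods::as(Matrix::Matrix(w, sparse = TRUE), "generalMatrix")
  Matrix::Diagonal(x = Matrix::rowSums(w)) - w
}

## Build the class-major stacked linear system of the regularized M-step:
## A = Omega + alpha (I_K ox L_graph) + beta (L_label ox I_N), right-hand
## side Z_k[i] = sum_j n_ij post_ijk. Omega's diagonal repeats the per-node
## total counts rho_i across the K class blocks.
build_mstep_system <- function(dataset, post, lap_graph, lap_label,
                               alpha, beta) {
  z <- post$p_c_given_x * (post$ratio %*% post$p_w_given_c)  # N x K
  n <- nrow(z); K <- ncol(z)
  if (nrow(post$degenerate)) {
    for (r in seq_len(nrow(post$degenerate))) {
      cell <- post$degenerate[r, ]
      z[cell[1], ] <- z[cell[1], ] + post$counts[cell[1], cell[2]] / K
    }
  }
  rho <- rowSums(z)
  a <- Matrix::Diagonal(x = rep(rho, K))
  if (alpha > 0)
    a <- a + alpha * Matrix::kronecker(Matrix::Diagonal(K), lap_graph)
  if (beta > 0)
    a <- a + beta * Matrix::kronecker(lap_label, Matrix::Diagonal(n))
  list(A = a, Z = z, rho = rho)
}

## Solve for P(c|x): sparse symmetric solve, unstack, floor, renormalize,
## clamp labeled rows. Nodes with rho = 0 (all-zero count rows) keep their
## previous value via an identity row in the system.
m_step_pcx <- function(dataset, post, lap_graph, lap_label, rho_counts,
                       alpha, beta, eps) {
  sys <- build_mstep_system(dataset, post, lap_graph, lap_label, alpha, beta)
  n <- nrow(sys$Z); K <- ncol(sys$Z)
  # rho identity: posterior sums to 1 over classes, so Omega's diagonal must
  # reproduce the per-node total counts
  if (max(abs(sys$rho - rho_counts)) > 1e-8 * max(1, max(rho_counts)))
    stop("posterior normalization violated when building Omega")
  zvec <- as.numeric(sys$Z)  # column-major = class-major stacking
  a <- sys$A
  # rho_i = 0 with no graph coupling makes the node's equations singular;
  # pin those rows to their previous value
  deg <- alpha * Matrix::diag(lap_graph)
  dead <- which(sys$rho <= 0 & deg <= 0)
  if (length(dead)) {
    warning(length(dead), " node(s) with zero total counts; ",
            "previous P(c|x) retained")
    idx <- as.vector(outer(dead, (seq_len(K) - 1L) * n, `+`))
    d <- Matrix::Diagonal(n * K, x = replace(numeric(n * K), idx, 1))
    a <- a + d
    zvec[idx] <- as.numeric(post$p_c_given_x)[idx]
  }
  y <- as.numeric(Matrix::solve(a, zvec))
  pcx <- matrix(y, n, K, dimnames = dimnames(post$p_c_given_x))
  pcx <- pmax(pcx, eps)
  pcx <- pcx / rowSums(pcx)
  clamp_labeled(pcx, dataset)
}

## --- methods ---------------------------------------------------------------

#' @export
print.gmsmcc <- function(x, ...) {
  d <- dim(x$dataset)
  cat("GM-SMCC fit (graph:", x$graph_kind, ")\n")
  cat(sprintf("  N = %d nodes, M = %d features, K = %d classes, %d labeled\n",
              d[1], d[2], d[3], sum(x$dataset$labeled_mask)))
  cat(sprintf("  alpha = %g, beta = %g; %d EM iteration(s), %s\n",
              x$alpha, x$beta, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  objective %.4f = loglik %.4f - alpha*%.4f - beta*%.4f\n",
              last$objective, last$loglik, last$network, last$label))
  invisible(x)
}

#' @export
summary.gmsmcc <- function(object, ...) {
  structure(list(fit = object,
                 pred = predict(object)),
            class = "summary.gmsmcc")
}

#' @export
print.summary.gmsmcc <- function(x, ...) {
  print(x$fit)
  card <- lengths(x$pred$relevant)
  cat(sprintf("  relevant-label cardinality: mean %.2f (range %d-%d)\n",
              mean(card), min(card), max(card)))
  invisible(x)
}

#' @export
coef.gmsmcc <- function(object, ...) {
  list(p_w_given_c = object$p_w_given_c, p_c_given_x = object$p_c_given_x)
}

#' @export
fitted.gmsmcc <- function(object, ...) object$p_c_given_x

#' @export
logLik.gmsmcc <- function(object, ...) {
  structure(object$trace$loglik[nrow(object$trace)],
            df = prod(dim(object$p_w_given_c)) +
              prod(dim(object$p_c_given_x)),
            class = "logLik")
}

#' Predicted label scores and relevant-label sets
#'
#' Returns the fitted `P(c|x)` as a [score_table()], with per-node relevant
#' labels from the largest-gap thresholding rule.
#'
#' @param object a fitted [gmsmcc()] (or [egmsmcc()]) model.
#' @param ... unused.
#' @return a [score_table()].
#' @export
predict.gmsmcc <- function(object, ...) {
  score_table(object$p_c_given_x, class_names = object$dataset$class_names,
              node_ids = object$dataset$node_ids)
}

#' @export
plot.gmsmcc <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$objective, type = "b",
                 xlab = "EM iteration", ylab = "objective O", ...)
  invisible(x)
}
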