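#' Ensemble of graph-regularized models over multiple latent graphs
#'
#' Fits one [gmsmcc()] model per latent graph — each computing its network
#' regularizer on its own graph — and combines the fitted `P(c|x)` tables
#' by an elementwise arithmetic mean (`mode = "average-models"`, the
#' default). The alternative `mode = "average-graphs"` first averages the
#' graphs' weight matrices into a single graph and fits once (the
#' "mean-graph" variant). Relevant labels are extracted once, from the
#' combined scores.
#'
#' @param dataset a [networked_dataset()].
#' @param graphs either a character vector naming constructors among
#'   `"ppi"`, `"rwr"`, `"predsim"` (built with their default parameters),
#'   or a list of [latent_graph()] objects over the same node set.
#' @param alpha,beta regularization weights passed to every component fit.
#' @param mode `"average-models"` or `"average-graphs"`.
#' @param ... further arguments passed to [gmsmcc()] (`max_iter`, `tol`,
#'   `eps`, ...).
#' @return An object of class `egmsmcc` (inheriting the prediction methods
#'   of `gmsmcc`): `p_c_given_x` is the averaged score table, `components`
#'   the per-graph fits with their provenance, `graph_kinds` their kinds.
#'   Components that fail to converge are dropped from the average with a
#'   warning as long as at least one converged.
#' @examples
#' sim <- smcc_simulate(smcc_sim_config(n_nodes = 60, n_classes = 3,
#'                                      n_features = 12, seed = 1))
#' ens <- egmsmcc(sim$dataset, graphs = c("ppi", "rwr"), beta = 0)
#' ens
#' @export
egmsmcc <- function(dataset, graphs = c("ppi", "rwr", "predsim"),
                    alpha = 3, beta = 0.1,
                    mode = c("average-models", "average-graphs"), ...) {
  mode <- match.arg(mode)
  if (is.character(graphs)) {
    graphs <- lapply(graphs, function(g) {
      switch(g,
             ppi = ppi_graph(dataset),
             rwr = rwr_graph(dataset),
             predsim = predsim_graph(dataset),
             stop("unknown graph kind: ", g))
    })
  }
  stopifnot(length(graphs) >= 1,
            all(vapply(graphs, inherits, logical(1), "latent_graph")))

  if (mode == "average-graphs") {
    w <- Reduce(`+`, lapply(graphs, function(g) g$weights)) / length(graphs)
    Matrix::diag(w) <- 0  # self-weights are inert in the regularizer
    fit <- gmsmcc(dataset, graph = w, alpha = alpha, beta = beta, ...)
    fits <- list(fit)
  } else {
    fits <- lapply(graphs, function(g)
      gmsmcc(dataset, graph = g, alpha = alpha, beta = beta, ...))
    ok <- vapply(fits, `[[`, logical(1), "converged")
    if (!any(ok)) stop("no ensemble component converged")
    if (!all(ok)) {
      warning(sum(!ok), " non-converged component(s) dropped from the average")
      fits <- fits[ok]
    }
  }
  scores <- Reduce(`+`, lapply(fits, `[[`, "p_c_given_x")) / length(fits)

  structure(
    list(p_c_given_x = scores,
         components = fits,
         graph_kinds = vapply(fits, `[[`, character(1), "graph_kind"),
         mode = mode, alpha = alpha, beta = beta,
         dataset = dataset, call = match.call()),
    class = c("egmsmcc", "gmsmcc"))
}

#' @export
print.egmsmcc <- function(x, ...) {
  d <- dim(x$dataset)
  cat("EGM-SMCC ensemble (", x$mode, ") over ",
      length(x$components), " graph(s): ",
      paste(x$graph_kinds, collapse = ", "), "\n", sep = "")
  cat(sprintf("  N = %d, M = %d, K = %d, alpha = %g, beta = %g\n",
              d[1], d[2], d[3], x$alpha, x$beta))
  invisible(x)
}

#' @export
fitted.egmsmcc <- function(object, ...) object$p_c_given_x

#' @export
logLik.egmsmcc <- function(object, ...) {
  stop("the ensemble average has no single likelihood; ",
       "see logLik of the components")
}
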