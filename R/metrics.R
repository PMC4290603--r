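#' Multi-label evaluation metrics
#'
#' The ranking-based and set-based measures used to evaluate multi-label
#' node classification:
#' * `ml_coverage` — how far down the score-sorted label list one must go,
#'   on average, to cover all true labels of a node:
#'   `mean_i (max_{c in Y_i} rank(x_i, c) - 1)`, rank 1 = highest score.
#' * `ml_ranking_loss` — average fraction of (positive, negative) label
#'   pairs ordered wrongly, counting ties as reversals
#'   (`score(c+) <= score(c-)`); rows without both a positive and a
#'   negative label are skipped with a message.
#' * `ml_macro_f1` — per-label F1 (harmonic mean of precision and recall,
#'   0 when precision + recall = 0) averaged over labels, computed on
#'   binary predicted label sets.
#' * `ml_accuracy` — single-label mode: fraction of nodes whose top-scoring
#'   label is the true label (truth must have exactly one positive per
#'   row).
#'
#' Rank ties are broken by stable class order throughout.
#'
#' @param scores numeric `N x K` score matrix (any monotone scale).
#' @param truth binary `N x K` matrix of true labels.
#' @param predicted binary `N x K` matrix of predicted labels, or a
#'   [score_table()] whose relevant sets are used.
#' @return a scalar; `ml_macro_f1` also carries a `per_label` attribute
#'   with the K precision/recall pairs.
#' @export
ml_coverage <- function(scores, truth) {
  check_metric_input(scores, truth)
  if (any(rowSums(truth) == 0)) stop("every truth row needs >= 1 positive")
  mean(vapply(seq_len(nrow(scores)), function(i) {
    r <- score_ranks(scores[i, ])
    max(r[truth[i, ] == 1]) - 1
  }, numeric(1)))
}

#' @rdname ml_coverage
#' @export
ml_ranking_loss <- function(scores, truth) {
  check_metric_input(scores, truth)
  pos_n <- rowSums(truth)
  ok <- pos_n >= 1 & pos_n < ncol(truth)
  if (!all(ok))
    message(sum(!ok), " row(s) without both positive and negative labels skipped")
  if (!any(ok)) stop("no row with both positive and negative labels")
  mean(vapply(which(ok), function(i) {
    sp <- scores[i, truth[i, ] == 1]
    sn <- scores[i, truth[i, ] == 0]
    sum(outer(sp, sn, `<=`)) / (length(sp) * length(sn))
  }, numeric(1)))
}

#' @rdname ml_coverage
#' @export
ml_macro_f1 <- function(predicted, truth) {
  predicted <- as_binary_predictions(predicted, truth)
  check_metric_input(predicted, truth)
  prf <- t(vapply(seq_len(ncol(truth)), function(k) {
    tp <- sum(predicted[, k] == 1 & truth[, k] == 1)
    p <- if (sum(predicted[, k]) > 0) tp / sum(predicted[, k]) else 0
    r <- if (sum(truth[, k]) > 0) tp / sum(truth[, k]) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }, numeric(3)))
  structure(mean(prf[, "f1"]), per_label = prf)
}

#' @rdname ml_coverage
#' @export
ml_accuracy <- function(scores, truth) {
  check_metric_input(scores, truth)
  if (!all(rowSums(truth) == 1))
    stop("accuracy is a single-label metric: truth needs exactly one ",
         "positive per row")
  top <- apply(scores, 1, which.max)  # stable: first max wins
  mean(truth[cbind(seq_len(nrow(truth)), top)] == 1)
}

#' Evaluate fitted scores against full ground truth
#'
#' Computes the requested metrics on a subset of nodes (by default the
#' unlabeled nodes, the test set of a semi-supervised run). Set-based
#' metrics use the largest-gap relevant sets of the scores.
#'
#' @param scores `N x K` score matrix, [score_table()] or fitted model.
#' @param truth binary `N x K` full label matrix.
#' @param metrics character subset of
#'   `c("coverage", "rankingloss", "macrof1", "accuracy")`.
#' @param subset logical or integer node subset; `NULL` keeps all rows.
#' @return named list of metric values.
#' @export
evaluate_scores <- function(scores, truth,
                            metrics = c("coverage", "rankingloss", "macrof1"),
                            subset = NULL) {
  if (inherits(scores, "gmsmcc")) scores <- fitted(scores)
  tab <- if (inherits(scores, "score_table")) scores else score_table(scores)
  s <- tab$scores
  pred <- as_binary_predictions(tab, truth)
  if (!is.null(subset)) {
    s <- s[subset, , drop = FALSE]
    truth <- truth[subset, , drop = FALSE]
    pred <- pred[subset, , drop = FALSE]
  }
  out <- list()
  for (m in metrics) {
    out[[m]] <- switch(m,
      coverage = ml_coverage(s, truth),
      rankingloss = ml_ranking_loss(s, truth),
      macrof1 = as.numeric(ml_macro_f1(pred, truth)),
      accuracy = ml_accuracy(s, truth),
      stop("unknown metric: ", m))
  }
  out
}

## rank 1 = highest score; ties broken by stable class order
score_ranks <- function(s) {
  r <- integer(length(s))
  r[order(-s, seq_along(s))] <- seq_along(s)
  r
}

check_metric_input <- function(scores, truth) {
  if (!all(dim(scores) == dim(truth)))
    stop("scores and truth must have the same dimensions")
  if (!all(is.finite(scores))) stop("non-finite scores")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  invisible(TRUE)
}

as_binary_predictions <- function(predicted, truth) {
  if (inherits(predicted, "score_table")) {
    out <- matrix(0, nrow(predicted$scores), ncol(predicted$scores),
                  dimnames = dimnames(predicted$scores))
    for (i in seq_len(nrow(out)))
      out[i, match(predicted$relevant[[i]], predicted$class_names)] <- 1
    out
  } else {
    as.matrix(predicted)
  }
}
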