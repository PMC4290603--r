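#' Split label scores into relevant and irrelevant sets (largest-gap rule)
#'
#' For each node, scores are sorted in decreasing order, the largest gap
#' between successive sorted values is located, and the midpoint of that
#' pair becomes the threshold: labels scoring strictly above it are
#' relevant. The top label is always included, so the relevant set is never
#' empty; with a single class it is that class. Ties in the gap search go to
#' the first (highest-scoring) gap, and score ties are broken by stable
#' class order, keeping the rule deterministic.
#'
#' @param scores row-stochastic `N x K` matrix of label probabilities.
#' @param class_names optional character vector of length `K`.
#' @return list of `N` character vectors (subsets of `class_names`).
#' @examples
#' relevant_labels(rbind(c(0.5, 0.3, 0.15, 0.05),
#'                       c(0.4, 0.35, 0.2, 0.05)))
#' @export
relevant_labels <- function(scores, class_names = NULL) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  class_names <- class_names %||% colnames(scores) %||% paste0("c", seq_len(k))
  lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    if (k == 1L) return(class_names)
    ord <- order(-s, seq_len(k))  # stable: class order breaks ties
    ss <- s[ord]
    gaps <- ss[-k] - ss[-1]
    if (max(gaps) <= 0) {
      message("all-equal score row ", i, "; top-1 label by class order")
      return(class_names[ord[1]])
    }
    g <- which.max(gaps)  # first largest gap
    t <- (ss[g] + ss[g + 1]) / 2
    class_names[sort(ord[seq_len(g)])]
  })
}

#' Cosine similarity between two nodes' class-probability vectors
#'
#' Measures how interrelated two instances are through the model's
#' conditional distributions: 1 for proportional vectors, 0 for orthogonal
#' ones (probabilistically independent class profiles).
#'
#' @param scores row-stochastic `N x K` matrix.
#' @param i,j row indices.
#' @return scalar in `[0, 1]`.
#' @export
instance_similarity <- function(scores, i, j) {
  a <- scores[i, ]; b <- scores[j, ]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
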