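#' Construct a partially labeled attributed network dataset
#'
#' Bundles the four ingredients of a collective-classification problem: an
#' undirected interaction network over `N` nodes, a nonnegative `N x M`
#' attribute count table (the "word" frequencies of the generative model), a
#' binary `N x K` label table, and a logical mask saying which nodes carry
#' known labels. Only the masked (labeled) rows of `labels` are treated as
#' observed; unlabeled rows are ignored by the model.
#'
#' @param adjacency symmetric `N x N` adjacency with zero diagonal; binary for
#'   an interaction network (latent graphs may be weighted). A base matrix or
#'   a [Matrix::Matrix()]; stored sparse.
#' @param counts nonnegative `N x M` numeric matrix of attribute counts.
#' @param labels binary `N x K` matrix; rows of unlabeled nodes may be zero.
#' @param labeled_mask logical length-`N` vector; `TRUE` rows of `labels`
#'   must contain at least one positive.
#' @param node_ids,class_names,feature_names optional character identifiers;
#'   defaults are taken from dimnames or generated.
#' @return An object of class `networked_dataset`.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
#' X <- matrix(rpois(6, 2), 3, 2)
#' Y <- rbind(c(1, 0), c(0, 0), c(0, 1))
#' d <- networked_dataset(A, X, Y, labeled_mask = c(TRUE, FALSE, TRUE))
#' d
#' @export
networked_dataset <- function(adjacency, counts, labels, labeled_mask,
                              node_ids = NULL, class_names = NULL,
                              feature_names = NULL) {
  adjacency <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
  counts <- as.matrix(counts)
  labels <- as.matrix(labels)
  n <- nrow(counts)
  if (nrow(adjacency) != n || ncol(adjacency) != n)
    stop("adjacency must be N x N matching the count table")
  if (nrow(labels) != n) stop("labels must have one row per node")
  if (length(labeled_mask) != n) stop("labeled_mask must have length N")
  labeled_mask <- as.logical(labeled_mask)
  if (anyNA(labeled_mask)) stop("labeled_mask must be TRUE/FALSE")
  if (!isSymmetric(as.matrix(adjacency)))
    stop("adjacency must be symmetric")
  if (any(Matrix::diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal (no self-loops)")
  if (any(adjacency@x < 0)) stop("adjacency entries must be nonnegative")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (ncol(labels) < 1 || ncol(counts) < 1 || n < 1)
    stop("need N, M, K >= 1")
  if (sum(labeled_mask) < 1) stop("at least one node must be labeled")
  if (any(rowSums(labels[labeled_mask, , drop = FALSE]) == 0))
    stop("every labeled node must carry at least one positive label")

  node_ids <- node_ids %||% rownames(counts) %||% paste0("v", seq_len(n))
  class_names <- class_names %||% colnames(labels) %||%
    paste0("c", seq_len(ncol(labels)))
  feature_names <- feature_names %||% colnames(counts) %||%
    paste0("w", seq_len(ncol(counts)))
  dimnames(counts) <- list(node_ids, feature_names)
  dimnames(labels) <- list(node_ids, class_names)
  dimnames(adjacency) <- list(node_ids, node_ids)

  structure(
    list(adjacency = adjacency, counts = counts, labels = labels,
         labeled_mask = labeled_mask, node_ids = node_ids,
         class_names = class_names, feature_names = feature_names),
    class = "networked_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.networked_dataset <- function(x, ...) {
  cat("Networked dataset:", length(x$node_ids), "nodes,",
      sum(x$adjacency != 0) / 2, "edges,",
      ncol(x$counts), "features,", ncol(x$labels), "classes\n")
  cat(sprintf("  labeled: %d (%.1f%%)\n", sum(x$labeled_mask),
              100 * mean(x$labeled_mask)))
  invisible(x)
}

#' @export
dim.networked_dataset <- function(x) {
  c(N = length(x$node_ids), M = ncol(x$counts), K = ncol(x$labels))
}

#' Read an undirected edge list
#'
#' Two whitespace- or tab-delimited columns of node identifiers, one edge per
#' line. Self-loops are dropped with a warning, duplicate edges collapse, and
#' node order is first-appearance order unless `node_ids` is supplied.
#'
#' @param path path to the edge file.
#' @param node_ids optional character vector fixing the node set and order;
#'   nodes absent from the file become isolated.
#' @return list with `adjacency` (sparse symmetric, zero diagonal) and
#'   `node_ids`.
#' @export
read_edge_list <- function(path, node_ids = NULL) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("from", "to"))
  loops <- tab$from == tab$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from ", path)
    tab <- tab[!loops, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no valid edges in ", path)
  ids <- node_ids %||% unique(c(rbind(tab$from, tab$to)))
  unknown <- setdiff(c(tab$from, tab$to), ids)
  if (length(unknown))
    stop("edge endpoints not in supplied node_ids: ",
         paste(utils::head(unknown), collapse = ", "))
  i <- match(tab$from, ids)
  j <- match(tab$to, ids)
  n <- length(ids)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
                              dimnames = list(ids, ids))
  adj@x[] <- 1  # collapse duplicates to binary
  list(adjacency = methods::as(adj, "CsparseMatrix"), node_ids = ids)
}

#' Read a node attribute table
#'
#' A header row of attribute names followed by one row per node; the first
#' column holds the node identifier. With `encoding = "categorical"` every
#' (attribute, value) pair becomes one indicator column of count 1 — the
#' encoding used for categorical annotations such as chromosome or phenotype
#' — and missing values get an explicit `(attr, missing)` indicator. With
#' `encoding = "counts"` the numeric values are used as-is.
#'
#' @param path path to the TSV file.
#' @param encoding `"categorical"` (default) or `"counts"`.
#' @return list with `counts` (nonnegative matrix, node ids as rownames) and
#'   `feature_names`.
#' @export
read_feature_table <- function(path, encoding = c("categorical", "counts")) {
  encoding <- match.arg(encoding)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2) stop("feature table needs a node id column plus >= 1 attribute")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate node ids in feature table")
  attrs <- tab[, -1, drop = FALSE]
  if (encoding == "counts") {
    counts <- vapply(attrs, function(col) as.numeric(col), numeric(nrow(tab)))
    counts <- matrix(counts, nrow = nrow(tab),
                     dimnames = list(ids, colnames(attrs)))
    if (anyNA(counts)) stop("non-numeric or missing value under encoding = 'counts'")
    if (any(counts < 0)) stop("negative count in feature table")
  } else {
    blocks <- lapply(names(attrs), function(a) {
      v <- attrs[[a]]
      v[is.na(v)] <- "missing"
      lv <- sort(unique(v))
      ind <- outer(v, lv, `==`) * 1
      colnames(ind) <- paste0(a, "=", lv)
      ind
    })
    counts <- do.call(cbind, blocks)
    rownames(counts) <- ids
  }
  list(counts = counts, feature_names = colnames(counts))
}

#' Read a partial multi-label table
#'
#' A header row (`id` column plus one binary column per class) and one row
#' per *labeled* node; nodes of `node_ids` absent from the file are treated
#' as unlabeled. A listed all-zero row, a duplicated id, an unknown id, or a
#' non-binary entry is an error.
#'
#' @param path path to the TSV file.
#' @param node_ids character vector of all node ids, fixing row order.
#' @return list with `labels` (binary `N x K`), `labeled_mask`, `class_names`.
#' @export
read_label_table <- function(path, node_ids) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("node id(s) listed more than once in label table")
  unknown <- setdiff(ids, node_ids)
  if (length(unknown)) stop("unknown node id(s) in label table: ",
                            paste(utils::head(unknown), collapse = ", "))
  y <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(y) <- "numeric"
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("label entries must be 0/1")
  if (any(rowSums(y) == 0)) stop("listed node(s) with no positive label")
  labels <- matrix(0, length(node_ids), ncol(y),
                   dimnames = list(node_ids, colnames(y)))
  labels[match(ids, node_ids), ] <- y
  mask <- node_ids %in% ids
  list(labels = labels, labeled_mask = mask, class_names = colnames(y))
}

#' Assemble a dataset from the three plain-text inputs
#'
#' Convenience wrapper around [read_edge_list()], [read_feature_table()] and
#' [read_label_table()]. Nodes present in the feature table but absent from
#' the edge list are retained as isolated nodes (with a message); node order
#' is first appearance in the edge file, then feature-file order.
#'
#' @param edge_file,feature_file,label_file paths to the three TSV inputs.
#' @param encoding passed to [read_feature_table()].
#' @return A [networked_dataset()].
#' @export
read_networked_dataset <- function(edge_file, feature_file, label_file,
                                   encoding = "categorical") {
  feats <- read_feature_table(feature_file, encoding = encoding)
  edge_ids <- read_edge_list(edge_file)$node_ids
  extra <- setdiff(rownames(feats$counts), edge_ids)
  if (length(extra))
    message(length(extra), " node(s) have features but no edges; kept as isolated")
  ids <- c(edge_ids, extra)
  if (!all(edge_ids %in% rownames(feats$counts)))
    stop("edge list mentions nodes missing from the feature table")
  adj <- read_edge_list(edge_file, node_ids = ids)$adjacency
  counts <- feats$counts[ids, , drop = FALSE]
  lab <- read_label_table(label_file, node_ids = ids)
  networked_dataset(adj, counts, lab$labels, lab$labeled_mask,
                    node_ids = ids, class_names = lab$class_names,
                    feature_names = feats$feature_names)
}

#' Per-node label scores with relevant-label sets
#'
#' A `score_table` pairs the row-stochastic `N x K` matrix of `P(c_k | x_i)`
#' with the per-node relevant label set obtained by the largest-gap rule
#' (see [relevant_labels()]), the package's label-decision output.
#'
#' @param scores row-stochastic `N x K` matrix (rows sum to 1 within 1e-9).
#' @param class_names,node_ids optional identifiers.
#' @param relevant optional precomputed list of relevant label sets; computed
#'   by [relevant_labels()] when missing.
#' @return An object of class `score_table` with components `scores`
#'   (matrix) and `relevant` (list of character vectors, all nonempty).
#' @export
score_table <- function(scores, class_names = NULL, node_ids = NULL,
                        relevant = NULL) {
  scores <- as.matrix(scores)
  class_names <- class_names %||% colnames(scores) %||%
    paste0("c", seq_len(ncol(scores)))
  node_ids <- node_ids %||% rownames(scores) %||%
    paste0("v", seq_len(nrow(scores)))
  dimnames(scores) <- list(node_ids, class_names)
  if (any(scores < 0)) stop("scores must be nonnegative")
  if (any(abs(rowSums(scores) - 1) > 1e-9))
    stop("score rows must sum to 1 within 1e-9")
  relevant <- relevant %||% relevant_labels(scores, class_names)
  stopifnot(length(relevant) == nrow(scores))
  if (any(lengths(relevant) == 0)) stop("relevant sets must be nonempty")
  structure(list(scores = scores, relevant = relevant,
                 node_ids = node_ids, class_names = class_names),
            class = "score_table")
}

#' @export
print.score_table <- function(x, n = 6L, ...) {
  cat("Score table:", nrow(x$scores), "nodes x", ncol(x$scores), "classes\n")
  show <- utils::head(seq_len(nrow(x$scores)), n)
  out <- data.frame(round(x$scores[show, , drop = FALSE], 4),
                    relevant = vapply(x$relevant[show], paste,
                                      character(1), collapse = ";"),
                    check.names = FALSE)
  print(out)
  if (nrow(x$scores) > n) cat("...", nrow(x$scores) - n, "more rows\n")
  invisible(x)
}

#' Write / read a score table
#'
#' TSV with the node id, one probability column per class printed at 15
#' significant digits, and a semicolon-joined relevant-label column;
#' round-trips through [read_scores()] to within 1e-9.
#'
#' @param x a [score_table()].
#' @param path output path.
#' @return `write_scores` returns `x` invisibly; `read_scores` a
#'   `score_table`.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "score_table"))
  df <- data.frame(id = x$node_ids,
                   format(x$scores, digits = 15, scientific = TRUE,
                          trim = TRUE),
                   relevant = vapply(x$relevant, paste, character(1),
                                     collapse = ";"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", x$class_names, "relevant")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  k <- ncol(tab) - 2L
  scores <- as.matrix(tab[, 1L + seq_len(k), drop = FALSE])
  storage.mode(scores) <- "numeric"
  rownames(scores) <- tab[[1]]
  relevant <- strsplit(tab[[ncol(tab)]], ";", fixed = TRUE)
  score_table(scores / rowSums(scores), class_names = colnames(scores),
              node_ids = tab[[1]], relevant = relevant)
}
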