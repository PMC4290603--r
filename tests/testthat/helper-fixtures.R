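# Small datasets built in code for unit tests.

# Deterministic 4-node dataset: path graph, hand-set counts, 2 labeled nodes.
tiny_dataset <- function() {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  adj[3, 4] <- adj[4, 3] <- 1
  counts <- rbind(c(3, 1, 0), c(2, 2, 0), c(0, 2, 2), c(0, 1, 3))
  labels <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 1))
  networked_dataset(adj, counts, labels,
                    labeled_mask = c(TRUE, FALSE, FALSE, TRUE))
}

# Random valid dataset with n_pos-guaranteed count rows and >= 1 labeled node.
random_dataset <- function(n = 5, m = 4, k = 3, n_labeled = 2, seed = 1) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n * m, 2), n, m)
  zero <- rowSums(counts) == 0
  counts[cbind(which(zero), sample.int(m, sum(zero), replace = TRUE))] <- 1
  adj <- matrix(0, n, n)
  pairs <- which(upper.tri(adj))
  picks <- sample(pairs, min(length(pairs), n))
  adj[picks] <- 1
  adj <- adj + t(adj)
  labels <- matrix(0, n, k)
  lab_idx <- sample.int(n, n_labeled)
  for (i in lab_idx) {
    pos <- sample.int(k, sample(1:min(2, k), 1))
    labels[i, pos] <- 1
  }
  mask <- seq_len(n) %in% lab_idx
  networked_dataset(adj, counts, labels, mask)
}

# Random row-stochastic matrix.
random_scores <- function(n, k, seed = 1) {
  set.seed(seed)
  s <- matrix(stats::runif(n * k), n, k)
  s / rowSums(s)
}

# Random truth with >= 1 positive per row (and <= k - 1 when possible).
random_truth <- function(n, k, seed = 1) {
  set.seed(seed)
  y <- matrix(stats::rbinom(n * k, 1, 0.4), n, k)
  empty <- rowSums(y) == 0
  y[cbind(which(empty), sample.int(k, sum(empty), replace = TRUE))] <- 1
  y
}
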