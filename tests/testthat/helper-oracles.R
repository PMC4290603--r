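# Clean-room oracles: explicit-loop implementations kept independent of the
# package's vectorized code paths.

# Textbook pLSA EM (loops over the full posterior tensor), with the same
# labeled-row clamp and smoothed initialization as the model so the
# alpha = beta = 0 limit is directly comparable. Returns the final
# log-likelihood after n_iter iterations.
oracle_plsa <- function(dataset, n_iter, smoothing) {
  n <- dataset$counts
  y <- dataset$labels
  mask <- dataset$labeled_mask
  N <- nrow(n); M <- ncol(n); K <- ncol(y)

  pwc <- matrix(0, M, K)
  for (k in seq_len(K)) {
    for (j in seq_len(M)) {
      acc <- smoothing
      for (i in seq_len(N))
        if (mask[i] && y[i, k] == 1) acc <- acc + n[i, j]
      pwc[j, k] <- acc
    }
    pwc[, k] <- pwc[, k] / sum(pwc[, k])
  }
  npos <- colSums(y[mask, , drop = FALSE])
  prior <- npos / sum(npos)
  pcx <- matrix(rep(prior, each = N), N, K)
  for (i in which(mask)) pcx[i, ] <- y[i, ] / sum(y[i, ])

  loglik <- NA_real_
  for (iter in seq_len(n_iter)) {
    post <- array(0, c(N, M, K))
    for (i in seq_len(N)) for (j in seq_len(M)) {
      num <- numeric(K)
      for (k in seq_len(K)) num[k] <- pwc[j, k] * pcx[i, k]
      # cells with n = 0 are never consumed; a fully zero mixture elsewhere
      # falls back to the uniform posterior, as in the model
      post[i, j, ] <- if (sum(num) > 0) num / sum(num) else rep(1 / K, K)
    }
    pwc_new <- matrix(0, M, K)
    for (k in seq_len(K)) {
      for (j in seq_len(M))
        for (i in seq_len(N))
          pwc_new[j, k] <- pwc_new[j, k] + n[i, j] * post[i, j, k]
      pwc_new[, k] <- pwc_new[, k] / sum(pwc_new[, k])
    }
    pcx_new <- matrix(0, N, K)
    for (i in seq_len(N)) {
      for (k in seq_len(K))
        for (j in seq_len(M))
          pcx_new[i, k] <- pcx_new[i, k] + n[i, j] * post[i, j, k]
      pcx_new[i, ] <- pcx_new[i, ] / sum(pcx_new[i, ])
    }
    for (i in which(mask)) pcx_new[i, ] <- y[i, ] / sum(y[i, ])
    pwc <- pwc_new; pcx <- pcx_new
    loglik <- 0
    for (i in seq_len(N)) for (j in seq_len(M)) {
      if (n[i, j] > 0) {
        mix <- 0
        for (k in seq_len(K)) mix <- mix + pwc[j, k] * pcx[i, k]
        loglik <- loglik + n[i, j] * log(max(mix, 1e-12))
      }
    }
  }
  list(loglik = loglik, p_w_given_c = pwc, p_c_given_x = pcx)
}

# Naive double-sum network regularizer over ordered node pairs.
oracle_network_reg <- function(pcx, w, eps = 1e-12) {
  z <- pmax(pcx, eps)
  z <- z / rowSums(z)
  w <- as.matrix(w)
  total <- 0
  for (i in seq_len(nrow(z))) for (s in seq_len(nrow(z))) {
    if (w[i, s] != 0) {
      d <- 0.5 * (sum(z[i, ] * log(z[i, ] / z[s, ])) +
                  sum(z[s, ] * log(z[s, ] / z[i, ])))
      total <- total + d * w[i, s]
    }
  }
  total
}

# Naive double-sum label regularizer over ordered class pairs, raw floored
# columns (no renormalization).
oracle_label_reg <- function(pcx, f, eps = 1e-12) {
  r <- pmax(pcx, eps)
  total <- 0
  for (k in seq_len(ncol(r))) for (l in seq_len(ncol(r))) {
    d <- 0.5 * (sum(r[, k] * log(r[, k] / r[, l])) +
                sum(r[, l] * log(r[, l] / r[, k])))
    total <- total + d * f[k, l]
  }
  total
}

# Brute-force rank of each label: 1 + #(strictly higher) + #(equal, earlier
# class index) — the stable tie order.
oracle_ranks <- function(s) {
  vapply(seq_along(s), function(k) {
    1L + sum(s > s[k]) + sum(s == s[k] & seq_along(s) < k)
  }, integer(1))
}

oracle_coverage <- function(scores, truth) {
  vals <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    r <- oracle_ranks(scores[i, ])
    vals[i] <- max(r[truth[i, ] == 1]) - 1
  }
  mean(vals)
}

oracle_ranking_loss <- function(scores, truth) {
  vals <- c()
  for (i in seq_len(nrow(scores))) {
    pos <- which(truth[i, ] == 1)
    neg <- which(truth[i, ] == 0)
    if (length(pos) == 0 || length(neg) == 0) next
    bad <- 0
    for (p in pos) for (q in neg) if (scores[i, p] <= scores[i, q]) bad <- bad + 1
    vals <- c(vals, bad / (length(pos) * length(neg)))
  }
  mean(vals)
}
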