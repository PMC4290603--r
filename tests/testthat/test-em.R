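test_that("labeled rows are clamped to the uniform distribution over known labels", {
  adj <- matrix(0, 2, 2)
  ds <- networked_dataset(adj, matrix(1, 2, 4),
                          rbind(c(1, 0, 1, 0), c(0, 1, 0, 0)),
                          c(TRUE, TRUE),
                          class_names = paste0("c", 1:4))
  pcx <- matrix(0.25, 2, 4)
  out <- smcc:::clamp_labeled(pcx, ds)
  expect_equal(unname(out[1, ]), c(0.5, 0, 0.5, 0))
  expect_equal(unname(out[2, ]), c(0, 1, 0, 0))  # single label -> one-hot
  expect_identical(smcc:::clamp_labeled(out, ds), out)  # idempotent
})

test_that("initialization uses smoothed labeled counts and the class prior", {
  # one labeled node with counts (2, 0), single class
  adj <- matrix(0, 2, 2)
  ds <- networked_dataset(adj, rbind(c(2, 0), c(1, 1)),
                          rbind(1, 0), c(TRUE, FALSE))
  s <- 0.5
  p <- smcc:::init_params(ds, smoothing = s)
  expect_equal(unname(p$p_w_given_c[, 1]),
               c((2 + s) / (2 + 2 * s), s / (2 + 2 * s)))

  # labeled class prior 3:1 fills the unlabeled rows
  adj5 <- matrix(0, 5, 5)
  labels <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 0))
  ds5 <- networked_dataset(adj5, matrix(1, 5, 3), labels,
                           c(TRUE, TRUE, TRUE, TRUE, FALSE))
  p5 <- smcc:::init_params(ds5, smoothing = 1 / 3)
  expect_equal(unname(p5$p_c_given_x[5, ]), c(0.75, 0.25))
  # all invariants hold
  expect_equal(unname(rowSums(p5$p_c_given_x)), rep(1, 5))
  expect_equal(unname(colSums(p5$p_w_given_c)), rep(1, 2))
  expect_true(all(p5$p_w_given_c >= 0) && all(p5$p_c_given_x >= 0))
})

test_that("a class without labeled positives warns and gets a uniform column", {
  adj <- matrix(0, 2, 2)
  ds <- networked_dataset(adj, rbind(c(2, 1), c(1, 1)),
                          rbind(c(1, 0), c(0, 0)), c(TRUE, FALSE))
  expect_warning(p <- smcc:::init_params(ds, smoothing = 0.5),
                 "without labeled positives")
  expect_equal(unname(p$p_w_given_c[, 2]), c(0.5, 0.5))
})

test_that("the E-step posterior is the Bayes ratio and sums to one", {
  ds <- tiny_dataset()
  pwc <- matrix(c(0.5, 0.3, 0.2, 0.25, 0.25, 0.5), 3, 2)
  pcx <- matrix(rep(c(0.4, 0.6), each = 4), 4, 2)
  post <- smcc:::e_step(ds, list(p_w_given_c = pwc, p_c_given_x = pcx))
  # P(w|c1) = 0.5, P(w|c2) = 0.25, P(c|x) = (0.4, 0.6)
  expect_equal(unname(smcc:::posterior_at(post, 1, 1)),
               c(0.2, 0.15) / 0.35, tolerance = 1e-12)
  for (cell in list(c(1, 2), c(2, 1), c(4, 3)))
    expect_equal(sum(smcc:::posterior_at(post, cell[1], cell[2])), 1)
  # K = 1: posterior is identically 1
  ds1 <- networked_dataset(matrix(0, 2, 2), rbind(c(1, 2), c(2, 1)),
                           rbind(1, 1), c(TRUE, FALSE))
  p1 <- smcc:::e_step(ds1, list(p_w_given_c = matrix(0.5, 2, 1),
                                p_c_given_x = matrix(1, 2, 1)))
  expect_equal(unname(smcc:::posterior_at(p1, 1, 1)), 1)
})

test_that("the P(w|c) M-step reduces to global frequencies when K = 1", {
  ds1 <- networked_dataset(matrix(0, 2, 2), rbind(c(3, 1), c(1, 3)),
                           rbind(1, 1), c(TRUE, FALSE))
  post <- smcc:::e_step(ds1, list(p_w_given_c = matrix(c(0.9, 0.1), 2, 1),
                                  p_c_given_x = matrix(1, 2, 1)))
  pwc <- smcc:::m_step_pwc(ds1, post)
  expect_equal(unname(pwc[, 1]), c(0.5, 0.5))
})

test_that("P(w|c) updates are column-stochastic on random inputs", {
  for (seed in 1:5) {
    ds <- random_dataset(n = 6, m = 5, k = 3, seed = seed)
    p <- suppressWarnings(smcc:::init_params(ds, smoothing = 0.2))
    post <- smcc:::e_step(ds, p)
    pwc <- suppressWarnings(smcc:::m_step_pwc(ds, post))
    expect_equal(unname(colSums(pwc)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(pwc >= 0))
  }
})

test_that("the M-step system diagonal reproduces per-node total counts", {
  for (seed in 1:5) {
    ds <- random_dataset(n = 6, m = 5, k = 3, seed = seed)
    p <- suppressWarnings(smcc:::init_params(ds, smoothing = 0.2))
    post <- smcc:::e_step(ds, p)
    lapg <- smcc:::laplacian(ds$adjacency)
    lapl <- smcc:::laplacian(label_affinity(ds))
    sys <- smcc:::build_mstep_system(ds, post, lapg, lapl, 1, 1)
    expect_equal(sys$rho, unname(rowSums(ds$counts)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("graph and label Laplacian operators are positive semidefinite", {
  ds <- random_dataset(n = 6, m = 5, k = 3, seed = 7)
  n <- 6; k <- 3
  lapg <- smcc:::laplacian(ds$adjacency)
  lapl <- smcc:::laplacian(label_affinity(ds))
  DB <- Matrix::kronecker(Matrix::Diagonal(k), lapg)
  UR <- Matrix::kronecker(lapl, Matrix::Diagonal(n))
  set.seed(42)
  for (r in 1:100) {
    y <- rnorm(n * k)
    expect_gte(as.numeric(t(y) %*% DB %*% y), -1e-10)
    expect_gte(as.numeric(t(y) %*% UR %*% y), -1e-10)
  }
})

test_that("at alpha = beta = 0 the P(c|x) M-step is the diagonal pLSA update", {
  ds <- random_dataset(n = 5, m = 4, k = 2, seed = 3)
  p <- smcc:::init_params(ds, smoothing = 0.25)
  post <- smcc:::e_step(ds, p)
  lapg <- smcc:::laplacian(ds$adjacency)
  lapl <- smcc:::laplacian(label_affinity(ds))
  rho <- rowSums(ds$counts)
  pcx <- smcc:::m_step_pcx(ds, post, lapg, lapl, rho, alpha = 0, beta = 0,
                           eps = 1e-12)
  sys <- smcc:::build_mstep_system(ds, post, lapg, lapl, 0, 0)
  closed <- sys$Z / rowSums(sys$Z)
  closed <- smcc:::clamp_labeled(closed, ds)
  expect_equal(unname(pcx), unname(closed), tolerance = 1e-9)
  # K = 1 degenerates to all-ones
  ds1 <- networked_dataset(matrix(0, 2, 2), rbind(c(1, 2), c(2, 1)),
                           rbind(1, 1), c(TRUE, FALSE))
  p1 <- smcc:::init_params(ds1, smoothing = 0.5)
  post1 <- smcc:::e_step(ds1, p1)
  pcx1 <- smcc:::m_step_pcx(ds1, post1, smcc:::laplacian(ds1$adjacency),
                            smcc:::laplacian(label_affinity(ds1)),
                            rowSums(ds1$counts), 1, 1, 1e-12)
  expect_equal(unname(pcx1[, 1]), c(1, 1))
})

test_that("EM keeps parameters normalized and labeled rows clamped at every iteration", {
  ds <- random_dataset(n = 8, m = 6, k = 3, n_labeled = 3, seed = 11)
  fit <- suppressWarnings(gmsmcc(ds, alpha = 2, beta = 0.1, keep_history = TRUE))
  y <- ds$labels[ds$labeled_mask, , drop = FALSE]
  clamp <- y / rowSums(y)
  for (p in fit$history) {
    expect_equal(unname(rowSums(p$p_c_given_x)), rep(1, 8), tolerance = 1e-9)
    expect_equal(unname(colSums(p$p_w_given_c)), rep(1, 3), tolerance = 1e-9)
    expect_identical(unname(p$p_c_given_x[ds$labeled_mask, ]), unname(clamp))
  }
})

test_that("the EM stopping rule is honored and the trace is well-formed", {
  ds <- random_dataset(n = 8, m = 6, k = 3, seed = 2)
  fit <- suppressWarnings(gmsmcc(ds, alpha = 1, beta = 0.1, tol = 1e-4, max_iter = 50))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 50)
  expect_equal(nrow(fit$trace), fit$n_iter)
  o <- fit$trace$objective
  n <- length(o)
  expect_lt(abs(o[n] - o[n - 1]) / abs(o[n - 1]), 1e-4)
})

test_that("with regularizers off the fitted likelihood matches the textbook pLSA oracle", {
  ds <- random_dataset(n = 5, m = 4, k = 2, seed = 21)
  fit <- gmsmcc(ds, alpha = 0, beta = 0, tol = 1e-15, max_iter = 25,
                smoothing = 0.25)
  orc <- oracle_plsa(ds, n_iter = fit$n_iter, smoothing = 0.25)
  expect_equal(fit$trace$loglik[fit$n_iter], orc$loglik, tolerance = 1e-6)
})

test_that("pLSA-limit likelihood is non-decreasing over iterations", {
  for (seed in c(5, 6)) {
    ds <- random_dataset(n = 6, m = 5, k = 3, seed = seed)
    fit <- suppressWarnings(gmsmcc(ds, alpha = 0, beta = 0, tol = 1e-12, max_iter = 30))
    expect_true(all(diff(fit$trace$loglik) > -1e-8))
  }
})

test_that("fit results expose standard model methods", {
  ds <- random_dataset(n = 8, m = 6, k = 3, seed = 8)
  fit <- suppressWarnings(gmsmcc(ds, alpha = 1, beta = 0.1))
  expect_output(print(fit), "GM-SMCC")
  expect_output(print(summary(fit)), "cardinality")
  cf <- coef(fit)
  expect_equal(dim(cf$p_w_given_c), c(6, 3))
  expect_equal(fitted(fit), fit$p_c_given_x)
  expect_s3_class(predict(fit), "score_table")
  expect_equal(as.numeric(logLik(fit)),
               fit$trace$loglik[fit$n_iter])
})
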