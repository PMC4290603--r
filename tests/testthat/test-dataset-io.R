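test_that("edge list reading symmetrizes, collapses duplicates, drops self-loops", {
  f <- withr::local_tempfile(lines = c("a\tb", "b\tc"))
  out <- read_edge_list(f)
  expect_equal(out$node_ids, c("a", "b", "c"))
  expect_equal(sum(out$adjacency != 0), 4)
  expect_true(isSymmetric(unname(as.matrix(out$adjacency))))
  expect_true(all(Matrix::diag(out$adjacency) == 0))

  dup <- withr::local_tempfile(lines = c("a\tb", "b\ta"))
  out2 <- read_edge_list(dup)
  expect_equal(length(out2$node_ids), 2)
  expect_equal(sum(out2$adjacency != 0), 2)
  expect_true(all(out2$adjacency@x == 1))

  loops <- withr::local_tempfile(lines = c("a\ta"))
  expect_warning(expect_error(read_edge_list(loops), "no valid edges"),
                 "self-loop")
})

test_that("categorical features one-hot encode and counts pass through", {
  f <- withr::local_tempfile(lines = c("id\tchromosome",
                                       "a\t1", "b\t2", "c\t1"))
  out <- read_feature_table(f, encoding = "categorical")
  expect_equal(ncol(out$counts), 2)
  expect_equal(unname(rowSums(out$counts)), c(1, 1, 1))
  expect_equal(sort(out$feature_names),
               c("chromosome=1", "chromosome=2"))

  cf <- withr::local_tempfile(lines = c("id\tw1\tw2",
                                        "a\t3\t0", "b\t1\t2"))
  out2 <- read_feature_table(cf, encoding = "counts")
  expect_equal(unname(out2$counts), rbind(c(3, 0), c(1, 2)))

  neg <- withr::local_tempfile(lines = c("id\tw1", "a\t-1"))
  expect_error(read_feature_table(neg, encoding = "counts"), "negative")
})

test_that("missing categorical values become an explicit indicator", {
  f <- withr::local_tempfile(lines = c("id\tmotif", "a\tx", "b\t"))
  out <- read_feature_table(f)
  expect_true("motif=missing" %in% out$feature_names)
  expect_equal(unname(rowSums(out$counts)), c(1, 1))
})

test_that("label table masks unlisted nodes and rejects invalid rows", {
  ids <- c("a", "b", "c", "d", "e")
  f <- withr::local_tempfile(lines = c("id\tc1\tc2", "a\t1\t0", "d\t1\t1"))
  out <- read_label_table(f, ids)
  expect_equal(sum(out$labeled_mask), 2)
  expect_equal(sum(!out$labeled_mask), 3)
  expect_equal(out$labels["d", ], c(c1 = 1, c2 = 1))
  expect_equal(unname(out$labels["b", ]), c(0, 0))

  zero <- withr::local_tempfile(lines = c("id\tc1\tc2", "a\t0\t0"))
  expect_error(read_label_table(zero, ids), "no positive")
  dup <- withr::local_tempfile(lines = c("id\tc1\tc2", "a\t1\t0", "a\t0\t1"))
  expect_error(read_label_table(dup, ids), "more than once")
  unk <- withr::local_tempfile(lines = c("id\tc1\tc2", "zz\t1\t0"))
  expect_error(read_label_table(unk, ids), "unknown")
  bad <- withr::local_tempfile(lines = c("id\tc1\tc2", "a\t2\t0"))
  expect_error(read_label_table(bad, ids), "0/1")
})

test_that("score tables round-trip through TSV within 1e-9", {
  s <- random_scores(7, 4, seed = 3)
  tab <- score_table(s)
  f <- withr::local_tempfile()
  write_scores(tab, f)
  back <- read_scores(f)
  expect_equal(back$scores, tab$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$relevant, tab$relevant)

  one <- score_table(matrix(1, 1, 1))
  f1 <- withr::local_tempfile()
  write_scores(one, f1)
  expect_equal(length(readLines(f1)), 2)  # header + one row
})

test_that("score tables enforce row-stochasticity and nonempty relevant sets", {
  expect_error(score_table(matrix(c(0.5, 0.4), 1, 2)), "sum to 1")
  expect_error(score_table(matrix(c(1.2, -0.2), 1, 2)), "nonnegative")
  expect_error(score_table(random_scores(2, 2), relevant = list(character(0), "c1")),
               "nonempty")
})

test_that("assembled datasets keep isolated feature-only nodes and satisfy invariants", {
  ef <- withr::local_tempfile(lines = c("a\tb", "b\tc"))
  ff <- withr::local_tempfile(lines = c("id\tattr", "a\tx", "b\ty",
                                        "c\tx", "d\ty"))
  lf <- withr::local_tempfile(lines = c("id\tc1\tc2", "a\t1\t0", "d\t0\t1"))
  expect_message(ds <- read_networked_dataset(ef, ff, lf), "isolated")
  expect_equal(ds$node_ids, c("a", "b", "c", "d"))
  expect_equal(Matrix::rowSums(ds$adjacency)[["d"]], 0)
  expect_equal(sum(ds$labeled_mask), 2)
})

test_that("randomized valid files always produce invariant-satisfying datasets", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:9, 1)
    ids <- paste0("n", seq_len(n))
    edges <- t(replicate(n, sample(ids, 2)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) == 0) edges <- rbind(c(ids[1], ids[2]))
    ef <- withr::local_tempfile(lines = paste(edges[, 1], edges[, 2], sep = "\t"))
    ff <- withr::local_tempfile(lines = c("id\tattr",
                                          paste0(ids, "\t", sample(c("p", "q", "r"),
                                                                   n, TRUE))))
    k <- sample(2:4, 1)
    lab_ids <- sample(ids, sample(1:2, 1))
    y <- matrix(rbinom(length(lab_ids) * k, 1, 0.5), length(lab_ids), k)
    y[rowSums(y) == 0, 1] <- 1
    lf <- withr::local_tempfile(lines = c(
      paste(c("id", paste0("c", 1:k)), collapse = "\t"),
      paste(lab_ids, apply(y, 1, paste, collapse = "\t"), sep = "\t")))
    ds <- suppressMessages(read_networked_dataset(ef, ff, lf))
    expect_s3_class(ds, "networked_dataset")
    a <- as.matrix(ds$adjacency)
    expect_true(isSymmetric(unname(a)))
    expect_true(all(diag(a) == 0))
    expect_true(all(a %in% c(0, 1)))
    expect_true(all(ds$counts >= 0))
    expect_true(all(rowSums(ds$labels[ds$labeled_mask, , drop = FALSE]) >= 1))
  }
})
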