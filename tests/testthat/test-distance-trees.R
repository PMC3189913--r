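test_that("score distances match a naive double-loop computation", {
  set.seed(6)
  X <- matrix(rnorm(36), 9)
  rownames(X) <- paste0("s", 1:9)
  for (metric in c("euclidean", "squared_euclidean")) {
    dm <- score_distances(X, metric = metric)
    naive <- matrix(0, 9, 9)
    for (i in 1:9) for (j in 1:9) {
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      naive[i, j] <- if (metric == "euclidean") d else d^2
    }
    expect_lt(max(abs(dm$matrix - naive)), 1e-12)
    expect_lt(max(abs(dm$matrix - t(dm$matrix))), 1e-12)
    expect_equal(diag(dm$matrix), rep(0, 9))
  }
  expect_equal(score_distances(rbind(c(0, 0), c(3, 4)))$matrix[1, 2], 5)
  expect_equal(score_distances(rbind(c(0, 0), c(3, 4)),
                               "squared_euclidean")$matrix[1, 2], 25)
  expect_equal(score_distances(rbind(c(1, 2), c(1, 2)))$matrix[1, 2], 0)
})

test_that("group aggregation averages score vectors before distances", {
  X <- rbind(c(0, 0), c(2, 0), c(10, 0), c(12, 0))
  rownames(X) <- paste0("s", 1:4)
  dm <- score_distances(X, by_group = TRUE, groups = c("a", "a", "b", "b"))
  expect_equal(dm$labels, c("a", "b"))
  expect_equal(dm$matrix[1, 2], 10)  # centroids at 1 and 11
})

test_that("upgma reproduces the forced three-leaf solution", {
  dm <- distance_matrix(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3),
                        c("A", "B", "C"))
  tr <- upgma(dm)
  expect_equal(write_newick(tr), "((A:1,B:1):3,C:4);")
})

test_that("upgma reproduces ultrametric input distances exactly", {
  # build an ultrametric matrix from a known dendrogram
  labs <- c("A", "B", "C", "D", "E")
  D <- matrix(8, 5, 5, dimnames = list(labs, labs))
  D[cbind(c(1, 2), c(2, 1))] <- 2
  D[cbind(c(3, 4), c(4, 3))] <- 4
  D[cbind(c(3, 5), c(5, 3))] <- 6
  D[cbind(c(4, 5), c(5, 4))] <- 6
  diag(D) <- 0
  tr <- upgma(distance_matrix(D, labs))
  co <- tree_cophenetic(tr)[labs, labs]
  expect_equal(unname(co), unname(D), tolerance = 1e-9)
})

test_that("upgma cophenetic distances match average-linkage hclust", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(40), 10)
    rownames(X) <- paste0("s", 1:10)
    dm <- score_distances(X)
    tr <- upgma(dm)
    hc <- stats::hclust(stats::dist(X), method = "average")
    co1 <- tree_cophenetic(tr)[rownames(X), rownames(X)]
    co2 <- as.matrix(stats::cophenetic(hc))[rownames(X), rownames(X)]
    expect_lt(max(abs(co1 - co2)), 1e-9)
  }
})

test_that("upgma trees are ultrametric and permutation-invariant", {
  set.seed(8)
  X <- matrix(rnorm(32), 8)
  rownames(X) <- paste0("s", 1:8)
  tr <- upgma(score_distances(X))
  depths <- ape::node.depth.edgelength(tr)[seq_len(8)]
  expect_lt(diff(range(depths)), 1e-9)
  perm <- sample(8)
  tr2 <- upgma(score_distances(X[perm, ]))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("upgma rejects missing distances", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  m[1, 2] <- NA
  expect_error(distance_matrix(m, c("a", "b")), "NaN/NA")
})

test_that("outgroup placement is classified correctly", {
  tr <- upgma(distance_matrix(
    matrix(c(0, 2, 9, 9,
             2, 0, 9, 9,
             9, 9, 0, 3,
             9, 9, 3, 0), 4, 4), c("in1", "in2", "out1", "out2")))
  res <- outgroup_orient(tr, c("out1", "out2"))
  expect_true(res$monophyletic_basal)
  expect_equal(res$status, "monophyletic-basal")

  tr2 <- upgma(distance_matrix(
    matrix(c(0, 2, 5, 9,
             2, 0, 5, 9,
             5, 5, 0, 9,
             9, 9, 9, 0), 4, 4), c("in1", "in2", "outA", "outB")))
  res2 <- outgroup_orient(tr2, c("outA", "outB"))
  expect_false(res2$monophyletic_basal)
  expect_true(length(res2$offending_clade) > 2)
  expect_error(outgroup_orient(tr2, "nope"), "unknown outgroup")
})

test_that("a distinct outgroup mean shape lands basal across seeds", {
  mu <- base_shape(8)
  for (seed in 1:5) {
    spec <- sim_spec(seed, groups = list(
      list(label = "ing1", n = 6, mean_shape = mu, noise_sd = 0.015),
      list(label = "ing2", n = 6,
           mean_shape = mu + 0.12 * cbind(mu[, 2]^2, 0), noise_sd = 0.015),
      list(label = "outg", n = 6,
           mean_shape = mu + 0.6 * cbind(0, mu[, 1]^2), noise_sd = 0.015)))
    rw <- relative_warps(partial_warps(
      generalized_procrustes(simulate_landmarks(spec))))
    dm <- score_distances(rw$rw_scores, by_group = TRUE, groups = rw$group)
    res <- outgroup_orient(upgma(dm), "outg")
    expect_true(res$monophyletic_basal, info = paste("seed", seed))
  }
})
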