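holotype <- function() {
  read_measurements(system.file("extdata", "holotype_measurements.csv",
                                package = "pantherin"))
}

panthera_ranges <- function() {
  range_table(utils::read.csv(system.file(
    "extdata", "panthera_ratio_ranges.csv", package = "pantherin")))
}

test_that("the four printed holotype percentages are reproduced exactly", {
  h <- holotype()
  expect_equal(ratio(h$c1_height, h$CBL, decimals = 1, percent = TRUE), 23.7)
  expect_equal(ratio(h$nasal_length, h$CBL, decimals = 1, percent = TRUE), 34.5)
  expect_equal(ratio(h$p4_length, h$CBL, decimals = 1, percent = TRUE), 13.4)
  expect_equal(ratio(h$m1_length, h$mandible_length, decimals = 1,
                     percent = TRUE), 14.7)
})

test_that("ratio handles identities, rounding and bad input", {
  expect_equal(ratio(7.3, 7.3, decimals = 3), 1.000)
  expect_equal(round_half_up(0.2345, 3), 0.235)  # half rounds up
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)       # away from zero
  expect_error(ratio(-1, 2), "positive")
  expect_error(ratio(1, 0), "positive")
})

test_that("ratio_profile computes named ratios over a table", {
  h <- holotype()
  prof <- ratio_profile(h, list(canine = c("c1_height", "CBL"),
                                nasal = c("nasal_length", "CBL")),
                        percent = TRUE, decimals = 1)
  expect_equal(prof$canine, 23.7)
  expect_equal(prof$nasal, 34.5)
  expect_error(ratio_profile(h, list(x = c("nope", "CBL"))), "unknown variable")
})

test_that("range_compare reproduces the published verdicts", {
  rt <- panthera_ranges()
  nasal <- range_compare(0.345, rt, "nasal_length_cbl")
  tiger_nasal <- nasal[nasal$group == "tiger", ]
  expect_equal(tiger_nasal$verdict, "within")
  expect_equal(tiger_nasal$qualifier, "lower half")

  canine <- range_compare(0.237, rt, "canine_height_cbl")
  expect_equal(canine$verdict[canine$group == "tiger"], "above")
  expect_true(all(canine$verdict %in% c("above")))

  # closed-interval boundary convention
  at_max <- range_compare(0.230, rt, "canine_height_cbl")
  expect_equal(at_max$verdict[at_max$group == "tiger"], "within")
  expect_error(range_compare(0.3, rt, "unknown_ratio"), "unknown ratio")
})

test_that("size-adjusted PCA behaves like a covariance PCA of proportions", {
  tab <- measurement_table(data.frame(
    specimen_id = paste0("s", 1:6), group = rep(c("a", "b"), each = 3),
    CBL = c(200, 201, 199, 200, 202, 198),
    v1 = c(50, 50.2, 49.8, 70, 70.4, 69.6),
    v2 = c(30, 30.1, 29.9, 30, 30.2, 29.8)))
  pc <- size_adjusted_pca(tab, adjustment = "ratio_cbl")
  # PC1 separates the groups and loads on the differing variable
  expect_gt(abs(mean(pc$scores[1:3, 1]) - mean(pc$scores[4:6, 1])),
            5 * sd(pc$scores[1:3, 1]))
  expect_gt(abs(pc$loadings["v1", 1]), abs(pc$loadings["v2", 1]))
  expect_equal(sum(pc$eigenvalues), sum(diag(cov(pc$adjusted))),
               tolerance = 1e-9)

  # identical specimens: no variance anywhere
  tab0 <- measurement_table(data.frame(
    specimen_id = paste0("s", 1:4), group = "g",
    CBL = 200, v1 = 50, v2 = 30))
  expect_lt(max(size_adjusted_pca(tab0)$eigenvalues), 1e-12)

  no_cbl <- measurement_table(data.frame(
    specimen_id = paste0("s", 1:4), group = "g", v1 = 1:4 + 0, v2 = 2))
  expect_error(size_adjusted_pca(no_cbl), "CBL")
})

test_that("PCA scores are invariant to variable order; log-shape works", {
  tab <- simulate_measurements(sim_spec(3, groups = list(
    list(label = "a", n = 8, mean_vector = c(CBL = 200, v1 = 50, v2 = 30)),
    list(label = "b", n = 8, mean_vector = c(CBL = 210, v1 = 65, v2 = 31)))))
  p1 <- size_adjusted_pca(tab, "log_shape")
  tab2 <- tab[, c("specimen_id", "group", "v2", "CBL", "v1")]
  class(tab2) <- class(tab)
  p2 <- size_adjusted_pca(tab2, "log_shape")
  expect_equal(abs(unname(p1$scores)), abs(unname(p2$scores)),
               tolerance = 1e-9)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-9)
})

test_that("jackknifed DFA separates distant groups and classifies holdouts", {
  set.seed(5)
  n <- 20
  X <- rbind(matrix(rnorm(2 * n, 0, 1), n, 2),
             matrix(rnorm(2 * n, 10, 1), n, 2))
  rownames(X) <- paste0("s", seq_len(2 * n))
  g <- rep(c("A", "B"), each = n)
  res <- dfa_jackknife(X, g)
  expect_equal(res$loo_accuracy, 1)
  expect_equal(unname(res$per_group_accuracy), c(1, 1))

  # a held-out specimen drawn from A's distribution classifies as A
  Xh <- rbind(X, holdme = rnorm(2, 0, 1))
  res2 <- dfa_jackknife(Xh, c(g, "A"), holdout_label = "holdme")
  expect_equal(res2$holdout$predicted, "A")
})

test_that("identical group distributions classify at chance level", {
  set.seed(71)
  n <- 60
  X <- matrix(rnorm(2 * 2 * n), 2 * n, 2)
  g <- rep(c("A", "B"), each = n)
  res <- dfa_jackknife(X, g)
  p <- res$loo_accuracy
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / (2 * n)))
})

test_that("DFA guards: small groups, singular covariance, rescaling invariance", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(dfa_jackknife(X, c("a", "a", "a", "b", "b", "c")),
               ">= 2 groups with >= 3 members")
  # perfectly collinear variables: singular without shrinkage
  Y <- cbind(rnorm(12), 0)
  Y[, 2] <- 2 * Y[, 1]
  expect_error(dfa_jackknife(Y, rep(c("a", "b"), each = 6), shrinkage = 0),
               "shrinkage")
  # affine rescaling of one variable does not change assignments
  set.seed(4)
  Z <- rbind(matrix(rnorm(20, 0, 1), 10), matrix(rnorm(20, 4, 1), 10))
  g <- rep(c("a", "b"), each = 10)
  r1 <- dfa_jackknife(Z, g)
  Z2 <- Z
  Z2[, 2] <- Z2[, 2] * 1000 + 5
  r2 <- dfa_jackknife(Z2, g)
  expect_identical(r1$loo_predicted, r2$loo_predicted)
})
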