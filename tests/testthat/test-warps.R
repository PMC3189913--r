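fit_two_groups <- function(seed = 11, n = 15, noise = 0.02, offset = 0.3) {
  mu <- base_shape(8)
  spec <- sim_spec(seed, groups = list(
    list(label = "A", n = n, mean_shape = mu, noise_sd = noise),
    list(label = "B", n = n,
         mean_shape = mu + offset * cbind(mu[, 1]^2, 0), noise_sd = noise)))
  generalized_procrustes(simulate_landmarks(spec))
}

test_that("the bending-energy matrix is PSD with a 3-dimensional affine null space", {
  ref <- base_shape(9)
  B <- bending_energy_matrix(ref)
  ev <- eigen(B, symmetric = TRUE)$values
  expect_gt(min(ev), -1e-9)
  expect_equal(sum(abs(ev) < 1e-9), 3)
  # the null space is spanned by 1, x, y
  expect_lt(max(abs(B %*% cbind(1, ref))), 1e-9)
})

test_that("specimens identical to the consensus have all-zero scores", {
  mu <- base_shape(7)
  cfgs <- lapply(1:4, function(i) landmark_config(mu, paste0("s", i)))
  dec <- partial_warps(generalized_procrustes(cfgs))
  expect_lt(max(abs(dec$scores)), 1e-10)
})

test_that("a deformation along one principal warp scores only on that warp pair", {
  mu0 <- base_shape(8)
  fit0 <- generalized_procrustes(
    lapply(1:4, function(i) landmark_config(mu0, paste0("s", i))))
  ref <- fit0$mean_shape
  E <- eigen(bending_energy_matrix(ref), symmetric = TRUE)$vectors[, 2]
  eps <- 1e-3
  cfgs <- list(landmark_config(ref, "c1"),
               landmark_config(ref + eps * cbind(E, 0), "c2"),
               landmark_config(ref - eps * cbind(E, 0), "c3"),
               landmark_config(ref, "c4"))
  dec <- partial_warps(generalized_procrustes(cfgs))
  s2 <- dec$scores["c2", ]
  # the global identifiability rotation mixes x and y, so the signal lives
  # in the PW2 pair; every other warp pair must stay at noise level
  pair <- c("PW2X", "PW2Y")
  expect_gt(sqrt(sum(s2[pair]^2)), eps / 2)
  expect_lt(max(abs(s2[setdiff(names(s2), pair)])), eps * 1e-2)
})

test_that("summed squared scores equal the tangent-space variance (Pythagoras)", {
  fit <- fit_two_groups(seed = 41, n = 8)
  dec <- partial_warps(fit)
  ref <- fit$mean_shape; k <- nrow(ref)
  V <- sapply(seq_len(fit$n), function(i) {
    d <- fit$aligned[, , i] - ref
    c(d[, 1], d[, 2])
  })
  xr <- ref[, 1] - mean(ref[, 1]); yr <- ref[, 2] - mean(ref[, 2])
  S <- cbind(c(rep(1, k), rep(0, k)) / sqrt(k),
             c(rep(0, k), rep(1, k)) / sqrt(k),
             c(xr, yr) / sqrt(sum(xr^2 + yr^2)),
             c(-yr, xr) / sqrt(sum(xr^2 + yr^2)))
  Vt <- V - S %*% (t(S) %*% V)
  expect_equal(sum(dec$scores^2), sum(Vt^2), tolerance = 1e-9)
})

test_that("alpha = 0 relative warps equal a covariance PCA of the scores", {
  dec <- partial_warps(fit_two_groups(seed = 19, n = 10))
  rw <- relative_warps(dec, alpha = 0)
  pc <- stats::prcomp(dec$scores, center = TRUE, scale. = FALSE)
  p <- ncol(rw$rw_scores)
  # align prcomp's sign convention to ours before the exact comparison
  for (j in seq_len(p)) {
    nz <- which(abs(pc$rotation[, j]) > 1e-12)
    if (length(nz) && pc$rotation[nz[1], j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  expect_equal(unname(rw$rw_scores), unname(pc$x[, seq_len(p)]),
               tolerance = 1e-9)
  expect_equal(rw$rw_eigenvalues, unname(pc$sdev[seq_len(p)]^2),
               tolerance = 1e-9)
  expect_equal(sum(rw$rw_eigenvalues), sum(diag(stats::cov(dec$scores))),
               tolerance = 1e-9)
})

test_that("well-separated groups split on the first relative warp", {
  rw <- relative_warps(partial_warps(fit_two_groups(seed = 11)))
  a <- rw$rw_scores[rw$group == "A", 1]
  b <- rw$rw_scores[rw$group == "B", 1]
  between <- abs(mean(a) - mean(b))
  within <- mean(c(sd(a), sd(b)))
  expect_gt(between, 5 * within)
})

test_that("small or affine-only configurations are rejected", {
  tri <- lapply(1:4, function(i)
    landmark_config(cbind(c(0, 1, 0), c(0, 0, 1)), paste0("t", i)))
  expect_error(partial_warps(generalized_procrustes(tri)), "k <= 3")
  two <- random_configs(2, 6, seed = 2)
  expect_error(partial_warps(generalized_procrustes(two)), ">= 3 specimens")
})
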