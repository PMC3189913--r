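# deterministic sign convention: first element of largest magnitude-rank...
# we fix each basis vector so its first nonzero entry is positive.
fix_sign <- function(M, tol = 1e-12) {
  for (j in seq_len(ncol(M))) {
    nz <- which(abs(M[, j]) > tol)
    if (length(nz) && M[nz[1], j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Partial-warp and uniform-component decomposition
#'
#' Decomposes the Procrustes-aligned shape variation into non-uniform
#' (partial warp) and uniform (affine) components. Principal warps are the
#' eigenvectors of the consensus bending-energy matrix restricted to the
#' non-affine subspace, ordered by decreasing bending energy; each specimen's
#' deviation from the consensus is projected onto them, per coordinate,
#' giving 2(k-3) partial-warp scores. The uniform component is computed by
#' the complement method: the orthogonal complement of the non-uniform
#' subspace within the tangent space at the consensus (2 dimensions, columns
#' `UniX`/`UniY`). Together the 2k-4 scores are coordinates in an orthonormal
#' basis of the tangent space, so summed squared scores equal tangent-space
#' distances.
#'
#' @param fit a [generalized_procrustes()] fit with >= 3 specimens and k >= 4
#'   landmarks (k <= 3 has an empty bending subspace).
#' @return An object of class `warp_decomposition`: `reference`,
#'   `be_matrix`, `principal_warps` (k x (k-3)), `pw_bending_energy`,
#'   `partial_warp_scores` (n x 2(k-3)), `uniform_scores` (n x 2), `scores`
#'   (the two blocks column-bound), `specimen_id`, `group`, `k`, `n`.
#' @export
partial_warps <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  k <- fit$k; n <- fit$n
  if (k <= 3) stop("k <= 3: no bending (non-affine) subspace exists")
  if (n < 3) stop("need >= 3 specimens")
  ref <- fit$mean_shape
  BE <- bending_energy_matrix(ref)
  eg <- eigen(BE, symmetric = TRUE)
  keep <- seq_len(k - 3)  # eigenvalues sorted decreasing; last 3 are ~0
  E <- fix_sign(eg$vectors[, keep, drop = FALSE])
  lambda <- eg$values[keep]

  # orthonormal similarity directions in R^{2k} (stacked x then y)
  xr <- ref[, 1] - mean(ref[, 1]); yr <- ref[, 2] - mean(ref[, 2])
  S <- cbind(c(rep(1, k), rep(0, k)) / sqrt(k),
             c(rep(0, k), rep(1, k)) / sqrt(k),
             c(xr, yr) / sqrt(sum(xr^2 + yr^2)),
             c(-yr, xr) / sqrt(sum(xr^2 + yr^2)))
  # non-uniform basis: each principal warp on x and on y
  N <- cbind(rbind(E, matrix(0, k, k - 3)), rbind(matrix(0, k, k - 3), E))
  # uniform = orthogonal complement of span(S, N) in R^{2k} (2 dims)
  QQ <- qr.Q(qr(cbind(S, N)), complete = TRUE)
  Ub <- fix_sign(QQ[, (2 * k - 1):(2 * k), drop = FALSE])

  V <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) {
    d <- fit$aligned[, , i] - ref
    V[i, ] <- c(d[, 1], d[, 2])
  }
  # project residuals into the tangent space (drop similarity residue)
  V <- V - V %*% S %*% t(S)

  pw_x <- V[, seq_len(k), drop = FALSE] %*% E
  pw_y <- V[, k + seq_len(k), drop = FALSE] %*% E
  pw <- matrix(NA_real_, n, 2 * (k - 3))
  pw[, seq(1, 2 * (k - 3), by = 2)] <- pw_x
  pw[, seq(2, 2 * (k - 3), by = 2)] <- pw_y
  colnames(pw) <- paste0("PW", rep(seq_len(k - 3), each = 2), c("X", "Y"))
  uni <- V %*% Ub
  colnames(uni) <- c("UniX", "UniY")
  scores <- cbind(pw, uni)
  rownames(scores) <- fit$specimen_id
  structure(
    list(reference = ref, be_matrix = BE, principal_warps = E,
         pw_bending_energy = lambda,
         partial_warp_scores = pw, uniform_scores = uni, scores = scores,
         uniform_basis = Ub,
         specimen_id = fit$specimen_id, group = fit$group, k = k, n = n),
    class = "warp_decomposition")
}

#' Relative warps (principal components of warp scores)
#'
#' At `alpha = 0` a relative-warps analysis is a principal components
#' analysis of the covariance matrix of the partial-warp (plus, by default,
#' uniform) scores. Non-zero `alpha` re-weights each partial-warp pair by its
#' bending energy to the power `-alpha/2` (uniform columns are unweighted)
#' before the PCA.
#'
#' @param decomp a [partial_warps()] decomposition with >= 3 specimens.
#' @param alpha warp-weighting exponent; 0 (the default) gives an ordinary
#'   covariance PCA of the scores.
#' @param include_uniform include the uniform component in the PCA (default
#'   TRUE, matching common relative-warp practice).
#' @return The decomposition with fields added: `rw_scores` (n x p),
#'   `rw_eigenvalues` (variances, descending), `rw_loadings`, `alpha`.
#'   Loading signs follow the convention that the first nonzero loading of
#'   each component is positive.
#' @export
relative_warps <- function(decomp, alpha = 0, include_uniform = TRUE) {
  stopifnot(inherits(decomp, "warp_decomposition"))
  if (decomp$n < 3) stop("need >= 3 specimens for relative warps")
  M <- if (include_uniform) decomp$scores else decomp$partial_warp_scores
  if (alpha != 0) {
    w <- rep(decomp$pw_bending_energy^(-alpha / 2), each = 2)
    if (include_uniform) w <- c(w, 1, 1)
    M <- sweep(M, 2, w, `*`)
  }
  Mc <- sweep(M, 2, colMeans(M))
  C <- crossprod(Mc) / (nrow(Mc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  p <- min(nrow(Mc) - 1, ncol(Mc))
  load <- fix_sign(eg$vectors[, seq_len(p), drop = FALSE])
  vals <- pmax(eg$values[seq_len(p)], 0)
  sc <- Mc %*% load
  colnames(sc) <- paste0("RW", seq_len(p))
  rownames(sc) <- decomp$specimen_id
  decomp$rw_scores <- sc
  decomp$rw_eigenvalues <- vals
  decomp$rw_loadings <- load
  decomp$alpha <- alpha
  decomp
}

#' @export
print.warp_decomposition <- function(x, ...) {
  cat("<warp_decomposition>", x$n, "specimens,", x$k, "landmarks;",
      ncol(x$partial_warp_scores) / 2, "partial warps + uniform component\n")
  if (!is.null(x$rw_eigenvalues))
    cat("  relative warps (alpha =", x$alpha, "): first eigenvalues",
        paste(formatC(head(x$rw_eigenvalues, 3), format = "e", digits = 2),
              collapse = ", "), "\n")
  invisible(x)
}

#' Export a deformation grid for plotting
#'
#' Evaluates the thin-plate spline from the consensus to a target
#' configuration on a regular grid, for deformation-grid figures.
#'
#' @param decomp a `warp_decomposition`.
#' @param target k x 2 target configuration (e.g. one specimen's aligned
#'   coordinates, or consensus + a multiple of a principal warp).
#' @param n_grid grid lines per axis (default 24).
#' @param pad fractional margin around the reference (default 0.1).
#' @return data frame with columns `x0`, `y0` (grid) and `x`, `y` (mapped).
#' @export
deformation_grid <- function(decomp, target, n_grid = 24, pad = 0.1) {
  stopifnot(inherits(decomp, "warp_decomposition"))
  ref <- decomp$reference
  sp <- tps_fit(ref, target)
  rx <- range(ref[, 1]); ry <- range(ref[, 2])
  ex <- diff(rx) * pad; ey <- diff(ry) * pad
  g <- expand.grid(x0 = seq(rx[1] - ex, rx[2] + ex, length.out = n_grid),
                   y0 = seq(ry[1] - ey, ry[2] + ey, length.out = n_grid))
  m <- predict(sp, as.matrix(g))
  data.frame(g, x = m[, 1], y = m[, 2])
}
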