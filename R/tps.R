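# Thin-plate spline kernel U(r) = r^2 log(r^2), the fundamental solution of
# the biharmonic equation (up to a constant): Delta^2 U = 16 pi delta.
# U(0) is defined as the limit value 0 to avoid the log singularity.
tps_kernel <- function(r2) {
  u <- numeric(length(r2))
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos])
  dim(u) <- dim(r2)
  u
}

# pairwise squared distances between rows of two point sets
pairwise_r2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
}

#' Fit a thin-plate spline between two landmark configurations
#'
#' Finds the pair of interpolating functions (f_x, f_y) that map the
#' reference landmarks exactly onto the target landmarks while minimizing the
#' integrated squared second derivatives (bending energy). Each function is
#' an affine part plus a weighted sum of kernels U(r) = r^2 log(r^2) centered
#' at the reference landmarks; the kernel weights satisfy the side conditions
#' (zero sum and zero coordinate-weighted sums), which make the bending
#' energy finite.
#'
#' @param reference,target k x 2 coordinate matrices (or `landmark_config`s)
#'   with equal k >= 3; the reference must not be collinear.
#' @return An object of class `tps_spline`: `reference`, `target`, `weights`
#'   (k x 2, one column per output coordinate), `affine` (3 x 2: constant, x,
#'   y coefficients), `k`.
#' @examples
#' ref <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' tgt <- ref + 0.1 * cbind(c(0, 0, 1, 0), c(1, 0, 0, 0))
#' sp <- tps_fit(ref, tgt)
#' bending_energy(sp)
#' @export
tps_fit <- function(reference, target) {
  ref <- if (inherits(reference, "landmark_config")) reference$coords else as.matrix(reference)
  tgt <- if (inherits(target, "landmark_config")) target$coords else as.matrix(target)
  if (!identical(dim(ref), dim(tgt))) stop("landmark count mismatch")
  k <- nrow(ref)
  if (k < 3) stop("need k >= 3 landmarks")
  K <- tps_kernel(pairwise_r2(ref, ref))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rc <- rcond(L)
  if (!is.finite(rc) || rc < 1e-14)
    stop("singular TPS system: reference landmarks are collinear ",
         "(or coincident); jitter them slightly or review the landmarks")
  coef <- solve(L, rbind(tgt, matrix(0, 3, 2)))
  structure(
    list(reference = ref, target = tgt,
         weights = coef[seq_len(k), , drop = FALSE],
         affine = coef[k + 1:3, , drop = FALSE],
         k = k),
    class = "tps_spline")
}

#' Evaluate a thin-plate spline at new points
#'
#' @param object a `tps_spline`.
#' @param newdata m x 2 matrix of points; defaults to the reference landmarks.
#' @param ... unused.
#' @return m x 2 matrix of mapped points.
#' @export
predict.tps_spline <- function(object, newdata = object$reference, ...) {
  P <- as.matrix(newdata)
  U <- tps_kernel(pairwise_r2(P, object$reference))
  cbind(1, P) %*% object$affine + U %*% object$weights
}

#' Bending energy of a thin-plate spline
#'
#' The integral over the plane of the squared second derivatives of the two
#' coordinate functions, computed through the closed quadratic form in the
#' kernel weights (exact for TPS): with U(r) = r^2 log(r^2),
#' E = 16 pi (w_x' K w_x + w_y' K w_y). Zero iff the map is affine.
#'
#' @param spline a `tps_spline`.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(spline) {
  stopifnot(inherits(spline, "tps_spline"))
  K <- tps_kernel(pairwise_r2(spline$reference, spline$reference))
  e <- 16 * pi * sum(vapply(1:2, function(j) {
    w <- spline$weights[, j]
    drop(crossprod(w, K %*% w))
  }, numeric(1)))
  # the form is PSD on the side-condition subspace; clamp roundoff negatives
  if (e < 0 && e > -1e-8) e <- 0
  e
}

#' Bending-energy matrix of a reference configuration
#'
#' The k x k matrix whose quadratic form gives (up to the 16 pi constant) the
#' bending energy of any displacement of the reference landmarks: the upper
#' k x k block of the inverse of the bordered TPS system. It is positive
#' semi-definite with exactly three zero eigenvalues (the affine null space
#' spanned by the constant and the two reference coordinate vectors).
#'
#' @param reference k x 2 coordinate matrix (k >= 4 for a non-empty bending
#'   subspace) or `landmark_config`.
#' @return Symmetric k x k matrix.
#' @export
bending_energy_matrix <- function(reference) {
  ref <- if (inherits(reference, "landmark_config")) reference$coords else as.matrix(reference)
  k <- nrow(ref)
  K <- tps_kernel(pairwise_r2(ref, ref))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rc <- rcond(L)
  if (!is.finite(rc) || rc < 1e-14)
    stop("singular TPS system: reference landmarks are collinear")
  Linv <- solve(L)
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (B + t(B)) / 2
}
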