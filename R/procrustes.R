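# Optimal rotation (no reflection) of A onto B, both centered k x 2.
# Returns the 2 x 2 rotation R minimizing ||A %*% R - B||_F with det(R) = +1.
rotation_onto <- function(A, B) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 2] <- -u[, 2]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes superimposition
#'
#' Iteratively centers every configuration, scales it to unit centroid size,
#' rotates it (rotation only, reflections disallowed: anatomical lateral
#' views have fixed handedness) onto the current consensus, and re-estimates
#' the consensus until the consensus update falls below `tol`. For
#' identifiability the converged solution is rotated so that the first
#' specimen lies along its principal axes.
#'
#' @param configs list of [landmark_config()] objects, equal k >= 3.
#' @param tol convergence tolerance on the Frobenius norm of the consensus
#'   update (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return An object of class `procrustes_fit`: `aligned` (k x 2 x n array),
#'   `mean_shape` (arithmetic mean of the aligned configurations),
#'   `iterations`, `residual_change`, `specimen_id`, `group`, `k`, `n`.
#' @examples
#' set.seed(1)
#' base <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' cfgs <- lapply(1:5, function(i)
#'   landmark_config(base + matrix(rnorm(8, 0, 0.01), 4, 2), paste0("s", i)))
#' fit <- generalized_procrustes(cfgs)
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100L) {
  k <- check_landmark_set(configs)
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  X <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) {
    m <- configs[[i]]$coords
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < .Machine$double.eps * k)
      stop("configuration '", configs[[i]]$specimen_id,
           "' has zero centroid size")
    X[, , i] <- m / cs
  }
  consensus <- X[, , 1]
  iterations <- 0L
  change <- Inf
  while (iterations < max_iter && change > tol) {
    for (i in seq_len(n))
      X[, , i] <- X[, , i] %*% rotation_onto(X[, , i], consensus)
    new_cons <- apply(X, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    change <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    iterations <- iterations + 1L
  }
  # identifiability: principal axes of the first aligned specimen
  A <- crossprod(X[, , 1])
  ev <- eigen(A, symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 2] <- -ev[, 2]
  if (ev[1, 1] < 0) ev <- -ev
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% ev
  consensus <- consensus %*% ev
  dimnames(X) <- list(NULL, c("x", "y"),
                      vapply(configs, `[[`, character(1), "specimen_id"))
  structure(
    list(aligned = X,
         mean_shape = apply(X, c(1, 2), mean),
         iterations = iterations,
         residual_change = change,
         specimen_id = vapply(configs, `[[`, character(1), "specimen_id"),
         group = vapply(configs, `[[`, character(1), "group"),
         k = k, n = n),
    class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit>", x$n, "specimens,", x$k, "landmarks;",
      x$iterations, "iterations (final update",
      formatC(x$residual_change, format = "e", digits = 2), ")\n")
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, the
#' second is optimally rotated onto the first (no reflection), and the
#' Frobenius norm of the difference is returned.
#'
#' @param a,b `landmark_config` objects or k x 2 matrices with equal k.
#' @return Non-negative scalar; 0 iff the shapes are similarity-equivalent.
#' @export
procrustes_distance <- function(a, b) {
  ma <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  mb <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  if (!identical(dim(ma), dim(mb))) stop("landmark count mismatch")
  ma <- sweep(ma, 2, colMeans(ma)); ma <- ma / sqrt(sum(ma^2))
  mb <- sweep(mb, 2, colMeans(mb)); mb <- mb / sqrt(sum(mb^2))
  mb <- mb %*% rotation_onto(mb, ma)
  sqrt(sum((ma - mb)^2))
}
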