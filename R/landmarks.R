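#' Landmark configuration for one specimen
#'
#' An ordered set of 2-D landmarks digitized at homologous points (e.g. 16
#' cranial or 18 mandibular landmarks in lateral view), together with the
#' specimen and group (species/subspecies) labels. Landmark order must be
#' homologous across all specimens of one dataset.
#'
#' @param coords numeric k x 2 matrix of (x, y) coordinates, arbitrary units.
#'   Coordinates are Cartesian with y increasing upward; no image-row
#'   inversion is applied.
#' @param specimen_id character scalar.
#' @param group character scalar group label, `NA` if unknown.
#' @return An object of class `landmark_config` with fields `coords`,
#'   `specimen_id`, `group`, `k`.
#' @examples
#' landmark_config(cbind(c(0, 1, 0), c(0, 0, 1)), "sp1")
#' @export
landmark_config <- function(coords, specimen_id, group = NA_character_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be a k x 2 matrix of (x, y) pairs")
  storage.mode(coords) <- "double"
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs k >= 3 landmarks, got ", nrow(coords))
  if (!all(is.finite(coords)))
    stop("all landmark coordinates must be finite")
  structure(
    list(coords = unname(coords),
         specimen_id = as.character(specimen_id),
         group = as.character(group),
         k = nrow(coords)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> specimen", x$specimen_id,
      if (!is.na(x$group)) paste0("(", x$group, ")"),
      "-", x$k, "landmarks\n")
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; the size measure removed by Procrustes scaling.
#'
#' @param x a `landmark_config` or a k x 2 coordinate matrix.
#' @return Non-negative scalar.
#' @export
centroid_size <- function(x) {
  m <- if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
  m <- sweep(m, 2, colMeans(m))
  sqrt(sum(m^2))
}

# shared validation for lists of configurations
check_landmark_set <- function(configs) {
  if (!length(configs)) stop("empty landmark set")
  if (!all(vapply(configs, inherits, logical(1), "landmark_config")))
    stop("all elements must be landmark_config objects")
  ks <- vapply(configs, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L)
    stop("landmark count differs across configurations: ",
         paste(unique(ks), collapse = ", "))
  invisible(ks[1])
}
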