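# Named sub-streams: each generator seeds its own RNG stream from the single
# spec seed plus a fixed generator offset, so adding draws to one generator
# never perturbs another's output.
substream_seed <- function(seed, name) {
  offset <- c(landmarks = 101L, characters = 202L, measurements = 303L)[[name]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

#' Simulation specification
#'
#' A single reproducible description of the synthetic inputs: groups with
#' mean shapes or mean measurement vectors, sample sizes and noise levels; an
#' optional generating tree and character-count with a homoplasy rate.
#'
#' @param seed integer master seed; every generator derives its own named
#'   sub-stream from it.
#' @param groups list of group descriptions, each a list with `label`, `n`
#'   (>= 1), and `mean_shape` (k x 2 matrix, for landmarks) and/or
#'   `mean_vector` (named numeric, for measurements), plus `noise_sd` /
#'   `cv` as applicable.
#' @param tree optional generating `phylo` for character simulation.
#' @param n_chars number of characters to simulate.
#' @param homoplasy_rate per-character probability of one extra convergent
#'   state change, in \[0, 1\].
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(seed, groups = list(), tree = NULL, n_chars = NULL,
                     homoplasy_rate = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (homoplasy_rate < 0 || homoplasy_rate > 1)
    stop("homoplasy_rate must be in [0, 1]")
  for (g in groups) {
    if (is.null(g$label)) stop("every group needs a label")
    if (is.null(g$n) || g$n < 1) stop("group '", g$label, "': n must be >= 1")
  }
  structure(list(seed = as.integer(seed), groups = groups, tree = tree,
                 n_chars = n_chars, homoplasy_rate = homoplasy_rate),
            class = "sim_spec")
}

#' Simulate multi-species landmark samples
#'
#' Each specimen is its group's mean shape plus i.i.d. isotropic Gaussian
#' landmark noise, then pushed through a random similarity transform
#' (rotation uniform on the circle, scale uniform in \[0.5, 2\], translation
#' uniform in \[-10, 10\] per axis) so that Procrustes superimposition has
#' real work to do. Bit-reproducible given the spec seed.
#'
#' @param spec a [sim_spec()] whose groups carry `mean_shape` (shared k) and
#'   `noise_sd` (> 0).
#' @return list of [landmark_config()] objects with specimen ids
#'   `<label>_<i>`.
#' @export
simulate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  shapes <- lapply(spec$groups, `[[`, "mean_shape")
  if (any(vapply(shapes, is.null, logical(1))))
    stop("every group needs a mean_shape")
  ks <- vapply(shapes, nrow, integer(1))
  if (length(unique(ks)) != 1) stop("mean shapes must share k")
  set.seed(substream_seed(spec$seed, "landmarks"))
  out <- list()
  for (g in spec$groups) {
    sdg <- if (is.null(g$noise_sd)) 0.01 else g$noise_sd
    if (sdg <= 0) stop("noise_sd must be > 0")
    k <- nrow(g$mean_shape)
    for (i in seq_len(g$n)) {
      coords <- g$mean_shape + matrix(rnorm(2 * k, 0, sdg), k, 2)
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      s <- runif(1, 0.5, 2)
      tr <- runif(2, -10, 10)
      coords <- s * coords %*% R
      coords <- sweep(coords, 2, tr, `+`)
      out[[length(out) + 1L]] <-
        landmark_config(coords, paste0(g$label, "_", i), g$label)
    }
  }
  out
}

#' Simulate a character matrix on a known tree
#'
#' Generates binary characters that are each perfectly compatible with the
#' generating tree: an internal edge is chosen (uniformly at random, or
#' cycling deterministically through the internal edges so that each is
#' covered evenly), and the clade below it receives the derived state. With
#' probability `homoplasy_rate` a character additionally flips one random
#' taxon outside the clade, creating one convergent extra step. The engine
#' handles multistate characters; the simulator deliberately emits binary
#' ones, which suffice for every tree-recovery property.
#'
#' @param spec a [sim_spec()] with `tree` (rooted `phylo`, >= 4 leaves) and
#'   `n_chars` >= 1.
#' @param edge_choice `"random"` (default) or `"cycle"` (character i maps to
#'   internal edge (i-1) mod n_edges + 1, guaranteeing even coverage).
#' @return A [character_matrix()].
#' @export
simulate_characters <- function(spec, edge_choice = c("random", "cycle")) {
  edge_choice <- match.arg(edge_choice)
  stopifnot(inherits(spec, "sim_spec"))
  tree <- spec$tree
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("spec$tree must be a phylo object")
  if (length(tree$tip.label) < 4) stop("generating tree needs >= 4 leaves")
  if (is.null(spec$n_chars) || spec$n_chars < 1) stop("n_chars must be >= 1")
  n <- length(tree$tip.label)
  root <- n + 1L
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  if (!length(internal_children))
    stop("tree has no internal edges (star tree)")
  clades <- lapply(internal_children, function(nd)
    ape::extract.clade(tree, nd)$tip.label)
  # drop clades equal to the whole leaf set (can occur for the root child
  # of a rooted-on-edge tree); such a "split" is uninformative
  keep <- vapply(clades, function(cl) length(cl) < n, logical(1))
  clades <- clades[keep]
  set.seed(substream_seed(spec$seed, "characters"))
  states <- matrix("0", n, spec$n_chars)
  rownames(states) <- tree$tip.label
  for (j in seq_len(spec$n_chars)) {
    ci <- if (edge_choice == "cycle") ((j - 1L) %% length(clades)) + 1L
          else sample.int(length(clades), 1)
    derived <- clades[[ci]]
    states[derived, j] <- "1"
    if (runif(1) < spec$homoplasy_rate) {
      outside <- setdiff(tree$tip.label, derived)
      flip <- outside[sample.int(length(outside), 1)]
      states[flip, j] <- "1"
    }
  }
  character_matrix(states)
}

#' Simulate a measurement table with allometric structure
#'
#' Per specimen, each variable is the group mean times a shared per-specimen
#' size factor exp(N(0, size_sd)) (implementing allometric size variation
#' common to all measurements) times independent lognormal noise
#' exp(N(0, cv)). All values are positive by construction.
#'
#' @param spec a [sim_spec()] whose groups carry `mean_vector` (named, shared
#'   names, including `CBL`), `n`, and optionally `cv` (default 0.05) and
#'   `size_sd` (default 0.05).
#' @return A [measurement_table()].
#' @export
simulate_measurements <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  mv <- lapply(spec$groups, `[[`, "mean_vector")
  if (any(vapply(mv, is.null, logical(1))))
    stop("every group needs a mean_vector")
  nm <- names(mv[[1]])
  if (!("CBL" %in% nm)) stop("mean vectors must include CBL")
  if (!all(vapply(mv, function(v) identical(names(v), nm), logical(1))))
    stop("mean vectors must share variable names")
  set.seed(substream_seed(spec$seed, "measurements"))
  rows <- list()
  for (g in spec$groups) {
    cv <- if (is.null(g$cv)) 0.05 else g$cv
    size_sd <- if (is.null(g$size_sd)) 0.05 else g$size_sd
    for (i in seq_len(g$n)) {
      size <- exp(rnorm(1, 0, size_sd))
      vals <- g$mean_vector * size * exp(rnorm(length(nm), 0, cv))
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = paste0(g$label, "_", i), group = g$label,
        as.list(vals), check.names = FALSE)
    }
  }
  measurement_table(do.call(rbind, rows))
}
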