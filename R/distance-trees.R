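#' Pairwise distances between score vectors
#'
#' Euclidean or squared-Euclidean distances between per-specimen score
#' vectors (e.g. relative-warp or principal-component scores), optionally
#' between group centroids instead of specimens.
#'
#' @param scores numeric matrix (rows = specimens, named) or data frame.
#' @param metric `"euclidean"` or `"squared_euclidean"`.
#' @param by_group aggregate rows to group centroids before computing
#'   distances.
#' @param groups group label per row (required when `by_group`).
#' @param agg centroid function when aggregating: `"mean"` (default) or
#'   `"median"`.
#' @return An object of class `distance_matrix`: `labels`, `matrix`
#'   (symmetric, zero diagonal), `metric`.
#' @export
score_distances <- function(scores, metric = c("euclidean", "squared_euclidean"),
                            by_group = FALSE, groups = NULL,
                            agg = c("mean", "median")) {
  metric <- match.arg(metric)
  agg <- match.arg(agg)
  M <- as.matrix(scores)
  if (by_group) {
    if (is.null(groups) || length(groups) != nrow(M))
      stop("by_group requires one group label per row")
    f <- if (agg == "mean") colMeans else function(x) apply(x, 2, stats::median)
    gl <- sort(unique(groups))
    M <- do.call(rbind, lapply(gl, function(g) f(M[groups == g, , drop = FALSE])))
    rownames(M) <- gl
  }
  if (is.null(rownames(M))) rownames(M) <- paste0("item_", seq_len(nrow(M)))
  d <- as.matrix(stats::dist(M, method = "euclidean"))
  if (metric == "squared_euclidean") d <- d^2
  structure(list(labels = rownames(M), matrix = unname(d), metric = metric),
            class = "distance_matrix")
}

#' Construct a distance matrix object
#'
#' @param m symmetric non-negative matrix with zero diagonal.
#' @param labels item labels (defaults to rownames).
#' @param metric metric name.
#' @return A `distance_matrix`.
#' @export
distance_matrix <- function(m, labels = rownames(m), metric = "euclidean") {
  m <- as.matrix(m)
  if (is.null(labels)) stop("labels required")
  if (nrow(m) != ncol(m) || length(labels) != nrow(m)) stop("shape mismatch")
  if (any(is.na(m))) stop("NaN/NA distances are not allowed")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric (tol 1e-12)")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  structure(list(labels = as.character(labels), matrix = unname(m),
                 metric = metric),
            class = "distance_matrix")
}

#' UPGMA (average-linkage) clustering into an ultrametric tree
#'
#' Agglomerates the two clusters with the smallest average inter-cluster
#' distance, with ties broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its lexicographically smallest
#' member), and places each merge node at height merge-distance / 2. The
#' result is ultrametric by construction.
#'
#' @param dm a [distance_matrix()] with n >= 2 items.
#' @return A rooted, ultrametric ape `phylo` with branch lengths.
#' @export
upgma <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- length(dm$labels)
  if (n < 2) stop("need >= 2 items")
  if (any(is.na(dm$matrix))) stop("NaN distances are not allowed")
  D <- dm$matrix
  active <- seq_len(n)
  size <- rep(1, n)
  height <- rep(0, n)
  newick <- dm$labels
  minlab <- dm$labels
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      dij <- D[i, j]
      pair <- sort(c(minlab[i], minlab[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(i = i, j = j, d = dij, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    new_id <- length(size) + 1L
    size[new_id] <- size[i] + size[j]
    height[new_id] <- h
    # order children lexicographically for a deterministic newick
    ord <- order(c(minlab[i], minlab[j]))
    kids <- c(i, j)[ord]
    newick[new_id] <- paste0(
      "(", newick[kids[1]], ":", format(h - height[kids[1]], digits = 17),
      ",", newick[kids[2]], ":", format(h - height[kids[2]], digits = 17), ")")
    minlab[new_id] <- min(minlab[i], minlab[j])
    # average-linkage update
    D <- rbind(cbind(D, 0), 0)
    for (a in setdiff(active, c(i, j)))
      D[new_id, a] <- D[a, new_id] <-
        (size[i] * D[a, i] + size[j] * D[a, j]) / (size[i] + size[j])
    active <- c(setdiff(active, c(i, j)), new_id)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Check outgroup placement on a rooted tree
#'
#' UPGMA trees are rooted by their ultrametricity, not by the outgroup; this
#' reports whether the designated outgroup is monophyletic and basal (one of
#' the two clades meeting at the root) and annotates the tree. No re-rooting
#' is performed.
#'
#' @param tree a rooted ape `phylo`.
#' @param outgroup_labels character vector of outgroup tip labels.
#' @return list with `tree` (annotated via attribute `outgroup_status`),
#'   `monophyletic_basal` (logical), `status` (`"monophyletic-basal"` or
#'   `"non-basal"`), and for non-basal placements `offending_clade` (the
#'   smallest clade containing the outgroup).
#' @export
outgroup_orient <- function(tree, outgroup_labels) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(outgroup_labels, tree$tip.label)
  if (length(unknown))
    stop("unknown outgroup label(s): ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  root_clades <- lapply(kids, function(k) {
    if (k <= n) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
  og <- sort(outgroup_labels)
  basal <- any(vapply(root_clades, function(cl) identical(sort(cl), og),
                      logical(1)))
  if (basal) {
    attr(tree, "outgroup_status") <- "monophyletic-basal"
    return(list(tree = tree, monophyletic_basal = TRUE,
                status = "monophyletic-basal"))
  }
  mrca <- if (length(outgroup_labels) == 1)
    which(tree$tip.label == outgroup_labels)
  else ape::getMRCA(tree, outgroup_labels)
  clade <- if (mrca <= n) tree$tip.label[mrca]
  else ape::extract.clade(tree, mrca)$tip.label
  attr(tree, "outgroup_status") <- "non-basal"
  list(tree = tree, monophyletic_basal = FALSE, status = "non-basal",
       offending_clade = sort(clade))
}

#' Cophenetic distances implied by an ultrametric tree
#'
#' @param tree a `phylo` with branch lengths.
#' @return A symmetric matrix of path distances between tips.
#' @export
tree_cophenetic <- function(tree) {
  stats::cophenetic(tree)
}
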