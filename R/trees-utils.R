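# Internal unrooted-binary-tree machinery for the parsimony searches.
#
# A topology is an integer edge matrix (m x 2, undirected). Tips carry their
# original ids 1..N (N = total taxa in the dataset; a partial tree uses a
# subset); internal nodes are ids > N. For a tree on t tips there are 2t - 3
# edges and t - 2 internal nodes.

# the unique unrooted topology on three tips
base_tree3 <- function(tips, N) {
  cbind(rep(N + 1L, 3L), as.integer(tips))
}

# insert a new tip on edge `ei`, creating internal node `new_internal`
insert_tip <- function(edges, ei, tip, new_internal) {
  a <- edges[ei, 1]; b <- edges[ei, 2]
  edges[ei, ] <- c(a, new_internal)
  rbind(edges, c(new_internal, b), c(new_internal, as.integer(tip)))
}

# flatten/unflatten between m x 2 matrices and length-2m rows (p,c,p,c,...)
flatten_edges <- function(edges) as.integer(t(edges))
unflatten_edges <- function(row) matrix(as.integer(row), ncol = 2, byrow = TRUE)

#' Enumerate all unrooted binary topologies
#'
#' Exhaustively generates every unrooted binary tree on the given tips by
#' stepwise addition ((2t-5)!! topologies). Practical to about 9 or 10 tips;
#' used as the exact-search oracle.
#'
#' @param n_tips number of tips (ids 1..n_tips).
#' @return Integer matrix with one topology per row, each row the flattened
#'   (parent, child) edge list.
#' @keywords internal
#' @export
enumerate_topologies <- function(n_tips) {
  N <- as.integer(n_tips)
  if (N < 3) stop("need at least 3 tips")
  trees <- list(base_tree3(1:3, N))
  for (t_next in seq_len(N)[-(1:3)]) {
    new_internal <- N + t_next - 2L
    out <- vector("list", length(trees) * (2L * (t_next - 1L) - 3L))
    z <- 0L
    for (tr in trees) {
      for (ei in seq_len(nrow(tr))) {
        z <- z + 1L
        out[[z]] <- insert_tip(tr, ei, t_next, new_internal)
      }
    }
    trees <- out
  }
  do.call(rbind, lapply(trees, flatten_edges))
}

# adjacency list of an undirected edge matrix
edge_adjacency <- function(edges) {
  maxn <- max(edges)
  adj <- vector("list", maxn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# tip ids reachable from `start` without crossing the edge (avoid_a, avoid_b)
tips_on_side <- function(adj, start, avoid, n_tips) {
  seen <- integer(0)
  stack <- start
  prev <- avoid
  visited <- c(avoid)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u %in% visited) next
    visited <- c(visited, u)
    if (u <= n_tips) seen <- c(seen, u)
    stack <- c(stack, setdiff(adj[[u]], visited))
  }
  sort(seen)
}

# canonical bipartition set of an unrooted topology: for each internal edge,
# the tip set on the side not containing the smallest tip present
tree_bipartitions <- function(edges, n_tips) {
  adj <- edge_adjacency(edges)
  tips <- sort(unique(edges[edges <= n_tips]))
  ref_tip <- tips[1]
  res <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (a <= n_tips || b <= n_tips) next  # pendant edge: trivial split
    side_a <- tips_on_side(adj, a, b, n_tips)
    part <- if (ref_tip %in% side_a) setdiff(tips, side_a) else side_a
    res[[length(res) + 1L]] <- part
  }
  res
}

# canonical hash for deduplication up to unrooted isomorphism
tree_key <- function(edges, n_tips) {
  bp <- tree_bipartitions(edges, n_tips)
  paste(sort(vapply(bp, paste, character(1), collapse = ",")), collapse = "|")
}

# all nearest-neighbor-interchange rearrangements
nni_neighbors <- function(edges, n_tips) {
  adj <- edge_adjacency(edges)
  out <- list()
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    if (u <= n_tips || v <= n_tips) next
    us <- setdiff(adj[[u]], v)  # two subtrees on u's side
    vs <- setdiff(adj[[v]], u)  # two on v's side
    for (w in vs) {
      # swap us[2] with w
      ne <- edges
      i1 <- which((ne[, 1] == u & ne[, 2] == us[2]) | (ne[, 1] == us[2] & ne[, 2] == u))
      i2 <- which((ne[, 1] == v & ne[, 2] == w) | (ne[, 1] == w & ne[, 2] == v))
      ne[i1, ] <- c(u, w)
      ne[i2, ] <- c(v, us[2])
      out[[length(out) + 1L]] <- ne
    }
  }
  out
}

# all subtree-prune-regraft rearrangements
spr_neighbors <- function(edges, n_tips) {
  out <- list()
  m <- nrow(edges)
  adj <- edge_adjacency(edges)
  for (e in seq_len(m)) {
    for (dir in 1:2) {
      v <- edges[e, dir]          # root of the pruned subtree
      u <- edges[e, 3 - dir]      # attachment node to dissolve
      if (u <= n_tips) next       # cannot suppress a tip
      rest <- setdiff(adj[[u]], v)
      if (length(rest) != 2) next
      # edges of the remaining tree: drop (u,v) and the two edges at u,
      # reconnect rest[1]-rest[2]
      drop_idx <- which((edges[, 1] == u | edges[, 2] == u))
      keep <- edges[-drop_idx, , drop = FALSE]
      base <- rbind(keep, c(rest[1], rest[2]))
      # nodes in the pruned component (to exclude as regraft targets)
      pruned_nodes <- c(v, setdiff_component(adj, v, u))
      for (be in seq_len(nrow(base))) {
        a <- base[be, 1]; b <- base[be, 2]
        if (a %in% pruned_nodes || b %in% pruned_nodes) next
        # skip reinsertion into the edge we just created if it rebuilds
        # the original tree; dedup handles that downstream
        ne <- base
        ne[be, ] <- c(a, u)
        ne <- rbind(ne, c(u, b), c(u, v))
        out[[length(out) + 1L]] <- ne
      }
    }
  }
  out
}

# nodes reachable from start without crossing toward `avoid`
setdiff_component <- function(adj, start, avoid) {
  visited <- c(avoid)
  stack <- start
  comp <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u %in% visited) next
    visited <- c(visited, u)
    comp <- c(comp, u)
    stack <- c(stack, setdiff(adj[[u]], visited))
  }
  setdiff(comp, start)
}

# convert an internal edge matrix to an ape phylo (unrooted, binary)
edges_to_phylo <- function(edges, taxa) {
  n_tips <- length(taxa)
  adj <- edge_adjacency(edges)
  # recursive newick rooted at the internal neighbor of tip 1
  build <- function(u, parent) {
    kids <- setdiff(adj[[u]], parent)
    if (!length(kids)) return(taxa[u])
    paste0("(", paste(vapply(kids, build, character(1), parent = u),
                      collapse = ","), ")")
  }
  root <- adj[[1]][1]
  nwk <- paste0("(", taxa[1], ",",
                paste(vapply(setdiff(adj[[root]], 1), build, character(1),
                             parent = root), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

# convert an ape phylo to the internal edge representation, mapping tip
# labels through `taxa` (dataset order) and internal ids above length(taxa)
phylo_to_edges <- function(phy, taxa) {
  n_tips <- length(taxa)
  if (!is.null(phy$edge.length)) phy$edge.length <- NULL
  phy <- ape::unroot(phy)
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx))
    stop("tree tips not in taxa: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  map <- integer(max(phy$edge))
  map[seq_along(phy$tip.label)] <- idx
  internals <- sort(unique(phy$edge[phy$edge > length(phy$tip.label)]))
  map[internals] <- n_tips + seq_along(internals)
  cbind(map[phy$edge[, 1]], map[phy$edge[, 2]])
}
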