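# Shared fixtures and independent oracles used across the suite.

# a convex, non-symmetric octagon-ish base shape for landmark simulations
base_shape <- function(k = 8) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(cos(th) * (1 + 0.2 * sin(3 * th)), sin(th))
}

random_configs <- function(n, k, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    landmark_config(matrix(rnorm(2 * k, sd = 2), k, 2), paste0("r", i)))
}

random_character_matrix <- function(n_taxa, n_chars, seed, states = 0:1,
                                    missing_frac = 0) {
  set.seed(seed)
  st <- matrix(as.character(sample(states, n_taxa * n_chars, replace = TRUE)),
               n_taxa, n_chars)
  if (missing_frac > 0) {
    idx <- sample(length(st), round(missing_frac * length(st)))
    st[idx] <- "?"
    # keep every character scored for at least one taxon
    for (j in seq_len(n_chars))
      if (all(st[, j] == "?")) st[1, j] <- as.character(states[1])
  }
  rownames(st) <- paste0("t", seq_len(n_taxa))
  character_matrix(st)
}

# Exhaustive small-parsimony oracle: minimum changes over ALL assignments of
# observed states to internal nodes (and to '?' tips). Independent of the
# Fitch kernel: it never touches the package's tree machinery beyond ape.
brute_min_steps <- function(tree, cm, per_character = FALSE) {
  tru <- ape::unroot(tree)
  edge <- tru$edge
  n <- length(tru$tip.label)
  nnode <- tru$Nnode
  tip_of_taxon <- match(cm$taxa, tru$tip.label)
  per_char <- integer(cm$n_chars)
  for (j in seq_len(cm$n_chars)) {
    col <- cm$states[, j]
    obs <- sort(unique(col[col != "?"]))
    tipstate <- character(n)
    tipstate[tip_of_taxon] <- col
    free <- c(which(tipstate == "?"), n + seq_len(nnode))
    grid <- do.call(expand.grid,
                    c(rep(list(obs), length(free)),
                      list(stringsAsFactors = FALSE)))
    state <- matrix("", nrow(grid), n + nnode)
    fixed <- setdiff(seq_len(n), which(tipstate == "?"))
    state[, fixed] <- matrix(tipstate[fixed], nrow(grid), length(fixed),
                             byrow = TRUE)
    for (z in seq_along(free)) state[, free[z]] <- grid[[z]]
    diffs <- vapply(seq_len(nrow(edge)), function(e)
      state[, edge[e, 1]] != state[, edge[e, 2]], logical(nrow(grid)))
    if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
    per_char[j] <- min(rowSums(diffs))
  }
  if (per_character) per_char else sum(per_char)
}

# independent per-character min/max step counts from the raw column
naive_char_bounds <- function(cm) {
  m <- g <- integer(cm$n_chars)
  for (j in seq_len(cm$n_chars)) {
    obs <- cm$states[, j]
    obs <- obs[obs != "?"]
    m[j] <- length(unique(obs)) - 1L
    g[j] <- length(obs) - max(table(obs))
  }
  list(m = m, g = g)
}

# rooted-clade sets via ape only (oracle for consensus/bipartition checks);
# all trees are rooted at the given tip so clade sets are comparable
rooted_clades <- function(tree, at_tip) {
  tr <- ape::root(ape::unroot(tree), outgroup = at_tip, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(ix) sort(labs[ix]))
  # also include cherries' complements implicitly by adding every child clade
  unique(vapply(out, paste, character(1), collapse = "|"))
}

# clade set including all non-root internal nodes, as label strings
clade_strings <- function(tree, at_tip) {
  tr <- ape::root(ape::unroot(tree), outgroup = at_tip, resolve.root = TRUE)
  n <- length(tr$tip.label)
  internals <- setdiff(unique(tr$edge[, 1]), n + 1L)
  vapply(internals, function(nd)
    paste(sort(ape::extract.clade(tr, nd)$tip.label), collapse = "|"),
    character(1))
}

# the generating tree used throughout the parsimony recovery tests
recovery_tree <- function() {
  ape::read.tree(text = "(((A,B),(C,D)),(E,(F,G)));")
}
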