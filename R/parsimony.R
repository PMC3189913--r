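# State bitmasks for the Fitch kernel. '?' is treated as the full set of
# states observed in that character (it can match anything, costs nothing).
state_masks <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  n <- length(cm$taxa)
  masks <- matrix(0L, n, cm$n_chars)
  for (j in seq_len(cm$n_chars)) {
    col <- cm$states[, j]
    obs <- sort(unique(col[col != "?"]))
    bits <- bitwShiftL(1L, as.integer(obs))
    full <- Reduce(bitwOr, bits, 0L)
    m <- integer(n)
    m[col == "?"] <- full
    for (s in seq_along(obs)) m[col == obs[s]] <- bits[s]
    masks[, j] <- m
  }
  masks
}

# per-character counts used by the ensemble indices, over scored taxa only:
# m_i = distinct observed states - 1 (minimum conceivable steps)
# g_i = scored taxa - count of the most frequent observed state (maximum
#       steps on the least favorable tree, i.e. the star/bush value)
char_min_max_steps <- function(cm) {
  m <- g <- integer(cm$n_chars)
  for (j in seq_len(cm$n_chars)) {
    col <- cm$states[, j]
    obs <- col[col != "?"]
    tab <- table(obs)
    m[j] <- length(tab) - 1L
    g[j] <- length(obs) - max(tab)
  }
  list(min_steps = m, max_steps = g)
}

#' Fitch tree length of a character matrix on a tree
#'
#' Total number of character-state changes (steps, L) required by the tree
#' under Fitch optimization of unordered multistate characters. Missing
#' entries (`?`) are treated as the full observed state set of their
#' character. The length is invariant to rerooting and taxon order.
#'
#' @param tree an ape `phylo` with binary (fully resolved) unrooted topology;
#'   its leaf set must equal the matrix's taxa.
#' @param matrix a [character_matrix()].
#' @param per_character return the per-character step vector instead of the
#'   total (default FALSE).
#' @return Integer tree length, or an integer vector when `per_character`.
#' @export
fitch_length <- function(tree, matrix, per_character = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "character_matrix"))
  if (!setequal(tree$tip.label, matrix$taxa)) {
    extra <- setdiff(tree$tip.label, matrix$taxa)
    miss <- setdiff(matrix$taxa, tree$tip.label)
    stop("leaf/taxon mismatch",
         if (length(extra)) paste0("; tree-only: ", paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; matrix-only: ", paste(miss, collapse = ", ")))
  }
  tru <- ape::unroot(tree)
  if (!ape::is.binary(tru))
    stop("Fitch length requires a fully resolved (binary) topology")
  edges <- phylo_to_edges(tru, matrix$taxa)
  steps <- .fitch_chars_cpp(edges, state_masks(matrix), length(matrix$taxa))
  if (per_character) steps else sum(steps)
}

#' Ensemble parsimony indices
#'
#' Tree length and the ensemble consistency (CI), homoplasy (HI = 1 - CI),
#' retention (RI) and rescaled consistency (RC = CI * RI) indices of a
#' character matrix on a tree. Per character, over scored taxa only
#' (missing entries are excluded from the counts): the minimum steps m_i is
#' the number of distinct observed states minus one, and the maximum g_i is
#' the number of scored taxa minus the count of the most frequent state.
#' Then CI = sum(m_i)/L and RI = (sum(g_i) - L) / (sum(g_i) - sum(m_i)).
#'
#' @param tree,matrix as in [fitch_length()].
#' @param informative_only restrict CI (and L, m sums) to parsimony-
#'   informative characters (default FALSE: all characters included).
#' @param ri_exclude_uninformative drop characters with g_i = m_i from the RI
#'   sums (default TRUE, the usual convention; such characters cannot retain
#'   synapomorphy).
#' @return An object of class `parsimony_score`: list with `L`, `CI`, `HI`,
#'   `RI`, `RC`. RI/RC are `NA` when their denominator vanishes.
#' @export
ensemble_indices <- function(tree, matrix, informative_only = FALSE,
                             ri_exclude_uninformative = TRUE) {
  steps <- fitch_length(tree, matrix, per_character = TRUE)
  mm <- char_min_max_steps(matrix)
  parsimony_score_from_parts(steps, mm$min_steps, mm$max_steps,
                             informative_only, ri_exclude_uninformative)
}

# shared by ensemble_indices and search results
parsimony_score_from_parts <- function(steps, m, g, informative_only = FALSE,
                                       ri_exclude_uninformative = TRUE) {
  informative <- g > m  # a character can show homoplasy only when g > m
  ci_keep <- if (informative_only) informative else rep(TRUE, length(steps))
  L_ci <- sum(steps[ci_keep])
  if (L_ci == 0)
    stop("all characters invariant on this selection: L = 0, CI undefined")
  CI <- sum(m[ci_keep]) / L_ci
  ri_keep <- if (ri_exclude_uninformative) informative else rep(TRUE, length(steps))
  denom <- sum(g[ri_keep]) - sum(m[ri_keep])
  RI <- if (denom > 0) (sum(g[ri_keep]) - sum(steps[ri_keep])) / denom else NA_real_
  structure(
    list(L = sum(steps), CI = CI, HI = 1 - CI, RI = RI,
         RC = if (is.na(RI)) NA_real_ else CI * RI),
    class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("<parsimony_score> L = %d; CI = %.2f; HI = %.2f; RI = %s; RC = %s\n",
              x$L, x$CI, x$HI,
              if (is.na(x$RI)) "NA" else sprintf("%.2f", x$RI),
              if (is.na(x$RC)) "NA" else sprintf("%.2f", x$RC)))
  invisible(x)
}

#' Rescaled consistency identities from reported indices
#'
#' Recovers the derived ensemble indices from the two independent ones:
#' HI = 1 - CI and RC = CI * RI. Useful for checking published tree
#' statistics.
#'
#' @param CI,RI consistency and retention indices in (0, 1].
#' @return list with `HI` and `RC`.
#' @export
index_identities <- function(CI, RI) {
  stopifnot(CI > 0, CI <= 1, RI >= 0, RI <= 1)
  list(HI = 1 - CI, RC = CI * RI)
}

# ---- search ---------------------------------------------------------------

# greedy stepwise addition in the given taxon order; returns edge matrix
greedy_addition <- function(masks, n_tips, order) {
  tr <- base_tree3(order[1:3], n_tips)
  for (t_i in order[-(1:3)]) {
    cand <- lapply(seq_len(nrow(tr)), function(ei)
      insert_tip(tr, ei, t_i, next_internal_id(tr, n_tips)))
    lens <- .fitch_batch_cpp(do.call(rbind, lapply(cand, flatten_edges)),
                             masks, n_tips)
    tr <- cand[[which.min(lens)]]
  }
  tr
}

next_internal_id <- function(edges, n_tips) {
  max(n_tips, max(edges)) + 1L
}

# branch-and-bound over addition order: guaranteed to find all MPTs
bab_search <- function(masks, n_tips) {
  ub_tree <- greedy_addition(masks, n_tips, seq_len(n_tips))
  best_len <- .fitch_batch_cpp(matrix(flatten_edges(ub_tree), 1), masks, n_tips)[1]
  best <- list()
  recurse <- function(tr, next_taxon) {
    if (next_taxon > n_tips) {
      len <- .fitch_batch_cpp(matrix(flatten_edges(tr), 1), masks, n_tips)[1]
      if (len < best_len) {
        best_len <<- len
        best <<- list(tr)
      } else if (len == best_len) {
        best[[length(best) + 1L]] <<- tr
      }
      return(invisible())
    }
    cand <- lapply(seq_len(nrow(tr)), function(ei)
      insert_tip(tr, ei, next_taxon, next_internal_id(tr, n_tips)))
    lens <- .fitch_batch_cpp(do.call(rbind, lapply(cand, flatten_edges)),
                             masks, n_tips)
    for (i in order(lens)) {
      if (lens[i] > best_len) next  # partial length only grows with taxa
      recurse(cand[[i]], next_taxon + 1L)
    }
  }
  recurse(base_tree3(1:3, n_tips), 4L)
  list(trees = best, length = best_len)
}

# hill-climbing from a start tree over NNI+SPR neighborhoods, keeping all
# equally best trees (pool capped for plateau safety)
hill_climb <- function(start, masks, n_tips, max_pool = 64L) {
  pool <- list(start)
  keys <- tree_key(start, n_tips)
  best_len <- .fitch_batch_cpp(matrix(flatten_edges(start), 1), masks, n_tips)[1]
  repeat {
    nb <- list()
    for (tr in pool)
      nb <- c(nb, nni_neighbors(tr, n_tips), spr_neighbors(tr, n_tips))
    if (!length(nb)) break
    lens <- .fitch_batch_cpp(do.call(rbind, lapply(nb, flatten_edges)),
                             masks, n_tips)
    if (min(lens) < best_len) {
      best_len <- min(lens)
      idx <- which(lens == best_len)
      pool <- nb[idx]
      keys <- vapply(pool, tree_key, character(1), n_tips)
      dup <- duplicated(keys)
      pool <- pool[!dup]; keys <- keys[!dup]
      pool <- head(pool, max_pool); keys <- head(keys, max_pool)
    } else {
      grew <- FALSE
      for (i in which(lens == best_len)) {
        if (length(pool) >= max_pool) break
        k <- tree_key(nb[[i]], n_tips)
        if (!(k %in% keys)) {
          pool[[length(pool) + 1L]] <- nb[[i]]
          keys <- c(keys, k)
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  }
  list(trees = pool, keys = keys, length = best_len)
}

#' Maximum-parsimony tree search
#'
#' Finds the set of most parsimonious unrooted topologies (MPTs) for an
#' unordered multistate character matrix. Exact mode is a branch-and-bound
#' over taxon addition order, guaranteed to return every MPT; heuristic mode
#' runs random-addition starts followed by NNI/SPR hill-climbing, retaining
#' all equally best trees found. Mode `"auto"` uses exact search up to 12
#' taxa. Results are deduplicated up to unrooted isomorphism and are
#' reproducible given `seed`.
#'
#' @param matrix a [character_matrix()] with >= 4 taxa.
#' @param mode `"auto"`, `"exact"` or `"heuristic"`.
#' @param seed integer seed for the heuristic's random addition orders.
#' @param n_starts random-addition starts in heuristic mode (default 10).
#' @return An object of class `search_result`: `mpts` (an ape `multiPhylo`),
#'   `score` (a `parsimony_score` evaluated on the first MPT), `method`,
#'   `n_starts`.
#' @export
search_mpt <- function(matrix, mode = c("auto", "exact", "heuristic"),
                       seed = 1L, n_starts = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "character_matrix"))
  n_tips <- length(matrix$taxa)
  if (n_tips < 4) stop("need >= 4 taxa for tree search")
  masks <- state_masks(matrix)
  method <- if (mode == "exact" || (mode == "auto" && n_tips <= 12)) "exact" else "heuristic"
  if (method == "exact") {
    res <- bab_search(masks, n_tips)
    trees <- res$trees
    keys <- vapply(trees, tree_key, character(1), n_tips)
    trees <- trees[!duplicated(keys)]
  } else {
    set.seed(as.integer(seed))
    pool <- list(); keys <- character(0); best_len <- Inf
    for (s in seq_len(n_starts)) {
      start <- greedy_addition(masks, n_tips, sample(n_tips))
      hc <- hill_climb(start, masks, n_tips)
      if (hc$length < best_len) {
        best_len <- hc$length
        pool <- hc$trees; keys <- hc$keys
      } else if (hc$length == best_len) {
        for (i in seq_along(hc$trees)) {
          if (!(hc$keys[i] %in% keys)) {
            pool[[length(pool) + 1L]] <- hc$trees[[i]]
            keys <- c(keys, hc$keys[i])
          }
        }
      }
    }
    trees <- pool
  }
  mpts <- lapply(trees, edges_to_phylo, taxa = matrix$taxa)
  class(mpts) <- "multiPhylo"
  steps <- fitch_length(mpts[[1]], matrix, per_character = TRUE)
  mm <- char_min_max_steps(matrix)
  structure(
    list(mpts = mpts,
         score = parsimony_score_from_parts(steps, mm$min_steps, mm$max_steps),
         method = method,
         n_starts = if (method == "heuristic") n_starts else NA_integer_),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", length(x$mpts), "MPT(s) by", x$method, "search; ")
  print(x$score)
  invisible(x)
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) with identical leaf sets.
#' @return An ape `phylo`, possibly unresolved.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(x) x)
  if (length(trees) < 1) stop("no trees")
  base_tips <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), base_tips))
      stop("leaf-set mismatch across input trees")
  class(trees) <- "multiPhylo"
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' Nonparametric bootstrap support for clades
#'
#' Resamples characters with replacement (same count), reruns the heuristic
#' parsimony search per replicate, takes the bipartitions shared by all of
#' the replicate's equally parsimonious trees (its strict consensus), and
#' accumulates bipartition frequencies. Support is the percentage of
#' replicates whose consensus contains the clade. Exactly reproducible given
#' `seed` and `replicates`.
#'
#' @param matrix a [character_matrix()].
#' @param replicates bootstrap replicates (the reference analysis uses 1000;
#'   default 100 here for interactive use).
#' @param seed integer seed.
#' @param n_starts random-addition starts per replicate (default 2).
#' @return Named numeric vector of support percentages; names are the
#'   comma-joined sorted taxon labels of each clade (the bipartition side not
#'   containing the first taxon).
#' @export
bootstrap_support <- function(matrix, replicates = 100L, seed = 1L,
                              n_starts = 2L) {
  stopifnot(inherits(matrix, "character_matrix"), replicates >= 1)
  n_tips <- length(matrix$taxa)
  set.seed(as.integer(seed))
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(replicates)) {
    idx <- sample.int(matrix$n_chars, matrix$n_chars, replace = TRUE)
    bm <- character_matrix(
      `rownames<-`(matrix$states[, idx, drop = FALSE], matrix$taxa))
    res <- search_mpt(bm, mode = "heuristic", seed = sample.int(1e6, 1),
                      n_starts = n_starts)
    bps <- lapply(res$mpts, function(tr)
      tree_bipartitions(phylo_to_edges(tr, matrix$taxa), n_tips))
    keysets <- lapply(bps, function(b)
      vapply(b, paste, character(1), collapse = ","))
    shared <- Reduce(intersect, keysets)
    for (k in shared) {
      cur <- mget(k, envir = counts, ifnotfound = 0)[[1]]
      assign(k, cur + 1, envir = counts)
    }
  }
  keys <- ls(counts)
  if (!length(keys)) return(setNames(numeric(0), character(0)))
  sup <- vapply(keys, function(k) 100 * get(k, envir = counts) / replicates,
                numeric(1))
  names(sup) <- vapply(strsplit(keys, ","), function(ix)
    paste(sort(matrix$taxa[as.integer(ix)]), collapse = ","), character(1))
  sort(sup, decreasing = TRUE)
}

#' Annotate a tree's internal nodes with bootstrap support
#'
#' @param tree an ape `phylo` whose tips appear in the support table's clade
#'   names.
#' @param support named vector from [bootstrap_support()].
#' @return The tree with `node.label` set to the support percentage (empty
#'   where the clade was never seen).
#' @export
annotate_support <- function(tree, support) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    node <- n + i
    tips <- sort(tree$tip.label[unlist(phangorn_free_descendants(tree, node))])
    key1 <- paste(tips, collapse = ",")
    key2 <- paste(sort(setdiff(tree$tip.label, tips)), collapse = ",")
    hit <- support[match(c(key1, key2), names(support))]
    hit <- hit[!is.na(hit)]
    if (length(hit)) labs[i] <- formatC(hit[1], format = "fg")
  }
  tree$node.label <- labs
  tree
}

# tip indices descending from an internal node (no phangorn dependency)
phangorn_free_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer(0)
  for (k in kids) {
    if (k <= n) out <- c(out, k)
    else out <- c(out, phangorn_free_descendants(tree, k)[[1]])
  }
  list(out)
}
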