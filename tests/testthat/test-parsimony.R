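quartet_matrix <- function() {
  st <- matrix(c("0", "0", "1", "1"), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  character_matrix(st)
}

test_that("fitch_length reproduces textbook quartet counts", {
  cm <- quartet_matrix()
  ab_cd <- ape::read.tree(text = "((A,B),(C,D));")
  ac_bd <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(ab_cd, cm), 1)
  expect_equal(fitch_length(ac_bd, cm), 2)
  # invariant characters add nothing on any tree
  st2 <- cbind(cm$states, "1")
  rownames(st2) <- cm$taxa
  expect_equal(fitch_length(ab_cd, character_matrix(st2)), 1)
})

test_that("fitch_length equals exhaustive state minimization on random matrices", {
  set.seed(101)
  for (rep in 1:15) {
    cm <- random_character_matrix(8, 12, seed = 500 + rep, states = 0:2,
                                  missing_frac = 0.08)
    tr <- ape::rtree(8, tip.label = sample(cm$taxa))
    expect_equal(fitch_length(tr, cm), brute_min_steps(tr, cm),
                 info = paste("matrix", rep))
  }
})

test_that("fitch_length is invariant to rerooting and taxon order", {
  cm <- random_character_matrix(7, 20, seed = 77, states = 0:1)
  tr <- ape::rtree(7, tip.label = cm$taxa)
  L <- fitch_length(tr, cm)
  for (og in cm$taxa[2:4])
    expect_equal(fitch_length(ape::root(tr, og), cm), L)
  perm <- sample(seq_along(cm$taxa))
  st <- cm$states[perm, , drop = FALSE]
  rownames(st) <- cm$taxa[perm]
  expect_equal(fitch_length(tr, character_matrix(st)), L)
})

test_that("fitch_length validates its inputs", {
  cm <- quartet_matrix()
  wrong <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(fitch_length(wrong, cm), "tree-only: E.*matrix-only: D")
  poly <- ape::read.tree(text = "(A,B,C,D);")
  expect_error(fitch_length(poly, cm), "binary")
})

test_that("compatible characters give a unique MPT equal to the truth", {
  tree <- recovery_tree()
  sp <- sim_spec(11, tree = tree, n_chars = 10, homoplasy_rate = 0)
  cm <- simulate_characters(sp, edge_choice = "cycle")
  res <- search_mpt(cm, mode = "exact")
  expect_length(res$mpts, 1)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(res$mpts[[1]])),
               0, ignore_attr = TRUE)
})

test_that("branch-and-bound recovers the exhaustive MPT set", {
  topo <- enumerate_topologies(8)
  cm <- random_character_matrix(8, 15, seed = 13, states = 0:1)
  masks <- pantherin:::state_masks(cm)
  lens <- pantherin:::.fitch_batch_cpp(topo, masks, 8L)
  best <- topo[lens == min(lens), , drop = FALSE]
  exhaustive_keys <- sort(unique(apply(best, 1, function(r)
    pantherin:::tree_key(pantherin:::unflatten_edges(r), 8))))
  res <- search_mpt(cm, mode = "exact")
  expect_equal(res$score$L, min(lens))
  bab_keys <- sort(vapply(res$mpts, function(t)
    pantherin:::tree_key(pantherin:::phylo_to_edges(t, cm$taxa), 8),
    character(1)))
  expect_identical(bab_keys, exhaustive_keys)
})

test_that("the heuristic search attains the exact optimum on most seeds", {
  cm <- random_character_matrix(9, 18, seed = 9, states = 0:1)
  exact <- search_mpt(cm, mode = "exact")
  hits <- sum(vapply(1:5, function(s)
    search_mpt(cm, mode = "heuristic", seed = s)$score$L == exact$score$L,
    logical(1)))
  expect_gte(hits, 4)
})

test_that("ensemble indices are exact on homoplasy-free data and match a per-character oracle", {
  tree <- recovery_tree()
  sp <- sim_spec(21, tree = tree, n_chars = 10, homoplasy_rate = 0)
  cm <- simulate_characters(sp, edge_choice = "cycle")
  sc <- ensemble_indices(ape::read.tree(text = write_newick(tree)), cm)
  expect_equal(sc$CI, 1)
  expect_equal(sc$HI, 0)
  expect_equal(sc$RI, 1)
  expect_equal(sc$RC, 1)

  cmr <- random_character_matrix(8, 15, seed = 303, states = 0:2,
                                 missing_frac = 0.05)
  tr <- ape::rtree(8, tip.label = cmr$taxa)
  sc2 <- ensemble_indices(tr, cmr, ri_exclude_uninformative = FALSE)
  steps <- brute_min_steps(tr, cmr, per_character = TRUE)
  bounds <- naive_char_bounds(cmr)
  L <- sum(steps)
  expect_equal(sc2$L, L)
  expect_equal(sc2$CI, sum(bounds$m) / L)
  expect_equal(sc2$HI, 1 - sc2$CI)
  expect_equal(sc2$RI, (sum(bounds$g) - L) / (sum(bounds$g) - sum(bounds$m)))
  expect_equal(sc2$RC, sc2$CI * sc2$RI)
})

test_that("ensemble indices agree with phangorn on clean matrices", {
  cm <- random_character_matrix(8, 20, seed = 404, states = 0:2)
  tr <- ape::rtree(8, tip.label = cm$taxa)
  sc <- ensemble_indices(tr, cm)
  st <- cm$states
  rownames(st) <- cm$taxa
  pd <- phangorn::phyDat(st, type = "USER", levels = as.character(0:9))
  expect_equal(sc$CI, phangorn::CI(tr, pd), tolerance = 1e-12)
  expect_equal(sc$RI, phangorn::RI(tr, pd), tolerance = 1e-12)
})

test_that("all-invariant matrices signal that CI is undefined", {
  st <- matrix("1", 4, 3, dimnames = list(c("A", "B", "C", "D"), NULL))
  cm <- character_matrix(st)
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(ensemble_indices(tr, cm), "CI undefined")
})

test_that("published-style index identities hold (HI = 1 - CI, RC = CI * RI)", {
  ids <- index_identities(CI = 0.66, RI = 0.65)
  expect_equal(round_half_up(ids$HI, 2), 0.34)
  expect_equal(round_half_up(ids$RC, 2), 0.43)
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),C,D);")
  expect_equal(ape::dist.topo(strict_consensus(list(t1, t1)), t1), 0,
               ignore_attr = TRUE)
  t2 <- ape::read.tree(text = "((A,C),B,D);")
  cons <- strict_consensus(list(t1, t2))
  expect_equal(cons$Nnode, 1)  # fully collapsed star
  expect_error(strict_consensus(list(
    t1, ape::read.tree(text = "((A,B),C,E);"))), "leaf-set mismatch")
  # property: every consensus clade occurs in both inputs
  set.seed(55)
  for (rep in 1:10) {
    a <- ape::rtree(8, tip.label = paste0("t", 1:8))
    b <- ape::rtree(8, tip.label = paste0("t", 1:8))
    cons <- strict_consensus(list(a, b))
    cc <- clade_strings(cons, "t1")
    expect_true(all(cc %in% clade_strings(a, "t1")))
    expect_true(all(cc %in% clade_strings(b, "t1")))
  }
})

test_that("bootstrap support is 100% for a clade present in every replicate", {
  st <- matrix("0", 4, 10, dimnames = list(c("A", "B", "C", "D"), NULL))
  st[c("A", "B"), ] <- "1"
  cm <- character_matrix(st)
  sup <- bootstrap_support(cm, replicates = 30, seed = 2)
  # the A,B | C,D split is in every resampled dataset's MPT
  expect_equal(unname(sup[grepl("^(A,B|C,D)$", names(sup))]), 100)
})

test_that("bootstrap support is reproducible for a fixed seed", {
  tree <- recovery_tree()
  cm <- simulate_characters(
    sim_spec(31, tree = tree, n_chars = 15, homoplasy_rate = 0.2),
    edge_choice = "random")
  s1 <- bootstrap_support(cm, replicates = 25, seed = 14)
  s2 <- bootstrap_support(cm, replicates = 25, seed = 14)
  expect_identical(s1, s2)
  s3 <- bootstrap_support(cm, replicates = 25, seed = 15)
  expect_false(identical(s1, s3))
})

test_that("support annotation maps clades onto tree node labels", {
  tree <- recovery_tree()
  cm <- simulate_characters(
    sim_spec(33, tree = tree, n_chars = 15, homoplasy_rate = 0),
    edge_choice = "cycle")
  sup <- bootstrap_support(cm, replicates = 20, seed = 5)
  ann <- annotate_support(ape::unroot(tree), sup)
  expect_true(any(nzchar(ann$node.label)))
})
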