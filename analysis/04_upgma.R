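# 04 — UPGMA distance tree from the relative-warp scores.
#
# Average-linkage clustering of Euclidean distances between group mean
# score vectors, with the clouded-leopard group designated as outgroup
# (UPGMA roots by ultrametricity; the outgroup's placement is checked, not
# imposed).

source("analysis/00_common.R")

scores <- read.csv(file.path(RESULTS, "rw_scores.csv"), check.names = FALSE)
mat <- as.matrix(scores[, grep("^RW", names(scores))])
rownames(mat) <- scores$specimen_id

dm <- score_distances(mat, metric = "euclidean",
                      by_group = TRUE, groups = scores$group)
tr <- upgma(dm)
write_newick(tr, file.path(RESULTS, "upgma_groups.nwk"))
cat("UPGMA tree over group mean shapes:\n  ", write_newick(tr), "\n")

og <- outgroup_orient(tr, "Neofelis_nebulosa")
cat("outgroup placement:", og$status, "\n")

sisters <- ape::is.monophyletic(
  tr, c("Panthera_tigris", "Panthera_zdanskyi"))
cat("fossil + tiger form an exclusive cluster:", sisters, "\n")
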