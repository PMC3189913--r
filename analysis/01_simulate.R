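# 01 — Generate the synthetic study inputs.
#
# The original comparative database (hundreds of museum skulls) is not deposited,
# so every downstream driver runs on synthetic data with the same statistical
# structure: multi-species landmark samples around distinct mean shapes,
# characters evolved on a known tree with mild homoplasy, and measurement
# tables with group means, shared allometric size factors and lognormal
# noise. Everything is a pure function of SEED.

source("analysis/00_common.R")

shapes <- group_mean_shapes()
lm_spec <- sim_spec(SEED, groups = lapply(names(shapes), function(g)
  list(label = g, n = 12, mean_shape = shapes[[g]], noise_sd = 0.015)))
cfgs <- simulate_landmarks(lm_spec)
write_tps(cfgs, file.path(DATA_DIR, "synthetic_crania.tps"))
cat("landmarks :", length(cfgs), "specimens x", cfgs[[1]]$k,
    "landmarks ->", file.path(DATA_DIR, "synthetic_crania.tps"), "\n")

tree <- reference_topology()
ch_spec <- sim_spec(SEED, tree = tree, n_chars = 36, homoplasy_rate = 0.15)
cm <- simulate_characters(ch_spec, edge_choice = "cycle")
write_nexus_matrix(cm, file.path(DATA_DIR, "synthetic_characters.nex"))
cat("characters:", length(cm$taxa), "taxa x", cm$n_chars,
    "characters (homoplasy rate 0.15) ->",
    file.path(DATA_DIR, "synthetic_characters.nex"), "\n")

meas_spec <- sim_spec(SEED, groups = list(
  list(label = "Panthera_tigris", n = 25,
       mean_vector = c(CBL = 290, c1_height = 58, nasal_length = 105,
                       p4_length = 36, m1_length = 26), cv = 0.04),
  list(label = "Panthera_onca", n = 25,
       mean_vector = c(CBL = 240, c1_height = 44, nasal_length = 74,
                       p4_length = 29, m1_length = 21), cv = 0.04),
  list(label = "Panthera_pardus", n = 25,
       mean_vector = c(CBL = 210, c1_height = 35, nasal_length = 67,
                       p4_length = 27, m1_length = 19), cv = 0.04)))
tab <- simulate_measurements(meas_spec)
write_measurements(tab, file.path(DATA_DIR, "synthetic_measurements.csv"))
cat("measures  :", nrow(tab), "specimens x", ncol(tab) - 2,
    "variables ->", file.path(DATA_DIR, "synthetic_measurements.csv"), "\n")
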