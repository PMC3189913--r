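# Shared setup for the numbered analysis drivers. Each driver is a thin
# narrative script over the pantherin package; run them from the repository
# root in order. All outputs land under results/.

library(pantherin)
suppressPackageStartupMessages(library(ape))

SEED <- 20260919L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# A stylised lateral skull outline used as the landmark scaffold: a closed
# polygon with unequal lobes so that no symmetry hides alignment errors.
skull_outline <- function(k = 12) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(cos(th) * (1 + 0.25 * sin(2 * th) + 0.1 * cos(3 * th)),
        0.7 * sin(th) * (1 + 0.15 * cos(th)))
}

# Group mean shapes: small, localised deformations of the common scaffold,
# chosen so that the fossil group sits nearest the tiger-like mean (the
# structure the cranial analyses are designed to detect).
group_mean_shapes <- function() {
  mu <- skull_outline()
  bump <- function(w_rostrum, w_vault) {
    mu + w_rostrum * cbind(pmax(mu[, 1], 0)^2, 0) +
      w_vault * cbind(0, pmax(mu[, 2], 0)^2)
  }
  list(
    Panthera_tigris     = bump(0.30, 0.05),
    Panthera_zdanskyi   = bump(0.26, 0.07),
    Panthera_onca       = bump(0.10, 0.22),
    Panthera_pardus     = bump(0.02, 0.12),
    # the outgroup is by construction the most divergent shape
    Neofelis_nebulosa   = bump(-0.45, -0.55))
}

# The reference topology on which synthetic character matrices are evolved.
reference_topology <- function() {
  read.tree(text = paste0(
    "((Leopardus_pardalis,Puma_concolor),(Neofelis_nebulosa,",
    "((Panthera_onca,(Panthera_pardus,Panthera_leo)),",
    "(Panthera_uncia,(Panthera_tigris,Panthera_zdanskyi)))));"))
}
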