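# pantherin

Quantitative diagnosis of pantherine (big-cat) skulls from craniodental
data. The package implements, as tested reusable functions, the full
workflow used to characterize a fossil pantherine cranium and place it
phylogenetically:

* **Geometric morphometrics** — generalized Procrustes superimposition;
  thin-plate-spline (TPS) decomposition of shape variation into uniform and
  non-uniform components via the bending-energy matrix (principal/partial
  warps); relative warps at α = 0 (a covariance PCA of the warp scores).
  The TPS kernel is U(r) = r² log r², with bending energy computed through
  the exact quadratic form E = 16π (wₓᵀK wₓ + w_yᵀK w_y).
* **Maximum-parsimony cladistics** — Fitch tree length on unordered
  multistate characters (`?` = full observed state set), exact
  branch-and-bound search returning *all* most parsimonious trees,
  NNI/SPR heuristic search with random-addition starts, strict consensus,
  nonparametric bootstrap, and the ensemble indices
  L, CI = Σmᵢ/L, HI = 1 − CI, RI = (Σgᵢ − L)/(Σgᵢ − Σmᵢ), RC = CI·RI.
* **UPGMA distance trees** from relative-warp or principal-component
  scores (Euclidean or squared-Euclidean; per specimen or per group
  centroid), with outgroup-placement checking.
* **Craniodental profiling** — measurement ratios with reporting-layer
  half-up rounding, verdicts against comparative ranges, size-adjusted PCA
  (CBL-ratio or log-shape), and jackknifed (leave-one-out) linear
  discriminant classification.
* **Biomechanics** — the two-muscle relative bite-force model
  (temporalis √(((ZW − (BW+POW)/2)/2)·TFL)·MAT plus masseter
  √(((CFL+MSW)/2)·MSL)·MAM, doubled for both sides) and allometric body
  mass prediction from condylobasal length (log₁₀–log₁₀ OLS over species
  means).
* **Synthetic data generators** for landmark samples, tree-compatible
  character matrices with tunable homoplasy, and allometric measurement
  tables, so the whole pipeline is testable without museum specimens.

File formats: TPS landmark files, NEXUS character matrices (DATA/
CHARACTERS subset), Newick trees, CSV measurement tables.

## Worked example

The holotype measurements printed in the original description (bundled as
`inst/extdata/holotype_measurements.csv`) and the comparative ratio ranges
for *Panthera* reproduce the published craniodental profile:

```r
library(pantherin)
h <- read_measurements(system.file("extdata", "holotype_measurements.csv",
                                   package = "pantherin"))
ratio(h$c1_height, h$CBL, decimals = 1, percent = TRUE)        # 23.7
ratio(h$nasal_length, h$CBL, decimals = 1, percent = TRUE)     # 34.5
ratio(h$p4_length, h$CBL, decimals = 1, percent = TRUE)        # 13.4
ratio(h$m1_length, h$mandible_length, decimals = 1, percent = TRUE)  # 14.7

rt <- range_table(read.csv(system.file("extdata",
        "panthera_ratio_ranges.csv", package = "pantherin")))
range_compare(56.0 / 236.3, rt, "canine_height_cbl")
#>               group   min   max verdict qualifier
#> 1             tiger 0.166 0.230   above          
#> 2            jaguar 0.160 0.206   above          
#> ...
```

The upper canine is relatively taller than in every comparison group —
above even the tiger range — while the nasals (34.5% of CBL) fall in the
lower half of the tiger range: the combination the diagnosis rests on.

The cladistic and shape analyses run the same way on any data; the
numbered drivers under `analysis/` run them end-to-end on synthetic data
with a known truth. For example `analysis/03_parsimony.R` prints

```
1 MPT(s) by exact search: L = 39; CI = 0.92; HI = 0.08; RI = 0.94; RC = 0.87
fossil sister to the tiger in the first MPT: TRUE
bootstrap support for that pair: 98%
```

(36 synthetic characters evolved at homoplasy rate 0.15 on a nine-taxon
reference topology: the search recovers the generating tree, the indices
quantify the injected homoplasy, and the fossil–tiger pair is strongly
supported), and `analysis/04_upgma.R` reports the same sister-pairing from
cranial shape alone with the outgroup basal. The published tree statistics
(L = 103, two equally parsimonious trees) and the 76.8 kg body-mass figure
require data tables that exist only as supplementary files of the article;
`reproduce_supplementary()` runs those analyses the moment such files are
supplied and otherwise states exactly what is missing.

## Layout

```
R/                  package functions (every analysis step lives here)
src/                C++ Fitch scoring kernel
analysis/           numbered narrative drivers over the package
inst/extdata/       printed holotype measurements + comparative ranges
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  headline-quantity recomputation (JSON out)
vignettes/          methods vignette (models, assumptions, choices)
```
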