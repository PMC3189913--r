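---
title: "Methods behind pantherin: shape, parsimony and craniodental profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pantherin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantherin)
library(ape)
```

pantherin implements the quantitative toolkit used to diagnose a fossil
pantherine skull and place it phylogenetically: geometric morphometrics
(Procrustes superimposition and thin-plate-spline warps), maximum-parsimony
cladistics, UPGMA distance trees built from shape scores, craniodental ratio
profiling, jackknifed discriminant classification, a relative bite-force
model and allometric body-mass prediction. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical choices
the package makes where the methods literature leaves options open.

## Geometric morphometrics

### Procrustes superimposition

Shape is what remains of a landmark configuration after position, scale and
orientation are removed. `generalized_procrustes()` centers every
configuration, scales it to unit centroid size (the square root of summed
squared landmark distances from the centroid), and iteratively rotates each
specimen onto the running consensus until the consensus update falls below
`tol` (default `1e-10`, capped at 100 iterations; convergence is typically
reached in under ten). Two conventions matter:

* **Reflections are disallowed.** Lateral-view anatomical landmarks have a
  fixed handedness, so the rotation fit is constrained to determinant +1.
* **Identifiability.** A Procrustes solution is only defined up to a joint
  rotation; the package fixes it by rotating the converged set so the first
  specimen lies along its principal axes. This makes results deterministic
  given input order, and no downstream score depends on the choice.

The superimposition is idempotent and similarity-invariant: translating,
rotating or rescaling any input changes no downstream score by more than
numerical noise (asserted to `1e-8` in the test suite).

### Thin-plate splines and bending energy

`tps_fit()` interpolates one configuration onto another with a pair of
thin-plate splines, the unique interpolant minimizing the integral of
squared second derivatives ("bending energy"). The kernel is
U(r) = r² log(r²), the fundamental solution of the biharmonic equation,
with U(0) defined as its limit 0 to avoid the logarithmic singularity. The
kernel weights satisfy the side conditions (zero sum, zero coordinate
moments), which make the energy finite; with this kernel the energy has the
closed form E = 16π (wₓᵀK wₓ + w_yᵀK w_y), which `bending_energy()` uses.
The 16π constant follows from Δ²U = 16π δ, and the test suite verifies the
closed form against direct numerical integration of the squared second
derivatives (agreement within 1%). Affine maps — uniform stretching and
shearing — carry exactly zero bending energy.

### Partial, uniform and relative warps

`partial_warps()` decomposes shape variation around the consensus.
Principal warps are the eigenvectors of the consensus bending-energy matrix
(the upper k×k block of the inverse bordered TPS system), a positive
semi-definite matrix whose null space is exactly the three affine
directions. Projecting each specimen's deviation onto the k−3 principal
warps, per coordinate, yields 2(k−3) partial-warp scores. The uniform
(affine) component is computed by the *complement method*: the orthogonal
complement of the non-uniform subspace within the tangent space at the
consensus, a 2-dimensional space reported as `UniX`/`UniY`. Because
principal warps are orthonormal and orthogonal to the similarity
directions, the 2k−4 combined scores are coordinates in an orthonormal
tangent-space basis — summed squared scores equal tangent-space distances
exactly, which the suite asserts to `1e-9`.

`relative_warps()` with `alpha = 0` (the default, and the setting used
throughout the workflow) is then nothing more than a covariance-matrix PCA
of the combined score matrix; the package computes it by its own
eigendecomposition and the tests check it against `stats::prcomp` to
`1e-9`. The uniform component is included by default
(`include_uniform = TRUE`), matching common relative-warp practice; a flag
exposes the exclusion variant because published analyses are not always
explicit about this. Non-zero `alpha` re-weights warps by bending energy
and is provided for completeness only.

Open choices resolved here: the tangent-space projection is the standard
orthogonal projection at the consensus (adequate under the small-variation
assumption that holds for congeneric skull comparisons); deterministic sign
conventions (first non-zero loading positive) fix eigenvector and PCA sign
ambiguity.

## Maximum parsimony

Characters are unordered and equally weighted multistate symbols `0`–`9`
with `?` for missing data. `fitch_length()` computes tree length by Fitch
optimization, treating `?` as the full set of states observed in that
character (it can match anything and never forces a step). The kernel is
implemented in C++ with state bitmasks because the searches and oracles
below evaluate millions of topologies.

* `search_mpt(mode = "exact")` is a branch-and-bound over taxon addition
  order. Since adding a taxon can never decrease length, a partial tree
  longer than the best complete tree is pruned with its whole subtree of
  completions; candidates are expanded shortest-first from a greedy
  stepwise-addition upper bound. It is guaranteed to return *all* most
  parsimonious trees and is the default up to 12 taxa.
* `search_mpt(mode = "heuristic")` runs random-addition starts (default
  10) followed by hill-climbing over the combined NNI and SPR
  neighborhoods, retaining every equally best tree (pool capped at 64 for
  plateau safety, deduplicated by canonical bipartition set). The budget
  was chosen so the heuristic reliably attains the exact optimum on
  matrices of ≤15 taxa; the suite checks attainment on 5 seeded runs
  against branch-and-bound.

`ensemble_indices()` reports L, CI, HI, RI and RC. Per character, over
scored taxa only: the minimum conceivable steps mᵢ is the number of
distinct observed states minus one, and the maximum gᵢ is the number of
scored taxa minus the count of the most frequent state. Then CI = Σmᵢ/L,
HI = 1 − CI, RI = (Σgᵢ − L)/(Σgᵢ − Σmᵢ) and RC = CI·RI. Missing cells are
excluded from both counts (the standard PAUP convention). Characters with
gᵢ = mᵢ cannot retain synapomorphy and are dropped from the RI sums by
default (`ri_exclude_uninformative`); since such characters contribute
equal amounts to numerator and denominator the value is unchanged either
way, and a flag also restricts CI to informative characters for
cross-package comparison. When every character is invariant L = 0 and CI
is undefined; the package raises an explicit error rather than returning
NaN.

`bootstrap_support()` resamples characters with replacement, reruns the
heuristic search (2 random-addition starts per replicate — cheap, and
sufficient at these matrix sizes since replicates that miss the optimum
simply fail to vote for contested clades), takes the bipartitions common
to all of the replicate's equally parsimonious trees, and reports each
clade's frequency as a percentage. The reference workflow uses 1000
replicates; the package defaults to 100 for interactive use and the
analysis drivers say which they use. `strict_consensus()` delegates to
ape's consensus (p = 1) after validating leaf sets.

## UPGMA trees from shape scores

`score_distances()` computes Euclidean or squared-Euclidean distances
between specimen score vectors, or between group centroids
(`by_group = TRUE`, mean by default with a median option) — the workflow
aggregates per-specimen relative-warp scores to species centroids before
clustering, since the published trees have one leaf per taxon and the
aggregation rule is otherwise unstated. `upgma()` implements
average-linkage agglomeration with merge height = distance/2 and a
deterministic tie-break (the lexicographically smallest pair of cluster
labels, a cluster being labelled by its smallest member). Output trees are
ultrametric by construction; the suite cross-checks cophenetic distances
against `hclust(method = "average")`.

UPGMA roots by ultrametricity, not by an outgroup. `outgroup_orient()`
therefore only *reports* whether the designated outgroup is monophyletic
and basal (one of the two clades meeting at the root) and never re-roots —
the honest reconciliation of a rooted clustering method with the
outgroup-polarity language of distance analyses.

## Craniodental ratios and discriminant classification

`ratio()` and `ratio_profile()` compute measurement quotients at full
precision, with half-up rounding applied only at the reporting layer
(1 decimal for percentages, 3 for ratios — the conventions of the
comparative literature; base R's round-half-even would turn 23.65 into
23.6 where the literature prints 23.7). `range_compare()` classifies a
value against each group's observed range as below/within/above using
closed intervals, adding a "lower half" qualifier at or below the
midpoint.

`size_adjusted_pca()` removes isometric size before a covariance PCA,
either by dividing every variable by condylobasal length (`ratio_cbl`, the
default — CBL is the comparative literature's universal size denominator)
or by log-shape ratios (log variable minus specimen mean log). Rows with
missing values are dropped and recorded. `dfa_jackknife()` fits a linear
discriminant with pooled within-group covariance, classifies by smallest
Mahalanobis distance to group centroids, and estimates accuracy by
leave-one-out refitting of the entire model. When any group has fewer
specimens than variables + 2 the pooled covariance is shrunk toward its
diagonal (intensity 0.2 by default) — a deliberately simple stabilizer
whose intensity is exposed, since the alternative (failing on singular
covariance) is the worse default for small fossil samples. Stepwise
variable selection is deliberately not the default path; classification
uses all supplied variables unless the caller pre-selects.

## Biomechanics

`relative_bite_force()` implements the dry-skull two-muscle model:
temporalis output √(((ZW − (BW+POW)/2)/2)·TFL)·MAT and masseter output
√(((CFL+MSW)/2)·MSL)·MAM, summed per side and doubled for the skull total.
The outputs are relative (mm², not Newtons) and scale as length squared —
a c-times larger skull yields c² the output, which the tests assert. A
zygomatic width at or below the braincase/postorbital average would put a
negative number under the square root; the package treats equality as zero
temporalis output and anything below as a measurement-consistency error.

`predict_body_mass()` regresses log₁₀ body mass on log₁₀ CBL over species
means — means are taken on the arithmetic scale and then log-transformed,
the reading adopted where the source methods are ambiguous — and
back-transforms 10^ŷ without bias correction by default (the smearing-type
log-normal correction is available behind a flag). At least two species
are required to fit the line; note that published versions of such
regressions typically use six or more.

## Synthetic data: what it emulates and what it does not

The comparative samples behind the original analyses are hundreds of
museum skulls that are not deposited in machine-readable form, so the
package ships generators (`simulate_landmarks()`, `simulate_characters()`,
`simulate_measurements()`) that reproduce the *statistical structure* the
methods assume:

* landmark samples as isotropic Gaussian noise around distinct group mean
  shapes, pushed through random similarity transforms (rotation on the
  circle, scale in [0.5, 2], translation in [−10, 10]) so superimposition
  has real work to do;
* binary characters each perfectly compatible with a chosen internal edge
  of a generating tree, with a tunable per-character homoplasy rate that
  flips one taxon outside the clade (one convergent extra step); edges are
  chosen uniformly or cycled deterministically for even coverage;
* measurement tables as group mean vectors times a shared per-specimen
  lognormal size factor (allometric size variation) times independent
  lognormal noise (default coefficient of variation 0.05, matching typical
  intraspecific craniodental variation).

A single integer seed drives named sub-streams per generator, so adding
draws to one generator never perturbs another's output, and every
generator is a pure function of its spec.

What passing tests on these data do **not** show: real skulls have
correlated, anisotropic landmark noise, digitization error, allometric
shape (not just size) variation, and multistate characters with correlated
homoplasy. The generators deliberately omit all of these, so green tests
demonstrate that the *algorithms* are correct under their stated
assumptions, not that the biological conclusions would survive noisier
data. The simulator emits only binary characters; the parsimony engine
handles the full multistate alphabet and is tested on hand-built
multistate fixtures.

## Problem sizes and numerical choices

The test suite and the acceptance script run exhaustive oracles at sizes
where exhaustion is exact and quick: all 135,135 nine-taxon topologies for
the branch-and-bound check, brute-force minimization over internal state
assignments for eight-taxon Fitch checks, 30-specimen Monte-Carlo
recovery for the Procrustes consensus, and 100-replicate bootstraps.
Bending-energy integration uses a Cartesian core grid plus a masked polar
far field (the integrand decays as r⁻⁴ once the spline side conditions
cancel the leading terms). Linear systems are solved directly with a
reciprocal-condition guard (`1e-14`) that turns collinear landmark
configurations into an actionable error rather than a garbage spline.

The analysis drivers under `analysis/` use 12 specimens per species for
landmarks, 36 characters at homoplasy rate 0.15 on a nine-taxon reference
topology, and 25 specimens per species for measurement tables — small
enough to run in seconds, large enough that every recovery result is
stable across seeds. The synthetic body-mass training set uses
mass = a·CBL^b with b = 3.1 and a chosen so a 236 mm skull weighs roughly
what a jaguar-sized pantherine weighs; the bite-force demonstration skull
measures are plausible felid values spanning 0.8–1.25× a jaguar-sized
cranium.

## Known limitations

* 2-D landmarks only; no sliding semilandmarks, no 3-D TPS.
* Parsimony is unordered Fitch with equal weights: no ordered or
  step-matrix (Sankoff) characters, no implied weighting, and exact search
  is practical only to about 12 taxa.
* The published tree statistics (L = 103 over two equally parsimonious
  trees from the 23-taxon matrix) and the 76.8 kg body-mass prediction
  depend on supplementary data files that are not printed in the article;
  `reproduce_supplementary()` runs those analyses end-to-end when the
  files are supplied and otherwise reports exactly why they are
  unavailable. Nothing in the package pretends to reproduce those numbers
  from bundled data.
* UPGMA assumes rate constancy (ultrametricity); it is used here because
  the workflow under study used it, not because it is the best tree
  estimator for shape data.
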