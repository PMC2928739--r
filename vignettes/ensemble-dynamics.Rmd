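---
title: "Ensemble dynamics of protein complexes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble dynamics of protein complexes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdyn)
```

## What the package computes, and why

When an effector protein binds a complex, the observable consequence in a
trajectory is rarely a single structural change; it is a reshaping of the
whole conformational ensemble. The motivating system is the sumoylation
machinery: the E2 enzyme Ubc9 carrying SUMO, with and without the E3
ligase fragment RanBP2. The hypothesis of interest — that E3 binding
*allosterically restricts* the ensemble — is operationalized here as five
measurable statements about Cα trajectories:

1. **Quaternary rearrangement** shows up as a step in the *chain-pivot
   RMSD*: superpose the complex on chain X and measure chain Y. Self-aligned
   per-chain RMSD is blind to relative-orientation changes; the pivot form
   is sensitive to exactly those.
2. **Rigidification of loops** shows up as reduced per-residue
   *mean-square fluctuations* (msf).
3. **Reduced orientational freedom** of individual backbone segments shows
   up in the *time-delayed autocorrelation* of virtual Cα–Cα bond
   vectors, `A_i(tau) = <M_i(t) . M_i(t+tau)>`: a bond that keeps its
   orientation over tens of nanoseconds stays near 1.
4. **Coupling between distant functional regions** shows up in the
   normalized *dynamic cross-correlation map*
   `C_ij = <dR_i . dR_j> / sqrt(<dR_i^2><dR_j^2>)`, whole-run or per time
   window.
5. **Concentration of the ensemble** shows up as fewer occupied clusters
   and a narrower footprint in PCA space when two ensembles are clustered
   or projected *jointly*.

All statistics are Cα-only. The underlying quantities are residue-level,
and the virtual bond vectors are defined on Cα positions; an all-atom
treatment would change none of the definitions while multiplying the data
volume. Where a source analysis may have used heavier atom sets, the Cα
interpretation is this package's documented choice.

## Alignment conventions

Superposition is ordinary mass-unweighted Kabsch with the reflection
branch forbidden (a proper rotation is always returned; an improper fit
would be unphysical). Three conventions matter and are deliberately
different per statistic:

* **Cross-correlations and msf** are meaningless under unremoved global
  motion, so every analyzed frame is superposed on the caller's fit mask
  first. For per-chain msf the fit mask should be the chain itself: fitting
  a drifting complex as a whole inflates every chain's apparent
  fluctuation. Highly flexible segments (e.g. a disordered N-terminal
  tail) can be excluded from the fit *and* the report via `exclude_mask`;
  the values for the Ubc9/SUMO system (tail residues −1..19 of SUMO,
  equilibration times 2.5/5/0.5/0.4 ns) ship as `sumoylation_presets()` —
  they are simulation-specific configuration, not package defaults.
* **Bond autocorrelations** are computed on *raw, unaligned* coordinates.
  Bond vectors are internal directions: a time-independent global rigid
  transform leaves them unchanged (the suite asserts this), but per-frame
  realignment would rotate each frame differently and distort the
  orientational dynamics. This choice changes results, which is why it is
  stated prominently here and enforced in tests.
* **Clustering and PCA** align every frame once to a *fixed* reference
  conformation over the fit mask, and never re-align to moving centroids.
  Joined-ensemble comparisons are only meaningful if both ensembles share
  one frame of reference.

Frames flagged as equilibration (time ≤ `equilibration_end`, when the
marker is positive) are excluded from averages but never deleted, so one
trajectory object serves both full and equilibrated analyses.

## Windowed correlations

Time windows are `(start, end]` intervals, typically taken from the
cluster-membership timeline (the segmentation the clustering stage
suggests). Each window's map uses its own window-local mean for `dR` —
windows are presented as self-contained ensembles; a `global_mean` flag
switches to the whole-trajectory mean when a fixed baseline is wanted. The
coupling change between two named residue blocks across windows is
reduced to one number: the mean absolute difference of the two maps
restricted to the block-pair rectangle.

Residues with zero positional variance in a window have an undefined
correlation; they are reported as `NA`, never silently zero.

## Clustering: radius-seeded k-means

The similarity measure is the coordinate RMSD of the analysis selection to
the cluster centroid (equivalently, Euclidean distance in flattened
coordinate space divided by √n). The number of clusters is controlled by
an RMSD radius rather than a preset k: seeding scans frames in order and
founds a new centroid whenever a frame lies farther than the radius from
every existing one, after which Lloyd iterations (nearest-centroid
assignment, ties to the lowest index; coordinate-mean centroid updates;
empty clusters dropped) run to stability. Larger radii therefore give
fewer clusters, and the k-means objective is non-increasing — both are
asserted as properties in the suite. For the sumoylation analyses the
radii explored were 1.5/1.7/2 Å with 1.7 Å adopted for the Ubc9–SUMO and
joined-Ubc9 ensembles and 2 Å for the E3-bound complex
(`sumoylation_presets()`).

The seeding is deterministic by construction; a seed only matters if the
optional frame-order shuffle is enabled. This is an explicit, reproducible
stand-in for radius-controlled clustering tools whose internal seeding
order is unspecified: cluster *boundaries* on identical data may differ
from such tools, while the radius semantics and occupancy bookkeeping are
preserved. Centroids are coordinate means; the exported *representative
structures* are medoids (member frame closest to its centroid, earliest
frame on ties), since a mean of conformations need not be a sampled
conformation.

Occupancy tables are per source ensemble (rows sum to 100 %), computed
over post-equilibration frames; the membership timeline records
`(time, cluster)` per source. Before joining ensembles, an initial segment
of each trajectory (10 ns in the sumoylation preset) is typically
discarded via the equilibration marker — caller configuration, not a
hard-wired rule.

## PCA

The 3N×3N covariance of the selected, aligned coordinates over the joined
frames is eigendecomposed (via SVD of the centered frame matrix, divisor
F − 1). Each eigenvalue's share of the eigenvalue sum is the variance
proportion reported on projection axes, together with cumulative shares.
Projections are dot products of mean-centered coordinates with the
eigenvectors, in Å. Identities asserted in the suite: the eigenvalue sum
equals the total coordinate variance (trace identity), eigenvectors are
orthonormal, and a full-rank projection reconstructs the centered
coordinates exactly.

## The synthetic generators: what they emulate, and what they do not

The trajectories the original analyses were run on are not publicly
available, so validation rests on generators whose statistical structure
is planted and therefore known in closed form. The reference geometry is
an idealized helical Cα trace (2.3 Å radius, 1.5 Å rise, 100°/residue —
3.8 Å Cα spacing), not a real protein: closed-form expectations, no
external files.

* `generate_gaussian_trajectory()` — stationary Gaussian fluctuations with
  per-residue isotropic variances and block correlations planted through a
  common-factor structure (all distinct members of a block pairwise
  correlated at ρ; positive semidefinite for 0 ≤ ρ ≤ 1, which is checked
  at spec validation). Temporal structure is either white or exact-AR(1)
  Ornstein–Uhlenbeck: the update factor is `exp(-dt/theta)`, so the
  displacement autocorrelation at delay τ is `exp(-tau/theta)` *exactly*
  on the frame grid (an Euler discretization would only approximate it).
  A block with a time window is active only inside it, planting the
  mid-run correlation switch used to validate windowed maps; this is
  restricted to the white model, where frames are exchangeable and the
  switch is well-defined.
* `generate_rotational_diffusion_bonds()` — bond directions evolve by
  per-step random rotation vectors with per-axis variance `2 D dt`; the
  rank-1 orientational correlation then decays as `exp(-2 D tau)` (the
  discretization bias is first order in `D dt`; with the step sizes used
  in the suite it is well inside the 0.03 assertion band). Coordinates are
  rebuilt by chaining 3.8 Å bonds.
* `generate_rotation_event()` — two chains fluctuate about the reference;
  at the event time one chain's reference is rigidly rotated/translated.
  The pivot-RMSD step has a closed form (the RMSD of the planted transform
  over the moving chain), while per-chain internal geometry is
  statistically unchanged — the signature separating quaternary from
  internal change.
* `generate_multibasin_ensemble()` — frames are drawn from basins chosen
  by planted weights. Basin centers are random displacement fields made
  orthogonal to all six rigid-body modes *and* to each other, so the
  planted offsets survive Kabsch alignment: basin i sits at RMSD
  `offset_i` from the reference and basins are `sqrt(o_i^2 + o_j^2)`
  apart. `spread` is the expected RMSD of a frame from its basin center
  (per-coordinate σ = spread/√3).

All draws flow from one seeded generator per trajectory; identical
(spec, seed) gives bit-identical output, and the caller's RNG stream is
never consumed.

What passing these tests shows — and does not show. The generators share
the statistical *form* of the quantities of interest (planted
correlations, relaxation times, occupancies, rigid events), so recovery
within stated tolerances validates the estimators, the alignment
conventions and the bookkeeping. They do not emulate force-field physics,
solvent, anharmonicity, or the coupling between internal and overall
motion in real proteins; agreement here is necessary, not sufficient, for
trustworthy numbers on real trajectories.

## Numerical choices and degenerate inputs

* Kabsch: fit sets of fewer than 3 residues, or with a vanishing second
  singular value (collinear/coincident configurations), are hard errors —
  the rotation would be underdetermined.
* Correlation matrices are symmetrized (`(C + t(C))/2`) to remove
  floating-point asymmetry and carry `NA` for zero-variance residues.
* Autocorrelation delays must be nonnegative multiples of the (uniform)
  frame spacing and leave at least two frame pairs; a delay beyond half
  the usable span triggers a configuration warning (few pairs, noisy
  average), mirroring the convention of choosing the largest delay
  slightly above half the simulation time.
* Zero-length virtual bonds (coincident successive Cα) are errors naming
  the residue pair; bonds never span chain boundaries.
* Clustering ties go to the lowest cluster index; medoid ties to the
  earliest frame; empty clusters are dropped (iteration) or skipped with
  a warning (export).
* Insertion codes in PDB input are rejected outright: unambiguous
  (chain, resno) indexing is worth more than coverage of rare inputs.
  Altlocs resolve to highest occupancy, then first listed.
* Result CSVs are written with 9 significant digits (round trip < 1e−8);
  the frame-table trajectory format uses 17 significant digits (exact
  round trip).

## Problem sizes

The validation suite runs entirely on synthetic data generated at test
time: planted-parameter recovery uses 4000–5000-frame trajectories of
10–60 residues; oracle-equivalence checks use ≤ 10 residues × 100 frames
where brute-force double loops are exact; clustering and PCA recovery use
1000–2000 frames of a 15–20-residue chain. These sizes put sampling noise
well inside the assertion bands while keeping the full suite in well under
a minute of compute.

## Known limitations

* Cα-only: no side-chain or hydrogen-bond geometry; "centers of mass" are
  unweighted Cα centroids, an approximation documented where used.
* No binary trajectory formats (DCD/XTC); convert externally or use the
  frame-table format.
* Structures to be compared must share a topology; there is no sequence
  or correspondence mapping.
* The clustering variant is a deterministic stand-in (see above); no
  automatic radius selection, density-based alternatives, or kinetic
  modeling.
* Second-rank (P2) orientational correlations and NMR order parameters
  are out of scope; `A_i(tau)` is the rank-1 correlation.
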