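# ensdyn

Residue-level ensemble-dynamics analysis of protein trajectories in R.

`ensdyn` quantifies how binding events reshape a protein complex's
conformational ensemble — the kind of question raised by allosteric
effectors such as the E3 ligase fragment RanBP2 acting on the E2–SUMO
(Ubc9–SUMO) conjugate: does binding restrict the partner's orientation,
rigidify distant functional loops, and concentrate the ensemble into fewer
conformational basins? The package answers these questions purely as
computable ensemble statistics over Cα trajectories (multi-model PDB or a
plain-text frame table), and ships synthetic-trajectory generators with
analytically known structure so that every statistic is testable end to end
without any simulation data.

## The statistics

For residues *i*, *j* with fluctuation vectors
ΔR<sub>i</sub>(t) = R<sub>i</sub>(t) − ⟨R<sub>i</sub>⟩ (after removal of
rigid-body motion), the **dynamic cross-correlation map** is

> C<sub>ij</sub> = ⟨ΔR<sub>i</sub> · ΔR<sub>j</sub>⟩ /
> √(⟨ΔR<sub>i</sub>²⟩ ⟨ΔR<sub>j</sub>²⟩) ∈ [−1, 1],

computed for the whole trajectory or for time windows
(`cross_correlation_matrix()`, `windowed_correlations()`).

For the **virtual backbone bond vector** M<sub>i</sub> (unit vector from
Cα<sub>i−1</sub> to Cα<sub>i</sub>), the time-delayed orientational
autocorrelation

> A<sub>i</sub>(τ) = ⟨M<sub>i</sub>(t) · M<sub>i</sub>(t + τ)⟩ ∈ [−1, 1]

measures each bond's orientational freedom (`bond_autocorrelation()`);
A<sub>i</sub>(0) = 1 and restricted bonds stay near 1 at long delays.

Around these sit the standard ensemble machinery: Kabsch superposition and
**chain-pivot RMSD** series (fit on one chain, measure another — sensitive
to quaternary rearrangements; `rmsd_timeseries()`), per-residue
**mean-square fluctuations** (`mean_square_fluctuations()`), Cα/centroid
**distance series** (`distance_timeseries()`), **radius-seeded k-means**
clustering of joined ensembles with RMSD-to-centroid as the similarity
measure and per-ensemble occupancy tables (`cluster_conformations()`,
`joined_ensemble_analysis()`), and joined-ensemble **PCA** with variance
proportions and projections (`pca_fit()`, `pca_project()`).

## Worked example

Cluster a three-basin synthetic ensemble with planted occupancies
50/15/35 % and recover them, then check a planted rotational-diffusion
decay:

```r
library(ensdyn)

spec <- synthetic_spec(
  chains = c(A = 20L), frames = 1000L, frame_interval = 0.1, seed = 5L,
  basins = list(list(offset = 3,   spread = 0.5, weight = 0.50),
                list(offset = 3,   spread = 0.5, weight = 0.15),
                list(offset = 4.5, spread = 0.5, weight = 0.35)))
ens <- generate_multibasin_ensemble(spec)
ref <- helix_reference(c(A = 20L))$coords

cluster_conformations(ens, ref, radius = 1.7, seed = 1)
#> conformational clustering: 3 cluster(s), radius 1.7 A, 1000 frames, 2 iteration(s)
#> occupancy (% of each source ensemble):
#>              cluster_1 cluster_2 cluster_3
#> trajectory_1      15.4      36.3      48.3
```

The three planted basins are found and their occupancies recovered to
within sampling noise (48.3/36.3/15.4 vs. planted 50/35/15). PCA on the
same ensemble puts 97.3 % of the variance on the two between-basin axes:

```r
pca_fit(ens, ref)
#> ensemble PCA: 1000 frames, 60 components
#> leading eigenvalues (A^2): 122.9 39.21 0.1529 0.1378 0.1233
#> variance proportions:     0.738 0.235 0.001 0.001 0.001
#> cumulative:               0.738 0.973 0.974 0.975 0.975
```

Bond vectors evolving by rotational diffusion with coefficient D decay as
exp(−2Dτ); with D = 0.5 rad²/ns:

```r
tr <- generate_rotational_diffusion_bonds(
  synthetic_spec(chains = c(A = 10L), frames = 5000L,
                 frame_interval = 0.02, seed = 3L), D = 0.5)
round(colMeans(bond_autocorrelation(tr, delays = c(0, 0.2, 0.5, 1))), 3)
#>   tau=0 tau=0.2 tau=0.5   tau=1
#>   1.000   0.820   0.615   0.378
```

(theory: 1, 0.819, 0.607, 0.368).

## Pipeline

A YAML configuration drives the whole battery reproducibly
(`validate_config()`, `run_pipeline()`); see
`inst/extdata/example_config.yaml` for a complete example producing RMSD,
msf, correlation, autocorrelation, clustering and PCA outputs plus a
checksummed `manifest.json` and a log. A thin CLI wrapper lives at
`inst/cli/ensdyn.R` (`run` / `validate` / `synth` subcommands). Parameter
presets for the Ubc9–SUMO–RanBP2 analyses (equilibration times, delay
grid, clustering radii) are documented in `sumoylation_presets()`.

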