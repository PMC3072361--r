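# cystsim

An agent-based simulator of epithelial cystogenesis: MDCK-like cells grown
in 3D matrix culture form hollow spherical cysts — a single cell layer
enclosing a fluid-filled lumen. `cystsim` models a 2D cross-section of this
process on a 100×100 hexagonal lattice with a cellular Potts
(Glazier–Graner–Hogeweg) engine, and ships the morphometric measurement
pipeline and the SM1/SM2/SSM1 similarity measures used to score simulated
time courses against cultured reference data.

## The model

Each cell and each lumen is a multi-site lattice object. The engine
proposes random single-site index changes and accepts them with the
Metropolis rule on the energy change ΔG of the Hamiltonian

```
G = Σ_cells  λ_A (TA − A)²  +  λ_P (TP − P)²
  + Σ_lumens λ_L (TA − A)²
  + Σ_edges  J(type_i, type_j)
  + connectivity and tight-junction penalties
```

with per-object target areas `TA` and target perimeters `TP`, per-edge
contact energies `J`, a hard penalty against fragmenting any cell, and a
hard penalty against remodeling tight junctions (a TJ is a lattice triangle
with one lumen corner and two corners in distinct cells; the sanctioned
remodeling happens in a separate end-of-cycle pass that also merges lumens
whose junctions meet).

On top of the Potts engine, each cell runs per-cycle agent logic
(48 cycles = 1 simulated day):

* **Target size.** Non-stabilized cells project their "wedge" area
  `W = A·M²/(M² − L²)` (M, L = half the boundary edges facing matrix and
  lumen) and steer `TA` toward an ideal wedge area of 82 grid points;
  stabilized cells hold `TA = 48 + 0.5·L`.
* **Polarization.** On first matrix contact a counter drawn uniform on
  [0.75, 1.25]×42 cycles starts; at zero the cell polarizes.
* **Stabilization.** Polarized cells bordering matrix and lumen stabilize
  when the lumen exceeds `stableRatio`×1000 = 500 grid points (LS
  mechanism), or on an internal timer (TS variant).
* **Division.** A cell-cycle counter (uniform on [0.75, 1.25]×70 cycles)
  decrements whenever `A > 20.5` — only with probability 0.15 once
  stabilized — and at zero the cell splits in half along an axis set by
  `divisionReg`: toward its stored midbody / the lumen centroid (oriented),
  uniformly random, or rotated 90° (reversed).
* **Death.** Per cycle, cells start dying with probability 4×10⁻⁴ (matrix
  contact) or 0.02 (no matrix contact), then shrink by 9 grid points of
  target area per cycle until resorbed.
* **Lumens.** Polarized matrix-contacting cells without lumen contact open
  a 1-site lumen at their midbody next to a similar neighbor; lumens expand
  under `ΔTA = max(0, 0.003·(estimatedArea + neighbors) −
  27·median(stretch))` and merge through tight-junction reorganization.

Areas scale at 2.25 µm² per grid point and perimeters at 0.75 µm per edge.

## A worked example

```r
library(cystsim)

params <- sim_params()              # all defaults, LS stabilization
run <- run_simulation(params, n_days = 10, seed = 42)
run$metrics[c(1, 4, 7, 11), c("day", "cell_number", "cyst_area",
                              "lumen_area", "cellular_to_cyst_ratio",
                              "lumen_count")]
#>    day cell_number cyst_area lumen_area cellular_to_cyst_ratio lumen_count
#> 1    0           1        82          0              1.0000000           0
#> 4    3           8       505         69              0.8633663           1
#> 7    6          15       980        271              0.7234694           1
#> 11  10          19      2001        994              0.5032484           1
```

One cell of 82 grid points (≈ 184 µm²) grows to a ~20-cell cyst whose
single lumen occupies roughly half the cross-section by day 10 — the
hallmark trajectory of cystogenesis. `run$events` logs every division,
polarization, stabilization, death and lumen event with its cycle.

Replicate batches and the preset intervention experiments
(`random_division`, `reversed_division`, `no_luminal_death`,
`delayed_polarization`, `slow_death`, `ts_variant`):

```r
batch <- run_experiment("control", replicates = 20, days = 10, seed = 1)
subset(batch$summary, day == 4,
       c(day, cell_number_mean, pct_single_lumen, pct_multi_lumen))
#>   day cell_number_mean pct_single_lumen pct_multi_lumen
#> 5   4              9.2               95               5
```

Score a batch against a reference time series (here the packaged synthetic
demonstration series; supply your own measured table with columns
`day,metric,mean,sd` for real validation):

```r
ref <- read_reference_series(system.file("extdata",
        "synthetic_reference_demo.csv", package = "cystsim"))
rep <- sm_report(batch$trajectories, ref)
rep$summary
```

A thin command-line interface over the same functions ships at
`inst/scripts/cystsim.R` (verbs `simulate`, `experiment`, `measure`,
`validate`).

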