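---
title: "Model and methods: hexagonal-lattice Potts simulation of cystogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: hexagonal-lattice Potts simulation of cystogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystsim)
```

`cystsim` simulates the growth of a single epithelial cyst — the hollow,
single-layered sphere that MDCK cells form in 3D matrix culture — as a 2D
cross-section on a hexagonal lattice. This vignette is the package's own
account of the model: the energy function and its constraints, the
per-cycle cell logic, every tunable parameter with its default and the
reasoning behind it, the numerical choices, what the simulations do and do
not reproduce, and the known limitations.

## Lattice and energy function

The field is a 100×100 hexagonal lattice in axial coordinates `(col, row)`
with the Cartesian embedding `x = col + row/2`, `y = row·√3/2` (unit
center-to-center distance). Boundaries are non-periodic; out-of-field space
behaves as extracellular matrix. Every site is indexed to exactly one
object: the matrix, a cell, or a lumen. Cells and lumens are multi-site
cellular Potts (Glazier–Graner–Hogeweg) objects evolving by energy-biased
single-site index changes; an attempt picks a random site in the bounding
box of the occupied region (plus a two-site halo), a random neighbor
direction, computes the energy change ΔG of copying the neighbor's index
onto the site, and accepts with the Metropolis probability
`min(1, exp(−ΔG/T))`.

The energy is the standard GGH form:

* **Area constraint** `λ·(TA − A)²` per object — cells use
  `lambda_area = 5`, lumens the stiffer `lambda_lumen = 20`, representing
  the outward pressure of the fluid-filled cavity.
* **Perimeter constraint** `lambda_perim·(TP − P)² = 2.5·(TP − P)²` per
  cell. `P` is the count of boundary edges; lumens have no perimeter
  target — their outline is shaped entirely by the surrounding cells.
* **Adhesion**: a per-edge contact energy `J(type_i, type_j)` between
  sites of different objects, with types matrix / unpolarized / polarized /
  stabilized / dying / lumen.
* **Constraints**: a large penalty (`connectivity_penalty = 1e7`) is added
  when a move would (i) fragment an object, checked by flood fill over the
  donor's remaining sites; (ii) change the local tight-junction count;
  (iii) create a lumen–matrix adjacency; or (iv) give a living cell contact
  with a second lumen. Penalized moves are effectively rejected, which is
  how the model expresses that cells are cohesive and that tight junctions
  seal the apical (lumen-facing) surface.

Because consecutive neighbor directions on the hexagonal lattice are
themselves adjacent, the lattice's triangles are exactly the
(site, neighbor k, neighbor k+1) triples. A tight junction is a triangle
with one lumen corner and two corners in two *different* cells — the
lattice analogue of the junction pair sealing two cells' apical membranes.
Only triangles containing the changed site can change, so the local
before/after TJ comparison in ΔG equals a global recount (verified against
a global enumeration oracle in the test suite).

## Per-cycle agent logic

A simulated day is 48 cycles of 30 simulated minutes. Each cycle executes,
in a fixed order: point-registry rebuild and engulfment of isolated matrix
points; lumen target growth and merging; death initiation and shrinkage;
per-cell target updates, polarization and stabilization; lumen creation;
division; then `attempts_factor = 10` Potts attempts per occupied site and
the end-of-cycle TJ reorganization pass. Cells act in ascending id
(creation) order, and a single RNG stream drives every draw in this fixed
order, so a seed reproduces a run bit for bit.

**Target size.** Cyst cross-sections are treated as roughly circular. A
cell with area `A`, matrix half-contact `M` and lumen half-contact `L`
projects the annular wedge it occupies to the cyst center:
`W = A·M²/(M² − L²)` for `M > L > 0` (for a wedge between radii `r < R`,
`W/A = R²/(R² − r²)`, with arcs proportional to `2M` and `2L`). The cell
then steers its target to `TA = A + (wedgeArea − W)`, clamped to
`[1, wedgeArea]` with `wedgeArea = 82` grid points (≈ 184 µm², the
pre-stabilization cell size). Limits: with no lumen contact `W = A`, so
the target moves to `wedgeArea`; with `L ≥ M` the wedge diverges and the
target drops to its floor — lumen-facing cells are squeezed; a cell with
no matrix anchor has no wedge and its target moves to `wedgeArea` as well.
Once stabilized, a cell instead holds `TA = stable_target_area +
stable_area_slope·L = 48 + 0.5·L`: a fixed small area that increases only
slightly with lumen contact, mimicking the maintenance of minimal cell
height under an expanding lumen. The slope 0.5 is a package choice (the
behavior is specified only qualitatively).

**Target perimeter.** `TP = multiplier·K·2√(πA)` — the circumference of a
circle of the cell's area, scaled into lattice-edge units. `K` is a pure
scaling factor with no stated value; we calibrated it geometrically
*before* running validation batches: a compact hexagonal disc of `n` sites
has a boundary-edge count of about `6.93·√n`, and cells packed in a small
cyst measure `P/(2√(πA)) ≈ 2.1–2.3`, so `K = 4.05` makes `TP` match the
relaxed perimeter of packed cells at the default `multiplier = 0.6`. This
matters because the dimensionless **stretch** of a cell is defined here as
`max(0, P/TP − 1)`: zero for relaxed, packed cells, positive when the
expanding lumen distends them. (The stretch definition is a package
reconstruction; the source behavior is specified only as "the degree cells
are stretched".)

**Polarization.** On first matrix contact a cell draws
`polarCounter ~ U[0.75, 1.25]·polar_delay` (default 42 cycles = 21 h) and
decrements it each cycle; at zero it becomes polarized. A cell that never
touches matrix never polarizes.

**Stabilization.** Both mechanisms are always armed and the parameters
select between them. *LS* (lumen-size, the default): a polarized cell
bordering both matrix and lumen stabilizes when the lumen's area exceeds
`stable_ratio·1000 = 500` grid points. *TS* (timer): a counter
`U[0.75, 1.25]·shift_delay` starts at polarization; the default
`shift_delay = 140000` makes it inert, and the `ts_variant` preset
(`shift_delay = 200`, `stable_ratio = 1000`) swaps the mechanisms.

**Division.** The cell-cycle counter starts at `U[0.75, 1.25]·cell_cycle`
(default 70 cycles ≈ 35 h) and decrements in every cycle in which
`A > doubling_area/2 = 20.5` — with probability
`1 − stable_cycle_delay = 0.15` once stabilized, which is what slows
growth after the lumen reaches its critical size. At zero the cell splits
in half: sites are ranked by signed distance to the division line through
the centroid and the daughter takes the `floor(A/2)` most-positive sites
(a median split; exact halving, odd remainder to the parent, ties broken
by site index). The line's direction follows `division_reg`: **1**
(default) through the lumen centroid when the cell touches a lumen, else
through the stored midbody, else random — a radial split line that keeps
both daughters spanning matrix to lumen; **0** uniformly random; **2**
random until polarized, then oriented; **3** the oriented line rotated
90°, which stacks the daughters radially and disrupts the monolayer. Both
daughters store the pre-division centroid as their midbody; the daughter's
polarization clock is jittered around the parent's by
`U[0.5, 1.5]·polar_delay − polar_delay`. Immediately after the forced
first division (the initial cell's counter is set to 1 during cycle 1, so
it divides at cycle 2) both cells redraw their counters on
`[(1 − cluster_prob)·cell_cycle, cell_cycle] = [14, 70]`, mimicking the
partial cell-cycle synchrony of freshly plated clusters.

**Death.** Each cycle a living cell starts dying with probability
`death_rate_epi = 4×10⁻⁴` if it touches matrix and
`death_rate_lumen = 0.02` if it does not (the rule applies to every state,
including unpolarized cells). Shrinkage begins the following cycle: the
target area falls by `dying_shrink_rate = 9` grid points per cycle, and
the cell is removed when its area reaches zero. Two energetic choices make
resorption behave like apoptosis rather than stalling: dying cells drop
their perimeter target to zero (apoptotic rounding — otherwise the
perimeter constraint rewards one-site-wide chains that can never finish
shrinking), and a move that removes a dying cell's last site erases its
remaining constraint energies instead of charging `(TP − 0)²`. Dying cells
are also exempt from the two tight-junction constraints: apoptotic cells
lose junctional integrity, and without the exemption a dying cell wedged
between two lumens is geometrically frozen and the lumens can never merge.
The resulting dying duration is paced by the target-area staircase:
roughly `TA₀/9` cycles plus a small Potts lag, i.e. ≈ 5–13 cycles
depending on the size at death.

**Lumen creation.** A polarized cell creates a lumen when it touches
matrix but no lumen, and a site near its midbody is adjacent to another
polarized, lumen-free cell. The site search covers the midbody site and
its surroundings out to lattice distance 2 (nearest first, deterministic
order) because the nascent apical patch opens *near* the last division
plane, not at one exact lattice point; each candidate site must satisfy
the global invariants (no matrix neighbor, no adjacent cell that already
touches a different lumen, no fragmentation of the site's current owner).
Stabilized cells never create lumens. The new lumen starts as one site
with target area 1.

**Lumen growth and merging.** Each cycle a lumen with `n ≥ 1` contacting
cells grows its target by
`max(0, lumen_growth_rate·(estimatedArea + n) − lgr_subtract·median(stretch))`
where `estimatedArea` is the lumen's area plus the areas of all contacting
cells and the stretch statistic is the median over the living contacting
cells. Growth therefore accelerates with cyst mass and equilibrates when
the typical distension of the wall reaches about
`lumen_growth_rate·estimatedArea / lgr_subtract`. Two structural choices
of this reconstructed law deserve comment (the defining formula exists
only as a verbal description): the *sum* form `est + n` was chosen over
the product `est·n` because the product grows super-exponentially once the
lumen dominates `est` — in trials it crushed the cell layer to a
cellular/cyst ratio of 0.04 by day 8, and no reachable stretch level can
brake it; and the *median* was chosen over the mean because a single
deformed cell among few neighbors otherwise stalls the whole lumen. At the
end of each cycle, TJ points may convert to lumen (Metropolis-gated, and
only where a neighboring point of a cell already holding apical surface on
that lumen can become the new TJ — junctions slide along the apical ring,
they do not insert apical membrane into a contact-free cell), and two
adjacent TJs of different lumens convert both points and merge the lumens,
the lower id surviving with the summed target area. Lumens brought into
direct contact by the resorption of the cells separating them merge the
same way.

## Parameters

The biological defaults (areas in grid points, durations in cycles,
probabilities per cycle): `wedge_area 82`, `lambda_area 5`,
`stable_target_area 48`, `cell_cycle 70`, `lambda_perim 2.5`,
`polar_delay 42`, `shift_delay 140000`, `doubling_area 41`,
`division_reg 1`, `multiplier 0.6`, `lumen_growth_rate 0.003`,
`death_rate_lumen 0.02`, `death_rate_epi 4e-4`, `cluster_prob 0.8`,
`lgr_subtract 27`, `dying_shrink_rate 9`, `stable_ratio 0.5`,
`stable_cycle_delay 0.85`; 48 cycles per day, 2.25 µm² per grid point,
0.75 µm per edge.

Engine settings the source leaves open, fixed here by calibration against
the control-condition endpoints (day-4 single-lumen fraction, day-3 cell
numbers, dying durations, the multi-lumen and ratio time courses):
temperature `T = 10`; `attempts_factor = 10` proposals per occupied site
per cycle; `K = 4.05`; adhesion `J(cell,matrix) = 8`, `J(cell,cell) = 4`,
`J(cell,lumen) = 4`, `J(lumen,matrix) = 20` (never realised — the
lumen-matrix penalty is hard). Raising `J(cell,lumen)` above
`J(cell,cell)` makes small satellite lumens unable to wet cell-cell
interfaces; they then persist to day 10 and the multi-lumen fraction
rises over time instead of falling.

## What a simulation reproduces

Under control defaults, 20–50-replicate batches show: one or two cells at
day 0 growing to ~8 cells at day 3 and ~17–25 by day 10 with the growth
rate dropping after day 6 (lumen-size-triggered stabilization); a single
lumen in ~90–95% of cysts by day 4 after early multiples (~30% at day 2)
merge; monotone cyst and lumen expansion with the cellular-to-cyst ratio
falling from 1.0 toward ~0.5; mean dying durations of ~8.6 cycles (~4.3 h)
at the default shrink rate and ~7.5–7.9 h when it is halved. The
similarity measures score such batches against a reference table of
per-day means and SDs: SM1 (fraction of replicates within ±25% of the
reference mean; window boundaries closed, days 1–10, pass above 0.5 on at
least nine days), SM2 (absolute difference of coefficients of variation;
strong < 0.15 on nine days, medium < 0.25 on eight), and SSM1 (SM1 of the
reference's own raw values). Only one printed anchor ships with the
package (day-3 cell-number mean 8.9, window 6.7–11.1); the bundled
`synthetic_reference_demo.csv` is generated, clearly synthetic data for
demonstrating the workflow, not measured truth.

## Known limitations

* **Intervention strength.** Randomizing or reversing the division axis
  degrades the monolayer in the right direction (more multi-lumen, fewer
  SLSL cysts, ~6% overall SLSL under reversal) but less sharply than the
  published in vitro and in silico interventions this model family targets:
  displaced daughters are healed within roughly a simulated day by luminal
  death of their buried siblings followed by lumen expansion into the
  vacated space, so the thick lumen-free multilayers that sustain ongoing
  lumen creation rarely persist. The day-4 single-lumen fraction under
  disrupted orientation is therefore too high (~60–70%), and the
  multi-lumen floor over days 2–9 too low. The calibration knobs available
  (adhesion, temperature, K, growth-law structure) trade this against
  control fidelity along a single merging/healing axis; the defaults favor
  the control condition.
* **Ratio flattening.** The cellular-to-cyst ratio keeps declining at a
  similar rate through day 10 rather than clearly flattening after day 6,
  because the lumen-growth brake has not yet equilibrated at that cyst
  size under the reconstructed law.
* The model is a 2D cross-section: no 3D extrapolation is attempted. Cells
  are atomic agents (no subcellular components), there is no cell
  migration, mitotic swelling or cyst rotation, and lumens only expand and
  merge. Simulations model exactly one cyst per field.
* Simulated variances are smaller than cultured ones (a single synthetic
  clone in a perfectly homogeneous matrix), so SM2 comparisons against
  real data probe the model's variability assumptions, not measurement
  noise.

## Numerical choices

Counters are real-valued and compared to zero with `≤`; uniform draws are
continuous. Ties in the division split go to the side the median assigns,
then by site index. Engulfment of an isolated matrix point goes to the
neighbor owning most of its edges, lowest id on ties. The TJ pass
processes points in row-major order. Audits (`audit_level = 2`) recount
areas, perimeters and the partition, verify connectivity of every object,
the single-lumen-contact invariant and the absence of lumen-matrix
adjacency after every cycle, and abort with a diagnostic on the first
violation; the acceptance test suite runs five audited ten-day replicates.
Problem sizes in the shipped tests (12-replicate batches, 6×6 oracle
lattices, 10³ oracle comparisons) were chosen so the full suite exercises
every subsystem in a few minutes; the acceptance script runs the published
50-replicate design.
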