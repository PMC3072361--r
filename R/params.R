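#' Contact-type labels used by the adhesion matrix
#'
#' Order matters: it is the row/column order of the 6x6 adhesion matrix.
#' @keywords internal
adhesion_types <- c("matrix", "unpolarized", "polarized", "stabilized",
                    "dying", "lumen")

#' Build a symmetric adhesion (contact-energy) matrix
#'
#' Contact energies are per lattice edge between sites of different objects.
#' Smaller values mean stronger effective adhesion (lower interfacial energy).
#' All four cell classes (unpolarized, polarized, stabilized, dying) share the
#' same contact energies by default; the lumen-matrix energy is set high
#' because a lumen surface exposed to matrix is not a physical configuration
#' and is additionally forbidden by a hard constraint in the engine.
#'
#' @param cell_matrix contact energy per cell-matrix edge.
#' @param cell_cell contact energy per edge between two different cells.
#' @param cell_lumen contact energy per cell-lumen edge.
#' @param lumen_matrix contact energy per lumen-matrix edge (never realised).
#' @param lumen_lumen contact energy per lumen-lumen edge (adjacent lumens
#'   merge immediately, so this is never realised either).
#' @return a symmetric 6x6 numeric matrix with dimnames [adhesion_types].
#' @export
default_adhesion <- function(cell_matrix = 8, cell_cell = 4, cell_lumen = 4,
                             lumen_matrix = 20, lumen_lumen = 0) {
  J <- matrix(0, 6, 6, dimnames = list(adhesion_types, adhesion_types))
  cells <- c("unpolarized", "polarized", "stabilized", "dying")
  J[cells, cells] <- cell_cell
  J["matrix", cells] <- cell_matrix
  J[cells, "matrix"] <- cell_matrix
  J[cells, "lumen"] <- cell_lumen
  J["lumen", cells] <- cell_lumen
  J["lumen", "matrix"] <- lumen_matrix
  J["matrix", "lumen"] <- lumen_matrix
  J["lumen", "lumen"] <- lumen_lumen
  J
}

#' Simulation parameters
#'
#' Returns the complete parameter set of the model with its documented
#' defaults. Units are relational: areas in grid points (one hexagonal lattice
#' site), perimeters in lattice edges, durations in simulation cycles
#' (48 cycles = 1 simulated day = 24 h, i.e. 30 min per cycle). Areas scale
#' to physical units at 2.25 um^2 per grid point and perimeters at 0.75 um
#' per edge.
#'
#' @param wedge_area target area of unpolarized cells and ideal wedge area
#'   for polarized cells (grid points).
#' @param lambda_area area-constraint stiffness of cells.
#' @param lambda_lumen area-constraint stiffness of lumens (fixed high to
#'   represent the outward force of the expanding lumen).
#' @param stable_target_area target area of stabilized cells (grid points).
#' @param stable_area_slope increase of a stabilized cell's target area per
#'   unit of lumen contact L (grid points per half-edge).
#' @param cell_cycle mean cell-cycle duration used to draw `cycleCounter`
#'   (cycles); the draw is uniform on [0.75, 1.25] x `cell_cycle`.
#' @param lambda_perim perimeter-constraint stiffness of cells.
#' @param polar_delay mean polarization delay used to draw `polarCounter`
#'   (cycles) on first matrix contact.
#' @param shift_delay mean stabilization timer (cycles) for the timer-triggered
#'   (TS) stabilization mechanism; the default is effectively "never", which
#'   selects the lumen-size (LS) mechanism.
#' @param doubling_area twice the minimal area a cell must have for its cell
#'   cycle to progress (grid points).
#' @param division_reg division-axis rule: 0 random, 1 oriented
#'   (midbody/lumen-directed), 2 random until polarized then oriented,
#'   3 oriented rotated by 90 degrees (reversed).
#' @param multiplier user-set factor in the target-perimeter rule.
#' @param k_perim scaling factor K in the target-perimeter rule
#'   TP = multiplier * K * 2*sqrt(pi*A). The default makes TP match the
#'   boundary-edge count of cells packed in a small cyst (measured
#'   P / (2*sqrt(pi*A)) of about 2.1-2.2 edges) at the default `multiplier`,
#'   so the stretch measure vanishes for relaxed, packed cells and becomes
#'   positive only when the expanding lumen distends them.
#' @param lumen_growth_rate rate multiplier of lumen target-area expansion.
#' @param death_rate_lumen per-cycle death probability of cells without
#'   matrix contact.
#' @param death_rate_epi per-cycle death probability of cells with matrix
#'   contact.
#' @param cluster_prob controls the spread of the first two cells' cycle
#'   counters, mimicking post-plating cell clustering.
#' @param lgr_subtract multiplied by mean cell stretch to slow lumen
#'   expansion.
#' @param dying_shrink_rate amount subtracted from a dying cell's target area
#'   each cycle (grid points/cycle).
#' @param stable_ratio critical lumen size (x 1000 grid points) at which
#'   lumen-contacting polarized cells stabilize (LS mechanism).
#' @param stable_cycle_delay 1 minus the probability that a stabilized cell
#'   decrements its cycle counter in a cycle.
#' @param cycles_per_day simulation cycles per simulated day.
#' @param minutes_per_cycle grounding of one cycle in minutes.
#' @param area_scale physical area per grid point (um^2).
#' @param perimeter_scale physical length per lattice edge (um).
#' @param width,height lattice dimensions (sites).
#' @param temperature acceptance-function temperature of the Potts step.
#' @param attempts_factor index-change attempts per cycle per non-matrix site.
#' @param connectivity_penalty energy penalty for moves that fragment a cell
#'   or remodel a tight junction; must dwarf any physical energy change.
#' @param adhesion 6x6 contact-energy matrix, see [default_adhesion()].
#' @return a named list of class `sim_params`.
#' @export
sim_params <- function(wedge_area = 82,
                        lambda_area = 5,
                        lambda_lumen = 20,
                        stable_target_area = 48,
                        stable_area_slope = 0.5,
                        cell_cycle = 70,
                        lambda_perim = 2.5,
                        polar_delay = 42,
                        shift_delay = 140000,
                        doubling_area = 41,
                        division_reg = 1,
                        multiplier = 0.6,
                        k_perim = 4.05,
                        lumen_growth_rate = 0.003,
                        death_rate_lumen = 0.02,
                        death_rate_epi = 0.0004,
                        cluster_prob = 0.8,
                        lgr_subtract = 27,
                        dying_shrink_rate = 9,
                        stable_ratio = 0.5,
                        stable_cycle_delay = 0.85,
                        cycles_per_day = 48,
                        minutes_per_cycle = 30,
                        area_scale = 2.25,
                        perimeter_scale = 0.75,
                        width = 100,
                        height = 100,
                        temperature = 10,
                        attempts_factor = 10,
                        connectivity_penalty = 1e7,
                        adhesion = default_adhesion()) {
  p <- list(wedge_area = wedge_area, lambda_area = lambda_area,
            lambda_lumen = lambda_lumen,
            stable_target_area = stable_target_area,
            stable_area_slope = stable_area_slope, cell_cycle = cell_cycle,
            lambda_perim = lambda_perim, polar_delay = polar_delay,
            shift_delay = shift_delay, doubling_area = doubling_area,
            division_reg = as.integer(division_reg), multiplier = multiplier,
            k_perim = k_perim, lumen_growth_rate = lumen_growth_rate,
            death_rate_lumen = death_rate_lumen,
            death_rate_epi = death_rate_epi, cluster_prob = cluster_prob,
            lgr_subtract = lgr_subtract,
            dying_shrink_rate = dying_shrink_rate,
            stable_ratio = stable_ratio,
            stable_cycle_delay = stable_cycle_delay,
            cycles_per_day = as.integer(cycles_per_day),
            minutes_per_cycle = minutes_per_cycle,
            area_scale = area_scale, perimeter_scale = perimeter_scale,
            width = as.integer(width), height = as.integer(height),
            temperature = temperature, attempts_factor = attempts_factor,
            connectivity_penalty = connectivity_penalty, adhesion = adhesion)
  class(p) <- "sim_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    p$lambda_area >= 0, p$lambda_lumen >= 0, p$lambda_perim >= 0,
    p$temperature > 0, p$attempts_factor >= 0,
    p$width > 0, p$height > 0,
    p$wedge_area > 0, p$stable_target_area > 0, p$cell_cycle > 0,
    p$doubling_area > 0, p$cycles_per_day > 0, p$minutes_per_cycle > 0,
    p$division_reg %in% 0:3,
    p$cycles_per_day * p$minutes_per_cycle == 1440
  )
  rates <- c(p$lumen_growth_rate, p$death_rate_lumen, p$death_rate_epi,
             p$cluster_prob, p$stable_cycle_delay)
  if (any(rates < 0 | rates > 1))
    stop("all probability/rate parameters must lie in [0, 1]")
  J <- p$adhesion
  if (!is.matrix(J) || any(dim(J) != c(6, 6)))
    stop("adhesion must be a 6x6 matrix")
  if (!isTRUE(all.equal(J, t(J))))
    stop("adhesion matrix must be symmetric")
  if (p$connectivity_penalty < 1e5)
    stop("connectivity_penalty must dwarf physical energy scales")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Cystogenesis simulation parameters\n")
  scalars <- x[!vapply(x, is.matrix, logical(1))]
  cat(paste0("  ", format(names(scalars), width = 22), " ",
             vapply(scalars, format, character(1))), sep = "\n")
  cat("  adhesion matrix (per-edge contact energies):\n")
  print(x$adhesion)
  invisible(x)
}

#' Preset intervention experiments
#'
#' Named presets reproduce the model's standard in silico experiments as
#' parameter overrides relative to the defaults of [sim_params()]:
#' * `control` — defaults, lumen-size (LS) stabilization.
#' * `ts_variant` — timer (TS) stabilization: `shift_delay = 200`,
#'   `stable_ratio = 1000` (the lumen-size trigger can then never fire).
#' * `random_division` — `division_reg = 0`, all divisions randomly oriented.
#' * `reversed_division` — `division_reg = 3`, the division axis is rotated
#'   90 degrees so it runs parallel to the lumen edge.
#' * `no_luminal_death` — `death_rate_lumen = 0`; matrix-contacting death
#'   is unchanged.
#' * `delayed_polarization` — `polar_delay = 130` (65 h instead of 21 h).
#' * `slow_death` — `dying_shrink_rate = 4.5`, dying cells shrink at half
#'   speed.
#'
#' @param name preset name.
#' @param replicates default replicate count for [run_experiment()].
#' @param days default simulated days.
#' @return list with elements `name`, `overrides`, `replicates`, `days`.
#' @export
sim_preset <- function(name, replicates = 50, days = 10) {
  presets <- list(
    control = list(),
    ts_variant = list(shift_delay = 200, stable_ratio = 1000),
    random_division = list(division_reg = 0L),
    reversed_division = list(division_reg = 3L),
    no_luminal_death = list(death_rate_lumen = 0),
    delayed_polarization = list(polar_delay = 130),
    slow_death = list(dying_shrink_rate = 4.5)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  structure(list(name = name, overrides = presets[[name]],
                 replicates = replicates, days = days),
            class = "sim_preset")
}

#' Resolve a preset (plus ad hoc overrides) into a full parameter set
#'
#' @param preset an [sim_preset()] or a preset name.
#' @param overrides named list of additional parameter overrides.
#' @param base base parameters to modify.
#' @return an `sim_params` object.
#' @export
resolve_params <- function(preset = "control", overrides = list(),
                           base = sim_params()) {
  if (is.character(preset)) preset <- sim_preset(preset)
  ov <- utils::modifyList(preset$overrides, overrides)
  bad <- setdiff(names(ov), names(base))
  if (length(bad))
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(unclass(base), ov)
  class(p) <- "sim_params"
  validate_params(p)
  p
}
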