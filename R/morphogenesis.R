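# Per-cycle cell logic: target size and shape, polarization, stabilization,
# death, division, lumen creation. The engine applies these rules each
# cycle; the formula-level functions here are the reference implementations
# used for reasoning and unit tests, and they define the rules exactly as
# the engine computes them.

#' Projected wedge area of a cell
#'
#' A lumen-cyst cross-section is treated as approximately circular. A cell
#' with outer (matrix) arc proportional to 2M and inner (lumen) arc
#' proportional to 2L occupies an annular wedge of area A; extending that
#' wedge to the cyst center gives the projected wedge area
#' `W = A * M^2 / (M^2 - L^2)` for `M > L > 0`. With no lumen contact
#' (L = 0) the wedge is the cell itself, `W = A`; with no matrix contact no
#' wedge is defined and `W = A` as well. When `L >= M` (cell more apical
#' than basal, a thin distended shell) the projected wedge diverges and the
#' update below drives the target area to its floor.
#'
#' @param A cell area (grid points).
#' @param M half the number of cell boundary edges contacting matrix.
#' @param L half the number of cell boundary edges contacting lumen.
#' @return the projected wedge area (possibly Inf).
#' @export
wedge_area <- function(A, M, L) {
  stopifnot(A >= 1, M >= 0, L >= 0)
  if (M <= 0 && L > 0) return(NA_real_)
  if (L <= 0) return(A)
  denom <- M^2 - L^2
  if (denom <= 0) return(Inf)
  A * M^2 / denom
}

#' Target-area update for a non-stabilized cell
#'
#' The cell subtracts its projected wedge area from the ideal `wedge_area`
#' parameter and adds the difference to its current area, clamped to
#' `[1, wedge_area]`.
#'
#' @param A,M,L as in [wedge_area()].
#' @param params an [sim_params()] object.
#' @return the new target area TA.
#' @export
target_area_update <- function(A, M, L, params = sim_params()) {
  W <- wedge_area(A, M, L)
  if (is.na(W)) W <- params$wedge_area   # apical-only cell: no adjustment
  ta <- A + (params$wedge_area - W)
  min(max(ta, 1), params$wedge_area)
}

#' Target area of a stabilized cell
#'
#' Stabilized cells hold a fixed smaller area that increases only slightly
#' with lumen contact: `TA = stable_target_area + stable_area_slope * L`.
#'
#' @param L lumen half-edge contact count.
#' @param params an [sim_params()] object.
#' @return the target area.
#' @export
stabilized_target_area <- function(L, params = sim_params()) {
  params$stable_target_area + params$stable_area_slope * L
}

#' Target perimeter from current area
#'
#' `TP = multiplier * K * 2 * sqrt(pi * A)`: the perimeter of a circle of
#' the cell's area, scaled into lattice-edge units by K and tightened by
#' `multiplier`. Two cells of equal area always share the same TP.
#'
#' @param A cell area (vectorized).
#' @param params an [sim_params()] object.
#' @return the target perimeter (edges).
#' @export
target_perimeter <- function(A, params = sim_params()) {
  stopifnot(all(A >= 1))
  params$multiplier * params$k_perim * 2 * sqrt(pi * A)
}

#' Cell stretch
#'
#' Relative excess perimeter, `max(0, P/TP - 1)`: zero for a relaxed
#' (compact) cell and positive as the expanding lumen distends it. Used by
#' the lumen growth law.
#'
#' @param P current perimeter (edges).
#' @param TP target perimeter.
#' @return dimensionless stretch (vectorized).
#' @export
cell_stretch <- function(P, TP) {
  pmax(0, P / TP - 1)
}

#' Lumen target-area growth increment
#'
#' `max(0, lumen_growth_rate * (estimatedArea + totalNeighbors) -
#' lgr_subtract * median(stretch))`, where `estimatedArea` is the lumen's
#' area plus the areas of all contacting cells and the stretch term is the
#' median over the living (non-dying) contacting cells — the typical
#' distension of the cells the lumen pushes against, robust to single
#' deformed cells. Expansion therefore accelerates with cyst mass and
#' equilibrates when the typical distension reaches about
#' `lumen_growth_rate * estimatedArea / lgr_subtract`. The increment is
#' clamped at zero: stretch never shrinks the lumen target.
#'
#' @param lumen_area current lumen area (grid points).
#' @param cell_areas areas of the contacting cells.
#' @param stretches stretch values of the living contacting cells.
#' @param params an [sim_params()] object.
#' @return the (non-negative) target-area increment.
#' @export
lumen_growth_increment <- function(lumen_area, cell_areas, stretches,
                                   params = sim_params()) {
  n <- length(cell_areas)
  if (n < 1) return(0)
  est <- lumen_area + sum(cell_areas)
  brake <- if (length(stretches)) stats::median(stretches) else 0
  max(0, params$lumen_growth_rate * (est + n) -
         params$lgr_subtract * brake)
}

#' Division axis of a cell
#'
#' Returns the unit direction of the division line through the cell
#' centroid under the `division_reg` rule: 0 random; 1 toward the lumen
#' centroid when the cell touches a lumen, else toward the stored midbody,
#' else random (never-divided isolated cell); 2 random until polarized then
#' as 1; 3 the mode-1 direction rotated 90 degrees. Random modes consume
#' one uniform draw from the R RNG stream.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @param id a living cell id.
#' @return numeric c(dx, dy), unit length.
#' @export
division_axis <- function(state, params, id) {
  engine_division_axis(state, unclass(params), id)
}

#' Divide a cell
#'
#' Splits the cell's area in half along the division axis: sites are ranked
#' by signed distance to the line and the daughter takes the most-positive
#' half (`floor(A/2)` sites, so odd areas leave the larger half with the
#' parent). Both midbodies are set to the pre-division centroid, both cycle
#' counters are redrawn uniform on `[0.75, 1.25] * cell_cycle`, and the
#' daughter's polarization counter is jittered around the parent's.
#' One-site cells (and degenerate splits) defer division.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @param id a living cell id.
#' @return list with the mutated `state`, `daughter` (new id, or 0 if
#'   deferred), and the division `events`.
#' @export
divide_cell <- function(state, params, id) {
  engine_divide(state, unclass(params), id)
}
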