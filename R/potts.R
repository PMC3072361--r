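# Energy model and the stochastic index-change step. The hot path lives in
# src/engine.cpp; the functions here are the module surface plus thin
# wrappers used for unit-level reasoning about single moves.

#' Quadratic area-constraint energy
#'
#' `lam * (TA - A)^2`: the cost of deviating from the target area.
#'
#' @param A current area (grid points).
#' @param TA target area.
#' @param lam stiffness (lambda_area for cells, lambda_lumen for lumens).
#' @return energy (vectorized).
#' @export
energy_area <- function(A, TA, lam) {
  stopifnot(all(lam >= 0))
  lam * (TA - A)^2
}

#' Quadratic perimeter-constraint energy
#'
#' @param P current perimeter (boundary edges).
#' @param TP target perimeter.
#' @param lam stiffness (lambda_perim).
#' @return energy (vectorized).
#' @export
energy_perimeter <- function(P, TP, lam) {
  stopifnot(all(lam >= 0))
  lam * (TP - P)^2
}

obj_adh_type <- function(objects, id) {
  if (id == 0) return("matrix")
  i <- match(id, objects$id)
  if (objects$kind[i] == 1L) return("lumen")
  if (objects$dying[i]) return("dying")
  c("unpolarized", "polarized", "stabilized")[objects$state[i] + 1]
}

#' Adhesion energy of a site under a hypothetical occupant
#'
#' Sums the per-edge contact energies between the site (as if owned by
#' `occupant_id`) and every neighboring site owned by a different object.
#' Out-of-field neighbors count as matrix.
#'
#' @param state a simulation state.
#' @param col,row site coordinates.
#' @param occupant_id object id assumed to own the site (0 = matrix).
#' @param J 6x6 contact-energy matrix, see [default_adhesion()].
#' @return total contact energy at the site.
#' @export
adhesion_energy_at <- function(state, col, row, occupant_id,
                               J = default_adhesion()) {
  if (col < 0 || col >= state$width || row < 0 || row >= state$height)
    stop("site out of field")
  t0 <- obj_adh_type(state$objects, occupant_id)
  e <- 0
  for (k in 1:6) {
    w <- owner_at(state, col + HEX_DC[k], row + HEX_DR[k])
    if (w != occupant_id) e <- e + J[t0, obj_adh_type(state$objects, w)]
  }
  e
}

#' Would removing a site disconnect its object?
#'
#' Checked by flood fill over the object's remaining sites. Cells must stay
#' connected: the engine adds `connectivity_penalty` to any move that
#' violates this.
#'
#' @param state a simulation state.
#' @param col,row site coordinates; the site must belong to a non-matrix
#'   object.
#' @return TRUE if the removal disconnects the remaining sites.
#' @export
connectivity_violation <- function(state, col, row) {
  engine_connectivity_violation(state, unclass(sim_params()), col, row)
}

#' Energy change of a single index change
#'
#' Computes `G_new - G_old` for re-indexing site (col, row) to
#' `candidate_id`, summing the area, perimeter and adhesion terms over the
#' two affected objects, plus the connectivity penalty when the donor would
#' fragment and the tight-junction penalty when the local TJ count would
#' change.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @param col,row site coordinates.
#' @param candidate_id id of an object occupying a neighboring site
#'   (0 = matrix).
#' @param bypass_tj skip the tight-junction integrity penalty (used by the
#'   sanctioned TJ reorganization pass).
#' @return the energy change.
#' @export
delta_G <- function(state, params, col, row, candidate_id,
                    bypass_tj = FALSE) {
  engine_delta_g(state, unclass(params), col, row, candidate_id, bypass_tj)
}

#' Metropolis acceptance rule
#'
#' Acceptance probability p = 1 for downhill moves and exp(-dG/T) otherwise;
#' the move is accepted when the uniform draw falls below p.
#'
#' @param delta_g energy change(s).
#' @param temperature acceptance temperature, > 0.
#' @param r uniform random number(s) in [0, 1).
#' @return logical (vectorized).
#' @export
accept_move <- function(delta_g, temperature, r) {
  stopifnot(temperature > 0)
  p <- ifelse(delta_g <= 0, 1, exp(-delta_g / temperature))
  r < p
}

#' Run a number of stochastic index-change attempts
#'
#' Each attempt picks a random site (within the bounding box of the
#' non-matrix region plus a two-site halo), a random neighbor direction,
#' and proposes copying the neighbor's index onto the site; the proposal is
#' accepted by [accept_move()] on [delta_G()]. Area and perimeter
#' bookkeeping is updated incrementally; moves that would fragment a cell
#' or remodel a tight junction are rejected through the energy penalty.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @param n_attempts number of proposals.
#' @return list with the mutated `state`, the number of non-trivial
#'   `proposals`, and the number `accepted`.
#' @export
potts_step <- function(state, params, n_attempts) {
  engine_potts_step(state, unclass(params), as.integer(n_attempts))
}
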