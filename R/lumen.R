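# Tight junctions and lumen maintenance. A tight junction (TJ) is a pair of
# points in two different cells, mutually adjacent and both adjacent to the
# same lumen point; on the hexagonal lattice a TJ is therefore a lattice
# triangle with one lumen corner and two corners in distinct cells. TJ
# integrity is enforced during the Potts step (moves changing the local TJ
# count are rejected); remodeling happens only in the end-of-cycle TJ pass,
# which also merges lumens whose TJs come into contact.

#' Enumerate all tight junctions on the lattice
#'
#' Lists every (pointA, pointB, lumen-site) triple meeting the definition,
#' each triangle once, in deterministic (row-major) order.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @return data.frame with the two cell points (`a_col`, `a_row`, `b_col`,
#'   `b_row`), the lumen point (`lumen_col`, `lumen_row`) and the object ids
#'   (`cell_a`, `cell_b`, `lumen`).
#' @export
detect_tight_junctions <- function(state, params = sim_params()) {
  engine_tj_triples(state, unclass(params))
}

#' Does a proposed index change alter the local tight-junction count?
#'
#' Only triangles containing the changed site can change, so the local
#' before/after comparison equals a global TJ recount comparison. When TRUE
#' the engine adds the connectivity penalty to the move's energy change.
#'
#' @param state a simulation state.
#' @param col,row site of the proposed change.
#' @param candidate_id proposed new occupant id.
#' @param params an [sim_params()] object.
#' @return TRUE if the TJ count would change.
#' @export
tj_integrity_penalty <- function(state, col, row, candidate_id,
                                 params = sim_params()) {
  engine_tj_local_change(state, unclass(params), col, row, candidate_id)
}

#' Merge two adjacent lumens
#'
#' All sites of the higher id are re-indexed to the lower id, and the
#' surviving lumen's target area is the sum of both; the source lumen is
#' removed. Errors if the lumens share no edge.
#'
#' @param state a simulation state.
#' @param lumen_a,lumen_b ids of two living, adjacent lumens.
#' @param params an [sim_params()] object.
#' @return list with the mutated `state` and the surviving id `kept`.
#' @export
merge_lumens <- function(state, lumen_a, lumen_b, params = sim_params()) {
  engine_merge_lumens(state, unclass(params), lumen_a, lumen_b)
}
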