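# Domain objects and the per-cycle point registry. The registry mirrors the
# lattice: every cycle all grid points are surveyed and listed under the
# object that owns them, after which isolated matrix points enclosed by
# objects are engulfed by the neighbor owning most of their edges.

#' Rebuild the point registry from the lattice
#'
#' @param state a simulation state.
#' @return named list mapping `"matrix"` and each object id (as character)
#'   to a data.frame of its sites (`col`, `row`); every site is listed under
#'   exactly one entry.
#' @export
rebuild_registry <- function(state) {
  ids <- sort(unique(as.vector(state$owner)))
  reg <- lapply(ids, function(id) {
    w <- which(state$owner == id, arr.ind = TRUE)
    data.frame(col = w[, 1] - 1L, row = w[, 2] - 1L)
  })
  names(reg) <- ifelse(ids == 0L, "matrix", as.character(ids))
  reg
}

#' Engulf isolated matrix points
#'
#' A matrix site whose six neighbors all belong to non-matrix objects is
#' reassigned to the neighboring object owning the most of its edges (ties
#' broken by lowest object id). Border sites are never isolated because
#' out-of-field space counts as matrix.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object (engine settings).
#' @return the mutated state.
#' @export
engulf_isolated_points <- function(state, params = sim_params()) {
  engine_engulf(state, unclass(params))$state
}

#' Consistency audit of a simulation state
#'
#' Checks the partition property (object bookkeeping equals a from-scratch
#' recount), connectivity of every object, the single-lumen-contact
#' invariant, and the absence of lumen-matrix adjacency. Errors with a
#' diagnostic on the first violation.
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @return TRUE, invisibly.
#' @export
audit_state <- function(state, params = sim_params()) {
  invisible(engine_audit(state, unclass(params)))
}
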