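# Per-cycle control flow and full-run orchestration. Each simulation cycle
# executes, in order: (1) point-registry rebuild and engulfment of isolated
# points; (2) lumen target growth and pending merges; (3) death initiation
# and dying advancement; (4) per-cell target area/perimeter, polarization
# and stabilization updates; (5) lumen creation; (6) division; (7) the
# stochastic Potts index-change step followed by end-of-cycle TJ
# reorganization. 48 cycles make one simulated day. A single R RNG stream
# drives every stochastic decision in a fixed order (phase order, then
# ascending object id), so a seed reproduces a run bit for bit.

#' Initialize a simulation
#'
#' Places a single unpolarized cell of area `wedge_area` (a compact
#' hexagonal disc) at the field center. Its cycle counter is drawn uniform
#' on `[0.75, 1.25] * cell_cycle` but is forced to 1 during cycle 1, so the
#' first division happens at cycle 2; immediately after that division both
#' cells redraw their counters uniform on
#' `[(1 - cluster_prob) * cell_cycle, cell_cycle]`, mimicking the partial
#' cell-cycle synchrony of freshly plated cell clusters.
#'
#' @param params an [sim_params()] object.
#' @return a simulation state at cycle 0.
#' @export
initialize_simulation <- function(params = sim_params()) {
  state <- empty_state(params$width, params$height)
  c0 <- params$width %/% 2
  r0 <- params$height %/% 2
  # compact disc: sites by increasing hex distance from center, fixed order
  rad <- 8
  cols <- rep((c0 - rad):(c0 + rad), times = 2 * rad + 1)
  rows <- rep((r0 - rad):(r0 + rad), each = 2 * rad + 1)
  d <- hex_distance(cols, rows, c0, r0)
  ord <- order(d, cols, rows)
  n <- round(params$wedge_area)
  sites <- data.frame(col = cols[ord][seq_len(n)],
                      row = rows[ord][seq_len(n)])
  cc <- (0.75 + 0.5 * stats::runif(1)) * params$cell_cycle
  state <- add_object(state, sites, kind = "cell",
                      cell_state = "unpolarized",
                      TA = params$wedge_area,
                      TP = target_perimeter(n, params),
                      cycle_counter = cc)
  state
}

#' Advance a simulation state by one or more cycles
#'
#' @param state a simulation state.
#' @param params an [sim_params()] object.
#' @param n_cycles number of cycles to run.
#' @param audit_level 0 = no audits, 1 = audit once at the end, 2 = audit
#'   after every cycle (partition, connectivity, single-lumen-contact and
#'   bookkeeping checks; errors on the first violation).
#' @return list with the advanced `state` and the `events` log
#'   (data.frame: cycle, id, event, x, y).
#' @export
run_cycle <- function(state, params, n_cycles = 1, audit_level = 0) {
  res <- engine_run(state, unclass(params), as.integer(n_cycles), 0L,
                    as.integer(audit_level))
  list(state = res$final, events = res$events)
}

#' Run a full simulation and record daily morphometrics
#'
#' Runs `cycles_per_day * n_days` cycles from a fresh initial state,
#' sampling [measure()] at day 0 (after initialization, before cycle 1) and
#' at the end of every simulated day.
#'
#' @param params an [sim_params()] object.
#' @param n_days number of simulated days (>= 1).
#' @param seed optional integer seed (`set.seed`) making the run fully
#'   reproducible.
#' @param audit_level see [run_cycle()].
#' @param keep_snapshots keep the day-boundary states in the result.
#' @return list with `metrics` (data.frame, one row per day 0..n_days),
#'   `events`, `final_state`, optionally `snapshots`, and the Potts
#'   `attempts`/`accepted` totals.
#' @export
run_simulation <- function(params = sim_params(), n_days = 10, seed = NULL,
                           audit_level = 0, keep_snapshots = FALSE) {
  stopifnot(n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_simulation(params)
  m0 <- measure(state)
  m0$day <- 0L
  res <- engine_run(state, unclass(params),
                    as.integer(params$cycles_per_day * n_days),
                    as.integer(params$cycles_per_day),
                    as.integer(audit_level))
  daily <- lapply(seq_along(res$snapshots), function(i) {
    m <- measure(res$snapshots[[i]], allow_empty = TRUE)
    m$day <- as.integer(res$snapshot_cycles[i] / params$cycles_per_day)
    m
  })
  metrics <- do.call(rbind, c(list(m0), daily))
  metrics <- metrics[, c("day", setdiff(names(metrics), "day"))]
  out <- list(metrics = metrics, events = res$events,
              final_state = res$final,
              attempts = res$attempts, accepted = res$accepted)
  if (keep_snapshots) out$snapshots <- res$snapshots
  out
}
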