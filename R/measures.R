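# Morphometrics of a simulated cyst cross-section: the same quantities
# measured on confocal cross-sections in vitro, computed exactly on the
# lattice. "Contact" means at least one boundary edge; the cyst is the
# union of all cells and lumens (simulations grow a single cyst).

cell_contact_table <- function(state) {
  o <- state$objects
  lum_ids <- o$id[o$kind == 1L & o$alive]
  nbins <- nrow(o)
  mat <- integer(nbins)
  lum <- integer(nbins)
  own <- state$owner
  W <- state$width; H <- state$height
  occupied <- own != 0L
  for (k in 1:6) {
    dc <- HEX_DC[k]; dr <- HEX_DR[k]
    nb <- matrix(0L, W, H)
    csrc <- max(1, 1 - dc):min(W, W - dc)
    rsrc <- max(1, 1 - dr):min(H, H - dr)
    nb[csrc, rsrc] <- own[csrc + dc, rsrc + dr]
    mat <- mat + tabulate(own[occupied & nb == 0L], nbins)
    lum <- lum + tabulate(own[occupied & matrix(nb %in% lum_ids, W, H)], nbins)
  }
  data.frame(id = o$id, matrix_edges = mat, lumen_edges = lum)
}

#' Morphometrics of one simulated cyst
#'
#' Computes, from the lattice alone: cell number; cyst area (all cell plus
#' lumen sites); lumen area; cyst perimeter (edges between the cyst and
#' matrix, out-of-field counting as matrix); mean cell area
#' `(cyst - lumen) / cells`; cellular-to-cyst ratio
#' `(cyst - lumen) / cyst`; lumen count; whether the cyst has exactly one
#' lumen; the single-layer single-lumen (SLSL) classification; and whether
#' any dying cell with / without matrix contact is present.
#'
#' @param state a simulation state with at least one living cell.
#' @param allow_empty return a zero row instead of erroring when no living
#'   cell remains (used by batch runners for rare whole-cyst extinctions).
#' @return a one-row data.frame (a `DailyMetrics` record).
#' @export
measure <- function(state, allow_empty = FALSE) {
  o <- state$objects
  cells <- o[o$kind == 0L & o$alive, ]
  lumens <- o[o$kind == 1L & o$alive, ]
  if (nrow(cells) < 1) {
    if (!allow_empty) stop("measure() needs at least one living cell")
    return(data.frame(
      cell_number = 0L, cyst_area = sum(lumens$A), lumen_area = sum(lumens$A),
      cyst_perimeter = NA_integer_, mean_cell_area = NA_real_,
      cellular_to_cyst_ratio = NA_real_, lumen_count = nrow(lumens),
      is_single_lumen = nrow(lumens) == 1L, is_slsl = FALSE,
      has_dying_matrix_contact = FALSE, has_dying_no_matrix = FALSE))
  }
  cyst_area <- sum(cells$A) + sum(lumens$A)
  lumen_area <- sum(lumens$A)
  # cyst perimeter: edges between non-matrix and matrix
  own <- state$owner
  W <- state$width; H <- state$height
  nonmat <- own != 0L
  per <- 0L
  for (k in 1:6) {
    dc <- HEX_DC[k]; dr <- HEX_DR[k]
    nb <- matrix(0L, W, H)
    csrc <- max(1, 1 - dc):min(W, W - dc)
    rsrc <- max(1, 1 - dr):min(H, H - dr)
    nb[csrc, rsrc] <- own[csrc + dc, rsrc + dr]
    per <- per + sum(nonmat & nb == 0L)
  }
  ct <- cell_contact_table(state)
  ct <- ct[ct$id %in% cells$id, ]
  slsl <- nrow(lumens) == 1L &&
    all(ct$matrix_edges >= 1L & ct$lumen_edges >= 1L)
  dying <- cells$dying
  dmat <- ct$matrix_edges[match(cells$id, ct$id)] > 0L
  data.frame(
    cell_number = nrow(cells),
    cyst_area = cyst_area,
    lumen_area = lumen_area,
    cyst_perimeter = per,
    mean_cell_area = (cyst_area - lumen_area) / nrow(cells),
    cellular_to_cyst_ratio = (cyst_area - lumen_area) / cyst_area,
    lumen_count = nrow(lumens),
    is_single_lumen = nrow(lumens) == 1L,
    is_slsl = slsl,
    has_dying_matrix_contact = any(dying & dmat),
    has_dying_no_matrix = any(dying & !dmat)
  )
}

#' Single-layer single-lumen (SLSL) classification
#'
#' TRUE iff the cyst has exactly one lumen and every living cell contacts
#' both the extracellular matrix and the lumen (>= 1 boundary edge each).
#'
#' @param state a simulation state.
#' @return logical.
#' @export
classify_slsl <- function(state) {
  measure(state)$is_slsl
}

#' Scale lattice metrics to physical units
#'
#' Areas are multiplied by `area_scale` (default 2.25 um^2 per grid point)
#' and perimeters by `perimeter_scale` (default 0.75 um per edge); derived
#' ratios and counts are unchanged.
#'
#' @param metrics a data.frame from [measure()] / [run_simulation()].
#' @param params an [sim_params()] object.
#' @return the metrics data.frame in um / um^2.
#' @export
scale_to_physical <- function(metrics, params = sim_params()) {
  out <- metrics
  for (col in intersect(c("cyst_area", "lumen_area", "mean_cell_area"),
                        names(out)))
    out[[col]] <- out[[col]] * params$area_scale
  if ("cyst_perimeter" %in% names(out))
    out$cyst_perimeter <- out$cyst_perimeter * params$perimeter_scale
  out
}

#' Per-day summaries across replicate simulations
#'
#' @param trajectories either a list of per-replicate metric data.frames
#'   (as returned in `run_simulation()$metrics`) or a single data.frame
#'   with a `replicate` column.
#' @return data.frame with one row per day: replicate count, mean, SD and
#'   coefficient of variation of each numeric metric, and the percentages
#'   of single-lumen, multi-lumen and SLSL cysts and of cysts containing
#'   dying cells with / without matrix contact.
#' @export
batch_summaries <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    traj <- trajectories
  } else {
    if (length(trajectories) < 2)
      stop("batch_summaries() needs at least two replicates")
    traj <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
      cbind(replicate = i, trajectories[[i]])
    }))
  }
  num <- c("cell_number", "cyst_area", "lumen_area", "cyst_perimeter",
           "mean_cell_area", "cellular_to_cyst_ratio", "lumen_count")
  days <- sort(unique(traj$day))
  rows <- lapply(days, function(d) {
    sub <- traj[traj$day == d, ]
    out <- data.frame(day = d, n = nrow(sub))
    for (m in num) {
      mu <- mean(sub[[m]], na.rm = TRUE)
      sdv <- stats::sd(sub[[m]], na.rm = TRUE)
      out[[paste0(m, "_mean")]] <- mu
      out[[paste0(m, "_sd")]] <- sdv
      out[[paste0(m, "_cov")]] <- if (is.finite(mu) && mu > 0) sdv / mu
                                  else NA_real_
    }
    out$pct_single_lumen <- 100 * mean(sub$lumen_count == 1, na.rm = TRUE)
    out$pct_multi_lumen <- 100 * mean(sub$lumen_count >= 2, na.rm = TRUE)
    out$pct_slsl <- 100 * mean(sub$is_slsl, na.rm = TRUE)
    out$pct_dying_matrix <- 100 * mean(sub$has_dying_matrix_contact, na.rm = TRUE)
    out$pct_dying_no_matrix <- 100 * mean(sub$has_dying_no_matrix, na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

#' Mean duration of the dying process
#'
#' Pairs each `death_start` event with the matching `death_complete` event
#' (per replicate and cell id) and averages the elapsed cycles over all
#' completed deaths.
#'
#' @param events an event log (data.frame with `cycle`, `id`, `event`),
#'   optionally with a `replicate` column when logs from several runs are
#'   concatenated.
#' @param units `"cycles"` or `"hours"` (30 minutes per cycle).
#' @param params an [sim_params()] object (for the cycle grounding).
#' @return list with `mean`, `n` (completed deaths) and the vector of
#'   `durations`.
#' @export
mean_dying_duration <- function(events, units = c("cycles", "hours"),
                                params = sim_params()) {
  units <- match.arg(units)
  if (!"replicate" %in% names(events)) events$replicate <- 1L
  st <- events[events$event == "death_start", c("replicate", "id", "cycle")]
  en <- events[events$event == "death_complete", c("replicate", "id", "cycle")]
  m <- merge(st, en, by = c("replicate", "id"), suffixes = c("_start", "_end"))
  dur <- m$cycle_end - m$cycle_start
  if (units == "hours") dur <- dur * params$minutes_per_cycle / 60
  list(mean = if (length(dur)) mean(dur) else NA_real_,
       n = length(dur), durations = dur)
}
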