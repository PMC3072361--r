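# Replicate batch runner for the preset intervention experiments, with flat
# CSV persistence. A batch is fully determined by its resolved parameter
# set, replicate count, day count and base seed; the resolved configuration
# is echoed next to the outputs so any run can be reconstructed from its
# output directory alone.

#' Run a preset experiment over replicate simulations
#'
#' Replicate `i` runs with seed `seed + i - 1`, so a batch is reproducible
#' and replicates are independent.
#'
#' @param preset an [sim_preset()], or a preset name.
#' @param replicates number of replicate simulations (the preset's default
#'   if NULL).
#' @param days simulated days per replicate (the preset's default if NULL).
#' @param seed base integer seed.
#' @param overrides named list of extra parameter overrides.
#' @param out_dir optional output directory; when given, writes
#'   `trajectories.csv`, `summary.csv`, `events.csv`, `config.json` (if the
#'   jsonlite package is available) and, with a reference, `sm_summary.csv`.
#' @param reference optional reference table
#'   (see [read_reference_series()]) for SM scoring.
#' @param audit_level see [run_cycle()].
#' @return list with `params`, `trajectories` (per-replicate daily metrics),
#'   `summary` (from [batch_summaries()]), `events` (with a `replicate`
#'   column), `seeds`, and `sm` when a reference was supplied.
#' @export
run_experiment <- function(preset = "control", replicates = NULL,
                           days = NULL, seed = 1, overrides = list(),
                           out_dir = NULL, reference = NULL,
                           audit_level = 0) {
  if (is.character(preset)) preset <- sim_preset(preset)
  if (is.null(replicates)) replicates <- preset$replicates
  if (is.null(days)) days <- preset$days
  params <- resolve_params(preset, overrides)
  seeds <- seed + seq_len(replicates) - 1L
  runs <- lapply(seq_len(replicates), function(i) {
    run_simulation(params, n_days = days, seed = seeds[i],
                   audit_level = audit_level)
  })
  traj <- do.call(rbind, lapply(seq_len(replicates), function(i) {
    cbind(replicate = i, seed = seeds[i], runs[[i]]$metrics)
  }))
  events <- do.call(rbind, lapply(seq_len(replicates), function(i) {
    ev <- runs[[i]]$events
    if (nrow(ev)) cbind(replicate = i, ev) else NULL
  }))
  if (is.null(events))
    events <- data.frame(replicate = integer(), cycle = integer(),
                         id = integer(), event = character(),
                         x = numeric(), y = numeric())
  summary <- batch_summaries(traj)
  out <- list(preset = preset$name, params = params, trajectories = traj,
              summary = summary, events = events, seeds = seeds)
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_reference_series(reference)
    out$sm <- sm_report(traj, reference)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    write_config(params, file.path(out_dir, "config.json"),
                 preset = preset$name, replicates = replicates,
                 days = days, seed = seed)
    if (!is.null(out$sm))
      utils::write.csv(out$sm$summary, file.path(out_dir, "sm_summary.csv"),
                       row.names = FALSE)
  }
  out
}

#' Write / read a resolved configuration
#'
#' The configuration is the complete parameter set plus the batch settings,
#' serialized as JSON (requires the jsonlite package). `read_config()`
#' returns a list with `params` (an `sim_params` object) and the batch
#' fields, sufficient to rerun the batch identically.
#'
#' @param params an [sim_params()] object.
#' @param path file path.
#' @param preset,replicates,days,seed batch settings to record.
#' @export
write_config <- function(params, path, preset = NA_character_,
                         replicates = NA_integer_, days = NA_integer_,
                         seed = NA_integer_) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    warning("jsonlite not available; config not written")
    return(invisible(NULL))
  }
  cfg <- list(preset = preset, replicates = replicates, days = days,
              seed = seed, params = unclass(params))
  cfg$params$adhesion <- as.data.frame(cfg$params$adhesion)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_config() requires the jsonlite package")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- as.matrix(cfg$params$adhesion)
  rownames(J) <- colnames(J)
  cfg$params$adhesion <- J
  base <- sim_params()
  p <- utils::modifyList(unclass(base), cfg$params)
  class(p) <- "sim_params"
  validate_params(p)
  list(preset = cfg$preset, replicates = cfg$replicates, days = cfg$days,
       seed = cfg$seed, params = p)
}
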