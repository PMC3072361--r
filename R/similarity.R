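# Similarity measures scoring a batch of simulated time courses against a
# reference (in vitro) time series. SM1 is the per-day fraction of
# simulated observations inside the +/-25% window around the reference
# mean; SM2 is the per-day absolute difference of coefficients of
# variation; SSM1 applies the SM1 computation to the reference's own raw
# values, quantifying its self-similarity. Verdicts follow the
# prespecified falsification thresholds.

#' The +/-25% similarity window around a reference mean
#'
#' @param mean a positive reference mean.
#' @return numeric c(low, high) = c(0.75, 1.25) * mean. Values exactly on a
#'   boundary count as inside (closed interval) throughout the package.
#' @export
window25 <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) || mean <= 0)
    stop("window25() needs a single positive mean")
  c(low = 0.75 * mean, high = 1.25 * mean)
}

check_sim_values <- function(sim_values_by_day) {
  stopifnot(is.data.frame(sim_values_by_day),
            all(c("day", "value") %in% names(sim_values_by_day)))
  sim_values_by_day
}

check_reference <- function(reference, need_sd = FALSE) {
  stopifnot(is.data.frame(reference), all(c("day", "mean") %in% names(reference)))
  if (need_sd && !"sd" %in% names(reference))
    stop("reference series must provide per-day SDs for SM2")
  if (anyDuplicated(reference$day)) stop("duplicated reference days")
  reference
}

verdict_days <- function(df) df[df$day >= 1 & df$day <= 10, , drop = FALSE]

#' Similarity Measure 1
#'
#' Per day, the fraction of simulated observations within +/-25% of the
#' reference mean. The batch survives falsification when the fraction
#' exceeds 0.5 on at least nine of days 1-10.
#'
#' @param sim_values_by_day data.frame with columns `day`, `value` (one row
#'   per replicate per day).
#' @param reference data.frame with columns `day`, `mean` (and optionally
#'   `sd`) for a single metric.
#' @return list with `per_day` (data.frame day, n, fraction) and logical
#'   `pass`.
#' @export
sm1 <- function(sim_values_by_day, reference) {
  sim <- check_sim_values(sim_values_by_day)
  ref <- check_reference(reference)
  days <- sort(unique(sim$day))
  missing_ref <- setdiff(days, ref$day)
  if (length(missing_ref))
    stop("reference has no mean for day(s) ",
         paste(missing_ref, collapse = ", "))
  per_day <- do.call(rbind, lapply(days, function(d) {
    v <- sim$value[sim$day == d]
    w <- window25(ref$mean[ref$day == d])
    data.frame(day = d, n = length(v),
               fraction = mean(v >= w[1] & v <= w[2]))
  }))
  vd <- verdict_days(per_day)
  pass <- sum(vd$fraction > 0.5) >= 9 && nrow(vd) >= 9
  list(per_day = per_day, pass = pass)
}

#' Similarity Measure 2
#'
#' Per day, the absolute difference between the simulated and reference
#' coefficients of variation (SD/mean). Verdicts: `"strong"` when
#' SM2 < 0.15 on at least nine of days 1-10, `"medium"` when SM2 < 0.25 on
#' at least eight of days 1-10, otherwise `"fail"`.
#'
#' @param sim_values_by_day data.frame with columns `day`, `value`
#'   (>= 2 replicates per day).
#' @param reference data.frame with columns `day`, `mean`, `sd`.
#' @return list with `per_day` (day, n, cov_sim, cov_ref, sm2) and
#'   `verdict`.
#' @export
sm2 <- function(sim_values_by_day, reference) {
  sim <- check_sim_values(sim_values_by_day)
  ref <- check_reference(reference, need_sd = TRUE)
  days <- sort(unique(sim$day))
  missing_ref <- setdiff(days, ref$day)
  if (length(missing_ref))
    stop("reference has no mean/sd for day(s) ",
         paste(missing_ref, collapse = ", "))
  per_day <- do.call(rbind, lapply(days, function(d) {
    v <- sim$value[sim$day == d]
    if (length(v) < 2) stop("SM2 needs >= 2 replicates per day (day ", d, ")")
    mu <- mean(v)
    if (mu == 0) stop("zero simulated mean on day ", d)
    i <- match(d, ref$day)
    if (ref$mean[i] == 0) stop("zero reference mean on day ", d)
    cov_sim <- stats::sd(v) / mu
    cov_ref <- ref$sd[i] / ref$mean[i]
    data.frame(day = d, n = length(v), cov_sim = cov_sim, cov_ref = cov_ref,
               sm2 = abs(cov_sim - cov_ref))
  }))
  vd <- verdict_days(per_day)
  verdict <- if (nrow(vd) >= 9 && sum(vd$sm2 < 0.15) >= 9) "strong"
             else if (nrow(vd) >= 8 && sum(vd$sm2 < 0.25) >= 8) "medium"
             else "fail"
  list(per_day = per_day, verdict = verdict)
}

#' Self-Similarity Measure 1
#'
#' SM1 applied to the reference's own raw per-cyst values around their own
#' per-day means: the fraction of individual reference measurements within
#' +/-25% of that day's mean.
#'
#' @param reference_raw_values_by_day data.frame with columns `day`,
#'   `value` (raw per-cyst reference measurements).
#' @return list as from [sm1()].
#' @export
ssm1 <- function(reference_raw_values_by_day) {
  raw <- check_sim_values(reference_raw_values_by_day)
  ref <- do.call(rbind, lapply(sort(unique(raw$day)), function(d) {
    data.frame(day = d, mean = mean(raw$value[raw$day == d]))
  }))
  sm1(raw, ref)
}

#' Read a reference time series from a delimited table
#'
#' Expected columns: `day`, `metric`, `mean`, `sd` (CSV). Rows for several
#' metrics can share a file.
#'
#' @param path file path.
#' @return data.frame with a `metric` column; split per metric before
#'   passing to [sm1()]/[sm2()].
#' @export
read_reference_series <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "metric", "mean", "sd")
  if (!all(need %in% names(ref)))
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  if (any(ref$sd < 0, na.rm = TRUE)) stop("reference SDs must be >= 0")
  for (m in unique(ref$metric)) {
    d <- sort(ref$day[ref$metric == m])
    if (!all(diff(d) == 1))
      stop("reference days for metric '", m, "' are not contiguous")
  }
  ref
}

#' A synthetic demonstration reference series
#'
#' Generates a smooth, entirely synthetic cyst-growth time series (it is
#' not measured data) in the shape [read_reference_series()] expects:
#' exponential-then-linear cell-number growth with a day-6 shift, monotone
#' cyst and lumen expansion, declining mean cell area and
#' cellular-to-cyst ratio, all in lattice units with 25-30% relative SDs.
#' Useful for demonstrating and testing [sm1()]/[sm2()]/[sm_report()]
#' workflows when no measured reference table is at hand. A copy ships as
#' `extdata/synthetic_reference_demo.csv`.
#'
#' @param days integer days to cover.
#' @return data.frame with columns `day`, `metric`, `mean`, `sd`.
#' @export
synthetic_reference <- function(days = 0:10) {
  cell <- ifelse(days <= 6, 1.6 * 1.45^days, 1.6 * 1.45^6 * (1 + 0.12 * (days - 6)))
  cyst <- 82 * 1.5^pmin(days, 8) * ifelse(days > 8, 1 + 0.1 * (days - 8), 1)
  ratio <- pmax(0.45, 1 - 0.09 * pmin(days, 6) - 0.01 * pmax(days - 6, 0))
  lumen <- cyst * (1 - ratio)
  mca <- (cyst - lumen) / pmax(cell, 1)
  tab <- rbind(
    data.frame(day = days, metric = "cell_number", mean = cell, sd = 0.28 * cell),
    data.frame(day = days, metric = "cyst_area", mean = cyst, sd = 0.30 * cyst),
    data.frame(day = days, metric = "lumen_area", mean = pmax(lumen, 0.5),
               sd = 0.35 * pmax(lumen, 0.5)),
    data.frame(day = days, metric = "mean_cell_area", mean = mca, sd = 0.25 * mca),
    data.frame(day = days, metric = "cellular_to_cyst_ratio", mean = ratio,
               sd = 0.12 * ratio))
  rownames(tab) <- NULL
  tab
}

#' Score a batch of simulated trajectories against a reference series
#'
#' Computes SM1 and SM2 for every metric present in both the trajectories
#' and the reference table.
#'
#' @param trajectories a data.frame of per-replicate daily metrics with
#'   columns `replicate`, `day` and metric columns, or a list of metric
#'   data.frames.
#' @param reference a reference table as from [read_reference_series()].
#' @return list with per-metric `sm1`/`sm2` results and a `summary`
#'   data.frame (metric, sm1_pass, sm2_verdict).
#' @export
sm_report <- function(trajectories, reference) {
  if (!is.data.frame(trajectories)) {
    trajectories <- do.call(rbind, lapply(seq_along(trajectories),
      function(i) cbind(replicate = i, trajectories[[i]])))
  }
  metrics <- intersect(unique(reference$metric), names(trajectories))
  if (!length(metrics))
    stop("no reference metric matches a trajectory column")
  res <- lapply(metrics, function(m) {
    ref_m <- reference[reference$metric == m, c("day", "mean", "sd")]
    sim <- data.frame(day = trajectories$day, value = trajectories[[m]])
    # verdicts cover the growth days 1-10; day 0 (plating) is excluded
    sim <- sim[sim$day %in% ref_m$day & sim$day >= 1, ]
    list(sm1 = sm1(sim, ref_m), sm2 = sm2(sim, ref_m))
  })
  names(res) <- metrics
  summary <- data.frame(
    metric = metrics,
    sm1_pass = vapply(res, function(r) r$sm1$pass, logical(1)),
    sm2_verdict = vapply(res, function(r) r$sm2$verdict, character(1)),
    row.names = NULL)
  c(res, list(summary = summary))
}
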