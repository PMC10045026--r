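# Scalar verification and comparison statistics: cycle-convergence error,
# WSF mesh-sensitivity metric, per-outlet flow distribution, relative
# perfusion changes, and cycle-averaged pressure drops.

#' Area-averaged pressure time series at a surface
#'
#' @param times uniformly spaced sample times, s.
#' @param values area-averaged pressure samples, Pa.
#' @param period cardiac cycle duration T, s; the sampling must resolve it
#'   with an integer number of steps.
#' @param label optional surface name (e.g. "I", "O13").
#' @return object of class `pressure_series` with `ns` samples per cycle.
#' @export
pressure_series <- function(times, values, period, label = "") {
  check_scalar(period, "period", positive = TRUE)
  stop_if_not(length(times) == length(values) && length(times) >= 4L,
              "need >= 4 equal-length samples")
  dt <- diff(times)
  stop_if_not(max(abs(dt - dt[1])) < 1e-9 * period, "non-uniform sampling")
  ns <- round(period / dt[1])
  stop_if_not(abs(ns * dt[1] - period) < 1e-6 * period,
              "sample spacing must divide the period")
  structure(list(times = times, values = values, period = period,
                 ns = as.integer(ns), label = label),
            class = "pressure_series")
}

#' Cycle-to-cycle convergence error of a pressure series
#'
#' Mean relative change of the surface pressure between consecutive
#' cardiac cycles,
#' \deqn{\Delta_T = \frac{1}{N_s} \sum_{l=1}^{N_s}
#'   \frac{|P(t_l) - P(t_l - T)|}{|P(t_l)|},}
#' evaluated over the `Ns` samples of one cycle. The summand is taken in
#' absolute value so oscillating transients cannot cancel. Simulations are
#' considered periodic (converged) once this drops below a few percent.
#'
#' @param series a [pressure_series()] covering at least 2 full cycles.
#' @param cycle which cycle to compare against its predecessor (2-based
#'   counting: `cycle = 2` compares cycle 2 vs 1); default the last
#'   complete cycle.
#' @param all if TRUE return the vector of errors for every complete
#'   cycle from 2 to the last.
#' @return dimensionless error(s).
#' @examples
#' tt <- seq(0, 2 * 0.96, by = 0.96 / 32)[-65]
#' ps <- pressure_series(tt, rep(1e4, length(tt)), 0.96)
#' cycle_convergence(ps)  # 0 for an exactly periodic series
#' @export
cycle_convergence <- function(series, cycle = NULL, all = FALSE) {
  stop_if_not(inherits(series, "pressure_series"), "need a pressure_series")
  ns <- series$ns
  n_cycles <- length(series$values) %/% ns
  stop_if_not(n_cycles >= 2, "series must cover at least 2 full cycles")
  one <- function(cy) {
    cur <- series$values[((cy - 1) * ns + 1):(cy * ns)]
    prev <- series$values[((cy - 2) * ns + 1):((cy - 1) * ns)]
    if (any(cur == 0))
      stop("zero pressure sample: relative error undefined", call. = FALSE)
    mean(abs(cur - prev) / abs(cur))
  }
  if (all) return(vapply(2:n_cycles, one, numeric(1)))
  if (is.null(cycle)) cycle <- n_cycles
  stop_if_not(cycle >= 2 && cycle <= n_cycles, "invalid 'cycle'")
  one(cycle)
}

#' Wall-shear-force magnitude time series on a grid
#'
#' @param times sample times over one cycle, s (uniform).
#' @param values WSF magnitudes, N.
#' @param grid grid label (e.g. "A".."F").
#' @return object of class `wsf_series`.
#' @export
wsf_series <- function(times, values, grid = "") {
  stop_if_not(length(times) == length(values) && length(times) >= 2L,
              "need >= 2 equal-length samples")
  dt <- diff(times)
  stop_if_not(max(abs(dt - dt[1])) <= 1e-9 * max(abs(dt[1]), 1e-300),
              "non-uniform sampling")
  structure(list(times = times, values = values, grid = grid),
            class = "wsf_series")
}

#' Mesh-sensitivity metric on wall shear force
#'
#' Mean absolute pointwise difference between the WSF histories of two
#' grids, normalized by the dynamic range of the reference (first) series:
#' \deqn{\Delta_{WSF} = \frac{1}{N_s} \sum_{l=1}^{N_s}
#'   \frac{|WSF_j(t_l) - WSF_m(t_l)|}{\max_l WSF_j - \min_l WSF_j}.}
#' The metric is asymmetric in its arguments; pass the finer (reference)
#' grid first when comparing grid pairs.
#'
#' @param series_j reference [wsf_series()] (provides the normalizing
#'   range).
#' @param series_m comparison [wsf_series()] on the same time base.
#' @return dimensionless sensitivity.
#' @export
mesh_sensitivity_wsf <- function(series_j, series_m) {
  stop_if_not(inherits(series_j, "wsf_series") &&
                inherits(series_m, "wsf_series"), "need two wsf_series")
  stop_if_not(length(series_j$times) == length(series_m$times) &&
                max(abs(series_j$times - series_m$times)) <=
                  1e-9 * max(abs(series_j$times), 1),
              "series must share the time base")
  rng <- max(series_j$values) - min(series_j$values)
  if (rng == 0)
    stop("flat reference series: zero range, metric undefined", call. = FALSE)
  mean(abs(series_j$values - series_m$values)) / rng
}

#' Per-outlet volume-flow distribution
#'
#' Converts per-outlet cycle volumes into percentage shares of the inlet
#' cycle volume: `share_i = 100 * V_i / V_inlet`. Negative outlet volumes
#' (net backflow at an outlet over the cycle) are accepted with a warning.
#'
#' @param outlet_volumes named numeric vector of per-outlet volumes per
#'   cycle, m^3 (names are outlet labels such as "O7").
#' @param inlet_volume inlet volume per cycle, m^3 (> 0).
#' @param geometry optional geometry label (e.g. "HA").
#' @return object of class `flow_distribution`: data.frame with columns
#'   `outlet`, `share` (%) plus attributes `geometry` and `inlet_volume`.
#' @export
flow_distribution <- function(outlet_volumes, inlet_volume, geometry = "") {
  check_scalar(inlet_volume, "inlet_volume", positive = TRUE)
  stop_if_not(!is.null(names(outlet_volumes)) &&
                all(nzchar(names(outlet_volumes))),
              "'outlet_volumes' must be a named vector")
  if (any(outlet_volumes < 0))
    warning("negative outlet volume(s): net backflow at an outlet")
  out <- data.frame(outlet = names(outlet_volumes),
                    share = 100 * unname(outlet_volumes) / inlet_volume,
                    stringsAsFactors = FALSE)
  structure(out, geometry = geometry, inlet_volume = inlet_volume,
            class = c("flow_distribution", "data.frame"))
}

#' Relative perfusion change against a baseline distribution
#'
#' Per-outlet signed percentage change of the flow share relative to a
#' baseline (healthy) distribution, with the reduction-positive sign
#' convention:
#' `change_i = 100 * (1 - share_i / baseline_i)`, so +66 means the outlet
#' receives 66% less of the inlet flow than at baseline and negative
#' values are increases. For reporting, changes are also rounded
#' half-away-from-zero to integers; the unrounded value is retained.
#'
#' @param dist a [flow_distribution()].
#' @param baseline the reference [flow_distribution()]; outlets missing
#'   from it (or with non-positive baseline share) are skipped with a
#'   warning.
#' @return data.frame with columns `outlet`, `share`, `baseline`, `change`
#'   (%), `change_rounded`.
#' @examples
#' ha  <- flow_distribution(c(O7 = 9.7e-6, O8 = 11.4e-6), 1e-4, "HA")
#' fpa <- flow_distribution(c(O7 = 3.3e-6, O8 = 6.4e-6), 1e-4, "FPA")
#' relative_change(fpa, ha)
#' @export
relative_change <- function(dist, baseline) {
  stop_if_not(inherits(dist, "flow_distribution") &&
                inherits(baseline, "flow_distribution"),
              "need two flow_distribution objects")
  bmap <- stats::setNames(baseline$share, baseline$outlet)
  keep <- dist$outlet %in% names(bmap) & bmap[dist$outlet] > 0
  keep[is.na(keep)] <- FALSE
  if (any(!keep))
    warning(sprintf("skipping outlet(s) missing from baseline or with non-positive baseline share: %s",
                    paste(dist$outlet[!keep], collapse = ", ")))
  d <- dist[keep, , drop = FALSE]
  b <- unname(bmap[d$outlet])
  change <- 100 * (1 - d$share / b)
  data.frame(outlet = d$outlet, share = d$share, baseline = b,
             change = change,
             change_rounded = round_half_away(change),
             stringsAsFactors = FALSE)
}

# round half away from zero (report convention; base round() is half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cycle-averaged pressure drop between two surfaces
#'
#' `<P_in - P_out>` over one cycle on a shared uniform time base,
#' converted to mmHg (1 mmHg = 133.322 Pa).
#'
#' @param series_in,series_out [pressure_series()] objects on identical
#'   time grids.
#' @return pressure drop in mmHg.
#' @export
mean_pressure_drop <- function(series_in, series_out) {
  stop_if_not(inherits(series_in, "pressure_series") &&
                inherits(series_out, "pressure_series"),
              "need two pressure_series")
  if (length(series_in$times) != length(series_out$times) ||
      max(abs(series_in$times - series_out$times)) >
        1e-9 * max(abs(series_in$times), 1))
    stop("mismatched time bases", call. = FALSE)
  pa_to_mmhg(mean(series_in$values - series_out$values))
}

#' Published per-branch volume-flow distribution table
#'
#' Loads the packaged fixture with the per-outlet volume-flow shares (% of
#' inlet flow) for the four reference aortic geometries: healthy aorta
#' (HA), fully perfused dissection (FPA), partially thrombosed dissection
#' (PTA), and fully thrombosed dissection (FTA), across outlets O1-O16.
#' Absent branches are NA.
#'
#' @return data.frame with `geometry` plus columns `O1`..`O16`.
#' @seealso [flow_distribution_from_table()]
#' @export
branch_flow_table <- function() {
  path <- system.file("extdata", "branch_flow_distribution.csv",
                      package = "aortaflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Turn one row of a share table into a flow_distribution
#'
#' Shares are percentages of the inlet flow, so they are loaded against a
#' nominal unit inlet volume.
#'
#' @param table a data.frame as returned by [branch_flow_table()].
#' @param geometry row label to extract ("HA", "FPA", "PTA" or "FTA").
#' @return a [flow_distribution()] (absent branches dropped).
#' @export
flow_distribution_from_table <- function(table, geometry) {
  row <- table[table$geometry == geometry, , drop = FALSE]
  stop_if_not(nrow(row) == 1, sprintf("geometry '%s' not in table", geometry))
  shares <- unlist(row[, names(row) != "geometry", drop = FALSE])
  shares <- shares[!is.na(shares)]
  # shares are % of inlet: volumes relative to a unit inlet volume
  flow_distribution(shares / 100, 1, geometry = geometry)
}
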