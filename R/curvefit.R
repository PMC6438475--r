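#' Fit a pass-through spline to one cytokine series
#'
#' Fits a natural cubic interpolating spline through the sampled
#' concentrations and resamples it on a uniform minute grid spanning exactly
#' \[first sample time, last sample time\] — no extrapolation. With the default
#' `smoothing_parameter = 1` the fitted curve reproduces every observation
#' (pass-through); values < 1 switch to a penalized smoothing spline with
#' roughness weight `(1 - p) / p`, provided for sensitivity analysis only.
#' Negative undershoot between samples is clipped to zero on the resampled
#' grid, since concentrations are physical quantities; clipping is recorded in
#' the result.
#'
#' @param series Data frame with columns `time_min` and `conc_pg_ml` (a single
#'   animal x cytokine series; extra identifier columns are carried along).
#' @param config An [analysis_config()].
#' @return A `cyto_curve`: list with `grid` (minutes), `values` (pg/mL),
#'   `clipped` (any negative values clipped?), `has_saturated` (source series
#'   contained saturated points?), and the source identifiers.
#' @examples
#' s <- tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
#'                     conc_pg_ml = c(0, 0, 100, 40, 10))
#' crv <- fit_curve(s)
#' curve_at(crv, 30) # == 100, pass-through
#' @export
fit_curve <- function(series, config = analysis_config()) {
  stopifnot(inherits(config, "cyto_config"))
  if (!all(c("time_min", "conc_pg_ml") %in% names(series))) {
    abort("series needs columns time_min and conc_pg_ml")
  }
  t <- as.numeric(series$time_min)
  y <- as.numeric(series$conc_pg_ml)
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (length(t) < 4) abort("need at least 4 points to fit a curve")
  if (anyDuplicated(t)) abort("duplicate sample times in series")

  step <- config$resample_step
  grid <- seq(t[1], t[length(t)], by = step)
  # the grid always includes the last sample exactly; the final step may be short
  if (tail(grid, 1) < t[length(t)]) grid <- c(grid, t[length(t)])

  p <- config$smoothing_parameter
  if (p >= 1) {
    f <- splinefun(t, y, method = "natural")
    vals <- f(grid)
  } else {
    fit <- stats::smooth.spline(t, y, lambda = (1 - p) / p, all.knots = TRUE,
                                keep.data = FALSE)
    vals <- stats::predict(fit, grid)$y
  }
  clipped <- any(vals < 0)
  vals <- pmax(vals, 0)

  structure(
    list(
      grid = grid,
      values = vals,
      animal_id = if ("animal_id" %in% names(series)) series$animal_id[1] else NA_character_,
      subgroup = if ("subgroup" %in% names(series)) series$subgroup[1] else NA_character_,
      cytokine = if ("cytokine" %in% names(series)) series$cytokine[1] else NA_character_,
      clipped = clipped,
      has_saturated = "flag" %in% names(series) && any(series$flag == "saturated"),
      sample_times = t,
      sample_values = y
    ),
    class = "cyto_curve"
  )
}

#' Evaluate a fitted curve at a time point
#'
#' Returns the value at the grid point nearest `t`; the grid is dense enough
#' (default 1-min) that this is within one resample step of the exact spline.
#' Evaluation outside the curve's domain is an error — the fit never
#' extrapolates.
#'
#' @param curve A `cyto_curve`.
#' @param t Time in minutes, inside `[min(grid), max(grid)]`.
#' @return Concentration in pg/mL (vectorized over `t`).
#' @export
curve_at <- function(curve, t) {
  stopifnot(inherits(curve, "cyto_curve"))
  lo <- curve$grid[1]; hi <- tail(curve$grid, 1)
  eps <- 1e-8 * max(1, abs(hi))
  if (any(t < lo - eps | t > hi + eps)) {
    abort(sprintf("t outside curve domain [%g, %g]; no extrapolation", lo, hi))
  }
  idx <- vapply(t, function(ti) which.min(abs(curve$grid - ti)), integer(1))
  curve$values[idx]
}

#' Convert a fitted curve to a tibble
#'
#' @param x A `cyto_curve`.
#' @param ... Unused.
#' @return Tibble with `time_min` and `value_pg_ml` plus source identifiers.
#' @export
as_tibble.cyto_curve <- function(x, ...) {
  tibble::tibble(
    animal_id = x$animal_id, subgroup = x$subgroup, cytokine = x$cytokine,
    time_min = x$grid, value_pg_ml = x$values
  )
}

#' @export
print.cyto_curve <- function(x, ...) {
  cat(sprintf("<cyto_curve> %s / %s: %d grid points on [%g, %g] min%s\n",
              x$animal_id, x$cytokine, length(x$grid), x$grid[1],
              tail(x$grid, 1),
              if (x$clipped) " (negative undershoot clipped)" else ""))
  invisible(x)
}

#' Fit curves for every series in a cohort
#'
#' @param cohort A `cyto_cohort`.
#' @param config An [analysis_config()].
#' @return `cohort_series(cohort)` with an added list-column `curve` of
#'   `cyto_curve` objects.
#' @export
fit_cohort <- function(cohort, config = analysis_config()) {
  ser <- cohort_series(cohort)
  ser$curve <- purrr::pmap(
    list(ser$data, ser$animal_id, ser$subgroup, ser$cytokine),
    function(d, a, g, c) {
      d$animal_id <- a; d$subgroup <- g; d$cytokine <- c
      fit_curve(d, config)
    }
  )
  ser
}
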