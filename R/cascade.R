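# Baseline used for correction: mean of fitted values at pre-injection times.
curve_baseline <- function(curve, config) {
  if (config$baseline_mode != "subtract_baseline") return(0)
  pre <- curve$grid < 0
  if (!any(pre)) return(0)
  mean(curve$values[pre])
}

# Indices of interior local maxima; a plateau counts once, at its first index.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    left_ok <- j > 1 && r$values[j - 1] < r$values[j]
    right_ok <- j < k && r$values[j + 1] < r$values[j]
    if (left_ok && right_ok) out <- c(out, starts[j])
  }
  out
}

# Topographic prominence of the peak at index i: height minus the higher of
# the two valley floors separating it from taller terrain (or the ends).
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i == 1) h else {
    seg <- v[seq_len(i - 1)]
    higher <- which(seg > h)
    lo <- if (length(higher)) max(higher) + 1 else 1
    min(v[lo:i])
  }
  right <- if (i == length(v)) h else {
    seg <- v[(i + 1):length(v)]
    higher <- which(seg > h)
    hi <- if (length(higher)) i + min(higher) - 1 else length(v)
    min(v[i:hi])
  }
  h - max(left, right)
}

no_elevation <- function(curve) {
  abort(
    sprintf("no elevation above baseline for %s / %s",
            curve$animal_id %||% "?", curve$cytokine %||% "?"),
    class = "cyto_no_elevation"
  )
}

#' Locate the (first) peak of a fitted cytokine curve
#'
#' Works on the baseline-corrected curve (baseline = mean of pre-injection
#' fitted values under the default `subtract_baseline` mode, zero under
#' `"raw"`). Candidate peaks are interior local maxima whose topographic
#' prominence is at least `prominence_fraction` of the corrected curve's
#' global range, so assay jitter does not register as a peak; the *earliest*
#' candidate is the peak, implementing the first-peak rule. When no candidate
#' exists and the curve is still rising at its last sample (the last value is
#' the running maximum), the last recorded concentration is used as the
#' effective peak, as for late-rising cytokines that have not yet peaked
#' within the observation window.
#'
#' @param curve A `cyto_curve` from [fit_curve()].
#' @param config An [analysis_config()].
#' @return List with `t_peak` (min), `peak_amp` (pg/mL above baseline),
#'   `effective_peak_is_last` (logical), `baseline` (pg/mL).
#'   Signals a condition of class `cyto_no_elevation` when the corrected curve
#'   never rises above baseline (`peak_amp <= 0`); such series are excluded
#'   from alignment and counted, reducing n.
#' @export
detect_peak <- function(curve, config = analysis_config()) {
  stopifnot(inherits(curve, "cyto_curve"))
  base <- curve_baseline(curve, config)
  v <- curve$values - base
  rng <- max(v) - min(v)
  if (max(v) <= 0 || rng <= 0) no_elevation(curve)

  cand <- local_maxima(v)
  if (length(cand) > 0) {
    prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
    cand <- cand[prom >= config$prominence_fraction * rng]
  }
  n <- length(v)
  if (length(cand) > 0) {
    i <- min(cand) # earliest qualifying peak
    eff_last <- FALSE
  } else if (v[n] >= max(v)) {
    i <- n # still rising: effective peak = last recorded concentration
    eff_last <- TRUE
  } else {
    i <- which.max(v)[1] # decaying from the start: global max (left-censored rise)
    eff_last <- FALSE
  }
  amp <- v[i]
  if (amp <= 0) no_elevation(curve)
  # noise-floor criterion: a calculable elevation must rise clear of baseline
  if (base > 0 && amp < config$min_elevation_ratio * base) no_elevation(curve)
  list(t_peak = curve$grid[i], peak_amp = amp,
       effective_peak_is_last = eff_last, baseline = base)
}

#' Find the elevation starting point of a fitted curve
#'
#' The starting point (onset) is the earliest grid time at which the
#' baseline-corrected curve reaches `onset_fraction` (default 5%) of its peak
#' above-baseline amplitude *and stays at or above that threshold until the
#' peak* (sustained-crossing rule; on noise-free curves this coincides with
#' the first touch). Onsets are reported at the grid resolution with ties
#' broken toward earlier time. If the curve already exceeds the threshold at
#' its first grid point the onset is left-censored at that point and flagged.
#'
#' @param curve A `cyto_curve`.
#' @param peak Peak description from [detect_peak()] (computed if omitted).
#' @inheritParams detect_peak
#' @return A `cyto_onset`: list with `baseline`, `t_peak`, `peak_amp`,
#'   `effective_peak_is_last`, `threshold_value` (= onset_fraction x peak_amp),
#'   `t_onset`, `left_censored`, plus the source identifiers.
#' @examples
#' tri <- tibble::tibble(time_min = c(-30, 0, 100, 200, 300),
#'                       conc_pg_ml = c(0, 0, 0, 100, 0))
#' crv <- fit_curve(tri)
#' @export
detect_onset <- function(curve, peak = NULL, config = analysis_config()) {
  stopifnot(inherits(curve, "cyto_curve"))
  if (is.null(peak)) peak <- detect_peak(curve, config)
  stopifnot(peak$peak_amp > 0)
  thr <- config$onset_fraction * peak$peak_amp
  v <- curve$values - peak$baseline
  ip <- which.min(abs(curve$grid - peak$t_peak))
  below <- which(v[seq_len(ip)] < thr)
  if (length(below) == 0) {
    i_on <- 1L
    censored <- TRUE
  } else {
    i_on <- max(below) + 1L # first index from which the curve stays >= threshold
    censored <- FALSE
    if (i_on > ip) i_on <- ip # degenerate: only the peak itself reaches threshold
  }
  structure(
    list(
      animal_id = curve$animal_id, subgroup = curve$subgroup,
      cytokine = curve$cytokine,
      baseline = peak$baseline, t_peak = peak$t_peak, peak_amp = peak$peak_amp,
      effective_peak_is_last = peak$effective_peak_is_last,
      threshold_value = thr, t_onset = curve$grid[i_on],
      left_censored = censored,
      has_saturated = isTRUE(curve$has_saturated)
    ),
    class = "cyto_onset"
  )
}

#' @export
print.cyto_onset <- function(x, ...) {
  cat(sprintf(
    "<cyto_onset> %s / %s: onset %g min, peak %g pg/mL above baseline at %g min%s%s\n",
    x$animal_id, x$cytokine, x$t_onset, signif(x$peak_amp, 4), x$t_peak,
    if (x$effective_peak_is_last) " (effective peak = last sample)" else "",
    if (x$left_censored) " [left-censored onset]" else ""))
  invisible(x)
}

#' Effective area under an aligned curve
#'
#' Trapezoidal integral of the zero-clipped, baseline-corrected curve over the
#' common post-onset window \[0, D\], in pg.min/mL.
#'
#' @param curve Data frame with columns `time_min` (aligned, onset = 0) and
#'   `value_pg_ml` (baseline-corrected), spanning `[0, D]`.
#' @param D Common duration in minutes (> 0).
#' @return AUC in pg.min/mL (non-negative).
#' @export
compute_auc <- function(curve, D) {
  if (!is.numeric(D) || length(D) != 1 || D <= 0) abort("D must be a positive duration")
  t <- curve$time_min
  v <- pmax(curve$value_pg_ml, 0)
  eps <- 1e-8 * max(1, D)
  if (min(t) > 0 + eps || max(t) < D - eps) {
    abort(sprintf("aligned curve must span [0, %g]", D))
  }
  keep <- t >= -eps & t <= D + eps
  pracma::trapz(t[keep], v[keep])
}

#' Align fitted curves at their onsets and quantify them
#'
#' Re-indexes each member curve to t' = t - t_onset so that time zero is the
#' 5%-of-peak starting point, truncates all members to the common duration
#' D = min(t_last - t_onset) — the last aligned time at which every member is
#' still recorded — and computes each member's effective AUC on \[0, D\].
#' Member curves are baseline-corrected and zero-clipped before integration.
#' AUCs of members whose source series contained saturated readings are
#' flagged as lower bounds.
#'
#' @param members Tibble (or list) pairing fitted curves with their onsets:
#'   either a tibble with list-columns `curve` and `onset`, or a list of
#'   `list(curve =, onset =)` pairs.
#' @param config An [analysis_config()].
#' @return A `cyto_aligned`: tibble with one row per member (`animal_id`,
#'   `subgroup`, `cytokine`, `t_onset`, `auc_pg_min_ml`, `auc_lower_bound`,
#'   list-column `aligned` holding the aligned curve on the common grid), with
#'   attribute `common_duration` = D.
#' @export
align_set <- function(members, config = analysis_config()) {
  if (is.data.frame(members)) {
    pairs <- purrr::map2(members$curve, members$onset, ~list(curve = .x, onset = .y))
  } else {
    pairs <- members
  }
  if (length(pairs) == 0) abort("align_set needs at least one member")
  step <- config$resample_step

  spans <- vapply(pairs, function(p) tail(p$curve$grid, 1) - p$onset$t_onset,
                  numeric(1))
  D <- min(spans)
  if (D <= 0) abort("a member has zero post-onset duration; cannot align")
  common <- seq(0, D, by = step)
  if (tail(common, 1) < D) common <- c(common, D)

  rows <- purrr::map(pairs, function(p) {
    crv <- p$curve; on <- p$onset
    shifted <- crv$grid - on$t_onset
    corrected <- crv$values - on$baseline
    vals <- stats::approx(shifted, corrected, xout = common, rule = 1)$y
    aligned <- tibble::tibble(time_min = common, value_pg_ml = vals)
    tibble::tibble(
      animal_id = on$animal_id, subgroup = on$subgroup, cytokine = on$cytokine,
      t_onset = on$t_onset,
      auc_pg_min_ml = compute_auc(aligned, D),
      auc_lower_bound = isTRUE(on$has_saturated),
      aligned = list(aligned)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "common_duration") <- D
  class(out) <- c("cyto_aligned", class(out))
  out
}

#' @export
print.cyto_aligned <- function(x, ...) {
  cat(sprintf("<cyto_aligned> %d curves, common duration %g min\n",
              nrow(x), attr(x, "common_duration")))
  NextMethod()
}

#' Per-series onset results for a whole cohort
#'
#' Runs fit -> peak -> onset on every (animal, cytokine) series. Series with
#' no elevation above baseline are kept in the table with `elevated = FALSE`
#' and NA landmarks, mirroring the reduced-n bookkeeping of sparse responders.
#'
#' @param cohort A `cyto_cohort`.
#' @param config An [analysis_config()].
#' @return Tibble with one row per series: identifiers, `elevated`, `t_onset`,
#'   `t_peak`, `peak_amp`, `baseline`, `threshold_value`,
#'   `effective_peak_is_last`, `left_censored`, and list-columns `curve`,
#'   `onset` for downstream alignment.
#' @export
cohort_onsets <- function(cohort, config = analysis_config()) {
  fitted <- fit_cohort(cohort, config)
  res <- purrr::map(fitted$curve, function(crv) {
    tryCatch({
      on <- detect_onset(crv, config = config)
      list(ok = TRUE, onset = on)
    }, cyto_no_elevation = function(e) list(ok = FALSE, onset = NULL))
  })
  fitted$elevated <- vapply(res, `[[`, logical(1), "ok")
  fitted$onset <- purrr::map(res, "onset")
  num <- function(field) vapply(res, function(r)
    if (r$ok) r$onset[[field]] else NA_real_, numeric(1))
  lgl <- function(field) vapply(res, function(r)
    if (r$ok) isTRUE(r$onset[[field]]) else NA, logical(1))
  fitted$t_onset <- num("t_onset")
  fitted$t_peak <- num("t_peak")
  fitted$peak_amp <- num("peak_amp")
  fitted$baseline <- num("baseline")
  fitted$threshold_value <- num("threshold_value")
  fitted$effective_peak_is_last <- lgl("effective_peak_is_last")
  fitted$left_censored <- lgl("left_censored")
  fitted
}

#' Per-cytokine onset summary table
#'
#' Summarizes elevation starting points across animals: mean, SD,
#' s.e.m. = SD/sqrt(n), and n over the series with a detected elevation
#' (non-responders reduce n), ordered by mean onset — the cascade order.
#'
#' @param cohort A `cyto_cohort`.
#' @param config An [analysis_config()].
#' @return Tibble with `cytokine`, `n`, `mean_onset_min`, `sd_onset_min`,
#'   `sem_onset_min`, `n_no_elevation`, `n_left_censored`, sorted by mean
#'   onset.
#' @export
onset_table <- function(cohort, config = analysis_config()) {
  onsets <- cohort_onsets(cohort, config)
  onsets |>
    dplyr::group_by(.data$cytokine) |>
    dplyr::summarise(
      n = sum(.data$elevated),
      mean_onset_min = mean(.data$t_onset[.data$elevated]),
      sd_onset_min = sd(.data$t_onset[.data$elevated]),
      sem_onset_min = .data$sd_onset_min / sqrt(.data$n),
      n_no_elevation = sum(!.data$elevated),
      n_left_censored = sum(.data$left_censored %in% TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_onset_min)
}
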