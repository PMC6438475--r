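# Shared fixtures: hand-built curves, piecewise-linear oracles, small cohorts.

# Construct a cyto_curve directly from breakpoints, linearly interpolated on a
# 1-min grid: lets the peak/onset/AUC logic be tested on analytically known
# shapes, independent of the spline stage.
make_curve <- function(break_t, break_v, animal_id = "A1", cytokine = "TNF-a",
                       subgroup = "SubD-Sham", step = 1) {
  grid <- seq(min(break_t), max(break_t), by = step)
  vals <- stats::approx(break_t, break_v, xout = grid)$y
  structure(
    list(grid = grid, values = pmax(vals, 0), animal_id = animal_id,
         subgroup = subgroup, cytokine = cytokine, clipped = any(vals < 0),
         has_saturated = FALSE, sample_times = break_t, sample_values = break_v),
    class = "cyto_curve"
  )
}

# Analytic 5%-crossing for a piecewise-linear pulse rising from zero:
# first time the line from (t_lo, v_lo) to (t_hi, v_hi) reaches `thr`.
lin_crossing <- function(t_lo, v_lo, t_hi, v_hi, thr) {
  t_lo + (thr - v_lo) * (t_hi - t_lo) / (v_hi - v_lo)
}

# A small, fully valid hand-written cohort: 2 animals x 2 cytokines x 12 rows.
toy_cohort_df <- function() {
  sched <- default_schedule()
  rows <- list()
  for (a in c("r1", "r2")) {
    for (cy in c("IL-10", "TNF-a")) {
      peak_t <- if (cy == "IL-10") 90 else 150
      conc <- 20 + 500 * exp(-((sched - peak_t) / 60)^2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        animal_id = a, subgroup = "SubD-Sham", cytokine = cy,
        time_min = sched, conc_pg_ml = round(conc, 3), flag = "ok")
    }
  }
  dplyr::bind_rows(rows)
}

# Random single-pulse series on the default schedule (for property tests).
random_pulse_series <- function(onset, amp = 1000, rise = 80, decay = 160,
                                floor = 20, sched = default_schedule()) {
  k_decay <- rise / decay
  vals <- floor + amp * pulse_asym((sched - onset + 0.26 * rise) / rise, k_decay)
  tibble::tibble(time_min = sched, conc_pg_ml = vals)
}
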