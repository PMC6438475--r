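test_that("peak detection finds the first prominent peak (analytic shapes)", {
  cfg <- analysis_config()
  tri <- make_curve(c(-30, 100, 200, 300), c(0, 0, 100, 0))
  pk <- detect_peak(tri, cfg)
  expect_equal(pk$t_peak, 200)
  expect_equal(pk$peak_amp, 100)
  expect_false(pk$effective_peak_is_last)
  expect_equal(pk$baseline, 0)

  # still rising at the last sample: effective peak = last recorded value
  rise <- make_curve(c(-30, 150, 300), c(0, 0, 60))
  pk2 <- detect_peak(rise, cfg)
  expect_equal(pk2$t_peak, 300)
  expect_equal(pk2$peak_amp, 60)
  expect_true(pk2$effective_peak_is_last)

  # flat series never elevates
  flat <- make_curve(c(-30, 0, 150, 300), c(2, 2, 2, 2))
  expect_error(detect_peak(flat, cfg), class = "cyto_no_elevation")

  # two peaks: the earlier prominent one wins even though the later is higher
  two <- make_curve(c(-30, 0, 100, 120, 180, 250, 300), c(0, 0, 0, 80, 20, 100, 0))
  pk3 <- detect_peak(two, cfg)
  expect_equal(pk3$t_peak, 120)
  expect_equal(pk3$peak_amp, 80)
})

test_that("small bumps below the prominence floor are not peaks", {
  # 10% bump then the real pulse: first-peak rule must skip the bump
  bumpy <- make_curve(c(-30, 0, 30, 60, 90, 200, 300),
                      c(0, 0, 10, 0, 0, 100, 0))
  pk <- detect_peak(bumpy, analysis_config())
  expect_equal(pk$t_peak, 200)
  pk_loose <- detect_peak(bumpy, analysis_config(prominence_fraction = 0.05))
  expect_equal(pk_loose$t_peak, 30)
})

test_that("baseline correction and the noise-floor criterion gate elevations", {
  # baseline 50, peak 80: amplitude 30 < 1 x baseline -> not a calculable elevation
  weak <- make_curve(c(-30, 0, 100, 200, 300), c(50, 50, 50, 80, 50))
  expect_error(detect_peak(weak, analysis_config()), class = "cyto_no_elevation")
  pk <- detect_peak(weak, analysis_config(min_elevation_ratio = 0))
  expect_equal(pk$peak_amp, 30)
  expect_equal(pk$baseline, 50)
})

test_that("onset is the sustained 5%-of-peak crossing, grid-rounded up", {
  cfg <- analysis_config()
  tri <- make_curve(c(-30, 100, 200, 300), c(0, 0, 100, 0))
  on <- detect_onset(tri, config = cfg)
  expect_equal(on$threshold_value, 5)
  expect_equal(on$t_onset, 105) # 1 pg/mL/min rise from t = 100
  expect_false(on$left_censored)

  rise <- make_curve(c(-30, 150, 300), c(0, 0, 60))
  on2 <- detect_onset(rise, config = cfg)
  expect_equal(on2$threshold_value, 3)
  expect_equal(on2$t_onset, 158) # 0.4/min crossing at 157.5, next grid minute

  two <- make_curve(c(-30, 0, 100, 120, 180, 250, 300), c(0, 0, 0, 80, 20, 100, 0))
  on3 <- detect_onset(two, config = cfg)
  expect_equal(on3$threshold_value, 4)
  expect_equal(on3$t_onset, 101) # 4/min rise from t = 100

  # curve already above threshold at its first grid point: left-censored
  high <- make_curve(c(-30, 0, 100, 300), c(50, 80, 100, 0))
  on4 <- detect_onset(high, config = analysis_config(baseline_mode = "raw"))
  expect_true(on4$left_censored)
  expect_equal(on4$t_onset, -30)
})

test_that("grid onset equals the analytic crossing on piecewise-linear pulses", {
  set.seed(99)
  cfg <- analysis_config()
  for (i in 1:25) {
    t_r <- sample(40:200, 1)          # foot of the rise
    t_p <- t_r + sample(20:80, 1)     # peak time
    amp <- runif(1, 50, 5000)
    crv <- make_curve(c(-30, t_r, t_p, 300), c(0, 0, amp, 0))
    on <- detect_onset(crv, config = cfg)
    analytic <- lin_crossing(t_r, 0, t_p, amp, 0.05 * amp)
    expect_equal(on$t_onset, ceiling(analytic - 1e-9))
  }
})

test_that("onset time never decreases as the onset fraction grows", {
  set.seed(11)
  fracs <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  for (i in 1:10) {
    s <- random_pulse_series(onset = runif(1, 60, 200),
                             amp = runif(1, 100, 5000))
    crv <- fit_curve(s)
    onsets <- vapply(fracs, function(f)
      detect_onset(crv, config = analysis_config(onset_fraction = f))$t_onset,
      numeric(1))
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("effective AUC matches closed forms", {
  const <- tibble::tibble(time_min = 0:100, value_pg_ml = 10)
  expect_equal(compute_auc(const, 100), 1000)

  lin <- tibble::tibble(time_min = 0:100, value_pg_ml = 0:100)
  expect_equal(compute_auc(lin, 100), 5000)

  tsin <- tibble::tibble(time_min = 0:200,
                         value_pg_ml = 100 * sin(pi * (0:200) / 200))
  expect_lt(abs(compute_auc(tsin, 200) - 40000 / pi) / (40000 / pi), 0.001)

  expect_error(compute_auc(const, 0), "positive duration")
  expect_error(compute_auc(const, 150), "span")
  # negative excursions are clipped before integration
  dipped <- tibble::tibble(time_min = 0:100, value_pg_ml = rep(c(-5, 10), length.out = 101))
  expect_gte(compute_auc(dipped, 100), 0)
})

test_that("alignment is shift-invariant and truncates to the common duration", {
  cfg <- analysis_config()
  base_breaks <- c(-30, 100, 200, 300)
  vals <- c(0, 0, 100, 0)
  a <- make_curve(base_breaks, vals, animal_id = "a")
  b <- make_curve(base_breaks + 37, vals, animal_id = "b")
  on_a <- detect_onset(a, config = cfg)
  on_b <- detect_onset(b, config = cfg)
  expect_equal(on_b$t_onset - on_a$t_onset, 37)
  expect_equal(on_b$peak_amp, on_a$peak_amp)

  aset <- align_set(list(list(curve = a, onset = on_a),
                         list(curve = b, onset = on_b)), cfg)
  expect_equal(attr(aset, "common_duration"), 300 - 105)
  expect_equal(aset$aligned[[1]]$value_pg_ml, aset$aligned[[2]]$value_pg_ml,
               tolerance = 1e-9)
  expect_equal(aset$auc_pg_min_ml[1], aset$auc_pg_min_ml[2], tolerance = 1e-9)

  # D = min over members of (t_last - t_onset)
  c_short <- make_curve(c(-30, 60, 160, 260), c(0, 0, 100, 0), animal_id = "c")
  on_c <- detect_onset(c_short, config = cfg) # onset 65, span 195
  aset2 <- align_set(list(list(curve = a, onset = on_a),
                          list(curve = c_short, onset = on_c)), cfg)
  expect_equal(attr(aset2, "common_duration"), 195)

  single <- align_set(list(list(curve = a, onset = on_a)), cfg)
  expect_equal(attr(single, "common_duration"), 195)
  expect_error(align_set(list(), cfg), "at least one")
})

test_that("cascade statistics are scale-equivariant, times scale-invariant", {
  cfg <- analysis_config()
  s <- random_pulse_series(onset = 120, amp = 800)
  s2 <- dplyr::mutate(s, conc_pg_ml = conc_pg_ml * 2.5)
  on1 <- detect_onset(fit_curve(s), config = cfg)
  on2 <- detect_onset(fit_curve(s2), config = cfg)
  expect_equal(on2$t_onset, on1$t_onset)
  expect_equal(on2$peak_amp, 2.5 * on1$peak_amp)
  expect_equal(on2$threshold_value, 2.5 * on1$threshold_value)
  a1 <- align_set(list(list(curve = fit_curve(s), onset = on1)), cfg)
  a2 <- align_set(list(list(curve = fit_curve(s2), onset = on2)), cfg)
  expect_equal(a2$auc_pg_min_ml, 2.5 * a1$auc_pg_min_ml, tolerance = 1e-9)
})

test_that("onset_table aggregates per cytokine with reduced n for non-responders", {
  sched <- default_schedule()
  mk <- function(id, onset_t, amp) {
    v <- stats::approx(c(-30, onset_t, onset_t + 90, 300), c(0, 0, amp, 0),
                       xout = sched)$y
    tibble::tibble(animal_id = id, subgroup = "g", cytokine = "TNF-a",
                   time_min = sched, conc_pg_ml = v, flag = "ok")
  }
  flat <- tibble::tibble(animal_id = "r3", subgroup = "g", cytokine = "TNF-a",
                         time_min = sched, conc_pg_ml = 5, flag = "ok")
  cohort <- as_cohort(dplyr::bind_rows(mk("r1", 60, 500), mk("r2", 120, 800), flat))
  per <- cohort_onsets(cohort)
  expect_equal(sum(per$elevated), 2)
  tab <- onset_table(cohort)
  expect_equal(tab$n, 2)
  expect_equal(tab$n_no_elevation, 1)
  kept <- per$t_onset[per$elevated]
  expect_equal(tab$mean_onset_min, mean(kept))
  expect_equal(tab$sd_onset_min, sd(kept))
  expect_equal(tab$sem_onset_min, sd(kept) / sqrt(2))
})
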