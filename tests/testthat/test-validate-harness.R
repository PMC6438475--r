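test_that("offset subsampling reproduces the staggered 30-min subset scheme", {
  dense <- tibble::tibble(time_min = seq(50, 230, by = 10),
                          conc_pg_ml = seq_along(seq(50, 230, by = 10)))
  subs <- subsample_offsets(dense, interval = 30, offsets = c(60, 70, 50))
  expect_equal(subs$offset_60$time_min, seq(60, 210, by = 30))
  expect_equal(subs$offset_70$time_min, seq(70, 220, by = 30))
  expect_equal(subs$offset_50$time_min, seq(50, 230, by = 30))

  # offset 0 on an already 30-min series is the identity
  sparse <- tibble::tibble(time_min = seq(-30, 300, by = 30), conc_pg_ml = 1:12)
  ident <- subsample_offsets(sparse, 30, 0)[[1]]
  expect_equal(ident$time_min, sparse$time_min)

  # offsets off the dense lattice cannot produce a usable subset
  expect_error(subsample_offsets(dense, 30, 55), "aligned")
})

test_that("repeating the same offset gives zero spread", {
  cyt <- default_cytokine_panel_spec()[2, ]
  dense <- dense_sample(cohort_spec(n_animals = 3, cytokines = cyt, seed = 2),
                        step = 10)
  rep0 <- offset_invariance(dense$cohort, 30, c(60, 60, 60))
  expect_equal(rep0$summary$mean_onset_spread_min, 0)
  expect_equal(rep0$summary$mean_auc_rel_spread_pct, 0)
})

test_that("offset spreads agree with an independent straight-line reimplementation", {
  set.seed(321)
  cfg <- analysis_config()
  offsets <- c(50, 60, 70); interval <- 30
  dense_t <- seq(-30, 300, by = 10)
  for (i in 1:10) {
    onset <- runif(1, 60, 150)
    amp <- runif(1, 200, 5000)
    rise <- runif(1, 60, 100)
    vals <- 20 + amp * pulse_asym((dense_t - onset + 0.26 * rise) / rise, 0.5)
    dense <- tibble::tibble(animal_id = "x", subgroup = "g", cytokine = "TNF-a",
                            time_min = dense_t, conc_pg_ml = vals, flag = "ok")
    got <- offset_invariance(as_cohort(dense), interval, offsets, cfg)

    # independent path: plain splinefun + explicit scans, no package internals
    ons <- numeric(0); spans <- numeric(0); curves <- list()
    for (o in offsets) {
      keep <- (dense_t - o) %% interval == 0
      tt <- dense_t[keep]; yy <- vals[keep]
      g <- seq(tt[1], tt[length(tt)], by = 1)
      cv <- pmax(stats::splinefun(tt, yy, method = "natural")(g), 0)
      bl <- mean(cv[g < 0])
      v <- cv - bl
      pk <- which.max(v)
      thr <- 0.05 * v[pk]
      below <- which(v[1:pk] < thr)
      on_i <- g[max(below) + 1]
      ons <- c(ons, on_i); spans <- c(spans, g[length(g)] - on_i)
      curves[[as.character(o)]] <- list(g = g, v = v, on = on_i)
    }
    D <- min(spans)
    aucs <- vapply(curves, function(cu) {
      tt <- cu$g - cu$on
      sel <- tt >= 0 & tt <= D
      sum(diff(tt[sel]) * (head(pmax(cu$v[sel], 0), -1) +
                           tail(pmax(cu$v[sel], 0), -1)) / 2)
    }, numeric(1))
    expect_equal(got$per_series$onset_spread_min, max(ons) - min(ons))
    expect_equal(got$per_series$auc_rel_spread_pct,
                 100 * (max(aucs) - min(aucs)) / mean(aucs), tolerance = 1e-6)
  }
})

test_that("offset spreads are invariant to scaling and consistent time shifts", {
  cyt <- default_cytokine_panel_spec()[2, ]
  cyt$meas_cv <- 0
  dense <- dense_sample(cohort_spec(n_animals = 4, cytokines = cyt, seed = 9),
                        step = 10)
  base <- offset_invariance(dense$cohort, 30, c(50, 60, 70))

  scaled <- dplyr::mutate(tibble::as_tibble(dense$cohort),
                          conc_pg_ml = conc_pg_ml * 12)
  rep_sc <- offset_invariance(as_cohort(scaled), 30, c(50, 60, 70))
  expect_equal(rep_sc$per_series$onset_spread_min,
               base$per_series$onset_spread_min)
  expect_equal(rep_sc$per_series$auc_rel_spread_pct,
               base$per_series$auc_rel_spread_pct, tolerance = 1e-9)

  # raw mode: the baseline window is pinned at t < 0, so exact shift
  # invariance holds only when no baseline correction is applied
  raw <- analysis_config(baseline_mode = "raw")
  base <- offset_invariance(dense$cohort, 30, c(50, 60, 70), raw)
  shifted <- dplyr::mutate(tibble::as_tibble(dense$cohort),
                           time_min = time_min - 30)
  rep_sh <- offset_invariance(as_cohort(shifted), 30, c(50, 60, 70) - 30, raw)
  expect_equal(rep_sh$per_series$onset_spread_min,
               base$per_series$onset_spread_min)
  expect_equal(rep_sh$per_series$auc_rel_spread_pct,
               base$per_series$auc_rel_spread_pct, tolerance = 1e-9)
})

test_that("series without elevations are skipped and counted", {
  sched <- seq(-30, 300, by = 10)
  flat <- tibble::tibble(animal_id = "f", subgroup = "g", cytokine = "IL-22",
                         time_min = sched, conc_pg_ml = 15, flag = "ok")
  rep <- offset_invariance(as_cohort(flat), 30, c(50, 60, 70))
  expect_equal(rep$n_skipped, 1)
  expect_equal(nrow(rep$per_series), 0)
})
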