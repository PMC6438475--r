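test_that("pulse shapes are one-humped, normalized and correctly parameterized", {
  u <- seq(-1, 6, by = 0.01)
  for (k in c(0.5, 1, 3)) {
    g <- pulse_gamma(u, k)
    expect_true(all(g[u <= 0] == 0))
    expect_equal(max(g), 1, tolerance = 1e-6)
    expect_equal(u[which.max(g)], 1, tolerance = 0.02)
  }
  h <- pulse_asym(u, k_decay = 0.5)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_true(all(diff(h[u > 0 & u < 1]) > 0))  # monotone rise
  expect_true(all(diff(h[u > 1.01]) < 0))       # monotone decay
  # falling limb: log g(u) = k (log u + 1 - u), so the decay rate tends to k
  r <- log(pulse_asym(5, 0.5) / pulse_asym(6, 0.5))
  expect_equal(r, 0.5 * (1 + log(5 / 6)), tolerance = 1e-9)
})

test_that("simulation is deterministic and schedule-independent in its truth", {
  spec <- cohort_spec(n_animals = 5, seed = 123)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(tibble::as_tibble(s1$cohort), tibble::as_tibble(s2$cohort))
  expect_identical(s1$truth, s2$truth)

  dense <- dense_sample(spec, step = 10)
  expect_identical(dense$truth, s1$truth) # shared ground truth
  n_times <- length(seq(-30, 300, by = 10))
  expect_equal(nrow(dense$cohort),
               nrow(dplyr::distinct(dense$truth, animal_id, cytokine)) * n_times)
  expect_equal(n_times, 34)
  expect_error(dense_sample(spec, step = 7), "divide")
})

test_that("generated cohorts respect flags, floors and saturation limits", {
  cyt <- cytokine_spec("IL-6", 100, 15, amp_mean = 1000, sat_limit = 600,
                       baseline_floor = 50, meas_cv = 0.3)
  sim <- simulate_cohort(cohort_spec(n_animals = 12, cytokines = cyt, seed = 4))
  co <- sim$cohort
  expect_true(all(co$conc_pg_ml <= 600))
  expect_true(all(co$conc_pg_ml >= 25)) # LOD at half the floor
  expect_true(any(co$flag == "saturated"))
  expect_equal(co$conc_pg_ml[co$flag == "saturated"],
               rep(600, sum(co$flag == "saturated")))
  expect_equal(nrow(validate_cohort(co)), 0)
})

test_that("noise-free dense cohorts reproduce the drawn onsets on the grid", {
  cyts <- dplyr::bind_rows(
    cytokine_spec("IL-10", 60, 10, amp_mean = 2000, rise_tau = 75,
                  decay_tau = 150, baseline_floor = 30, meas_cv = 0, amp_cv = 0),
    cytokine_spec("IFN-g", 170, 10, amp_mean = 1500, rise_tau = 75,
                  decay_tau = 150, baseline_floor = 20, meas_cv = 0, amp_cv = 0)
  )
  spec <- cohort_spec(n_animals = 6, cytokines = cyts, shared_shift_sd = 8,
                      seed = 17)
  sim <- dense_sample(spec, step = 5)
  est <- cohort_onsets(sim$cohort)
  j <- dplyr::inner_join(
    dplyr::select(est, "animal_id", "cytokine", "t_onset"),
    sim$truth, by = c("animal_id", "cytokine"))
  expect_true(all(abs(j$t_onset - j$true_onset_min) <= 1.5))
})

test_that("the marginal onset SD matches the per-cytokine budget", {
  cyt <- cytokine_spec("TNF-a", 100, 20, amp_mean = 2000)
  spec <- cohort_spec(n_animals = 600, cytokines = cyt, shared_shift_sd = 15,
                      seed = 31)
  truth <- simulate_cohort(spec)$truth
  expect_equal(sd(truth$true_onset_min), 20, tolerance = 0.1)
  expect_warning(
    cohort_spec(n_animals = 4, cytokines = cyt, shared_shift_sd = 15,
                resid_jitter_sd = 1),
    "budget")
})

test_that("the animal-level shared shift dominates and is recoverable", {
  cyts <- dplyr::bind_rows(
    cytokine_spec("IL-10", 70, 15.5, amp_mean = 2500, rise_tau = 75,
                  decay_tau = 150, baseline_floor = 30, meas_cv = 0.05),
    cytokine_spec("TNF-a", 130, 15.5, amp_mean = 4000, rise_tau = 75,
                  decay_tau = 150, baseline_floor = 20, meas_cv = 0.05)
  )
  spec <- cohort_spec(n_animals = 60, cytokines = cyts, shared_shift_sd = 15,
                      seed = 71)
  sim <- simulate_cohort(spec)
  est <- cohort_onsets(sim$cohort)
  wide <- est |>
    dplyr::select("animal_id", "cytokine", "t_onset") |>
    tidyr::pivot_wider(names_from = "cytokine", values_from = "t_onset")
  expect_gt(cor(wide$`IL-10`, wide$`TNF-a`, use = "complete.obs"), 0.8)
})

test_that("responder fractions reproduce reduced group sizes", {
  cyt <- cytokine_spec("IL-22", 150, 20, amp_mean = 200, baseline_floor = 15,
                       p_respond = 26 / 44)
  spec <- cohort_spec(n_animals = 300, cytokines = cyt, seed = 13)
  sim <- simulate_cohort(spec)
  expect_equal(mean(sim$truth$responder), 26 / 44, tolerance = 0.1)
  tab <- onset_table(sim$cohort)
  # pipeline-detected n tracks the generated responder count closely
  expect_lt(abs(tab$n - sum(sim$truth$responder)), 12)
})

test_that("effect scenarios embed recoverable amplitude multipliers", {
  cyt <- cytokine_spec("IL-10", 70, 12, amp_mean = 2500, amp_cv = 0.2,
                       rise_tau = 75, decay_tau = 150, baseline_floor = 30)
  base <- cohort_spec(n_animals = 24, cytokines = cyt, seed = 55)
  eff <- tibble::tibble(
    subgroup = c("HBes", "Down", "Null"),
    cytokine = "IL-10",
    multiplier = c(1.73, 0.5, 1)
  )
  scen <- make_effect_scenario(base, eff, reference = "SubD-Sham")
  expect_equal(scen$intended$intended_pct_change, c(73, -50, 0))
  expect_setequal(unique(scen$cohort$subgroup),
                  c("SubD-Sham", "HBes", "Down", "Null"))

  fit <- analyze_cohort(scen$cohort, reference = "SubD-Sham")
  em <- fit$effects
  expect_equal(em$pct_change[em$subgroup == "HBes"], 73, tolerance = 0.3)
  expect_equal(em$direction[em$subgroup == "HBes"], "up")
  expect_equal(em$direction[em$subgroup == "Down"], "down")
  expect_equal(em$direction[em$subgroup == "Null"], "no_change")

  expect_error(make_effect_scenario(base, dplyr::mutate(eff, multiplier = -1)),
               "multipliers")
  expect_error(
    make_effect_scenario(base, tibble::tibble(subgroup = "X", cytokine = "IL-9",
                                              multiplier = 2)),
    "not in the panel")
})
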