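# --- pulse shape -------------------------------------------------------------

#' Gamma-like pulse shape
#'
#' Smooth one-humped pulse `g(u) = u^k exp(k (1 - u))` for `u > 0`, zero
#' before, peaking at 1 when `u = 1`. `u` is time since pulse start in units
#' of the rise time, so the peak sits one rise time after the start; `k`
#' controls width — the late decay is exponential with time constant
#' `rise_tau / k`, so `k = rise_tau / decay_tau` realizes a requested decay
#' time.
#'
#' @param u Scaled time (dimensionless).
#' @param k Shape parameter (> 0).
#' @return Pulse values in \[0, 1\].
#' @export
pulse_gamma <- function(u, k) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(k * (log(u[pos]) + 1 - u[pos]))
  out
}

# scaled time at which the noiseless pulse first reaches `frac` of its peak
pulse_crossing <- function(k, frac = 0.05) {
  uniroot(function(x) pulse_gamma(x, k) - frac,
          lower = 1e-12, upper = 1, tol = 1e-10)$root
}

#' Asymmetric cytokine pulse
#'
#' Piecewise gamma hump: the rising limb (u in \[0, 1\], u = time since pulse
#' start over the rise time) is [pulse_gamma()] with shape `k_rise`, giving a
#' smooth zero-slope foot; the falling limb (u > 1) is [pulse_gamma()] with
#' shape `k_decay`, whose late decay is exponential with time constant
#' `rise_tau / k_decay`. Both limbs peak at 1 when `u = 1` with zero slope, so
#' the pulse is C1 at its maximum. `k_rise` is fixed at 5 by default — a
#' gradual, sigmoid-like uptake foot consistent with transcription-limited
#' cytokine release — while `k_decay = rise_tau / decay_tau` realizes the
#' requested decay time.
#'
#' @param u Scaled time since pulse start, in rise-time units.
#' @param k_decay Decay-side shape (rise over decay time constant).
#' @param k_rise Rise-side shape (foot smoothness); default 5.
#' @return Pulse values in \[0, 1\].
#' @export
pulse_asym <- function(u, k_decay, k_rise = 5) {
  ifelse(u <= 1, pulse_gamma(u, k_rise), pulse_gamma(u, k_decay))
}

# --- specifications ----------------------------------------------------------

#' Generative parameters for one cytokine
#'
#' @param name Cytokine name (normalized against the canonical panel).
#' @param mu_onset,sd_onset Mean and SD of the elevation starting point,
#'   minutes post-injection. Interpreted as the 5%-of-peak crossing time of
#'   the noiseless pulse, i.e. the quantity the analysis pipeline estimates.
#' @param amp_mean,amp_cv Pulse amplitude above baseline: lognormal mean
#'   (pg/mL) and coefficient of variation.
#' @param rise_tau Minutes from pulse start to peak.
#' @param decay_tau Late exponential decay time constant, minutes.
#' @param baseline_floor Resting/assay-floor concentration, pg/mL.
#' @param meas_cv Multiplicative (lognormal) measurement noise CV.
#' @param sat_limit Upper quantification limit, pg/mL (`Inf` = none).
#' @param p_respond Probability an animal shows a calculable elevation.
#' @return One-row tibble.
#' @export
cytokine_spec <- function(name, mu_onset, sd_onset, amp_mean, amp_cv = 0.6,
                          rise_tau = 60, decay_tau = 100, baseline_floor = 20,
                          meas_cv = 0.1, sat_limit = Inf, p_respond = 1) {
  stopifnot(mu_onset > 0, sd_onset >= 0, amp_mean > 0, amp_cv >= 0,
            rise_tau > 0, decay_tau > 0, baseline_floor >= 0, meas_cv >= 0,
            sat_limit > 0, p_respond > 0, p_respond <= 1)
  tibble::tibble(
    name = normalize_cytokine(name), mu_onset = mu_onset, sd_onset = sd_onset,
    amp_mean = amp_mean, amp_cv = amp_cv, rise_tau = rise_tau,
    decay_tau = decay_tau, baseline_floor = baseline_floor, meas_cv = meas_cv,
    sat_limit = sat_limit, p_respond = p_respond
  )
}

#' Default seven-cytokine IP challenge panel
#'
#' The seven cytokines with detectable elevations after a 5 mg/kg IP endotoxin
#' challenge, parameterized by their published starting-point means and SDs
#' (IP column): IL-10 49.2 ± 18.6, TNF-α 72.2 ± 22.9, GM-CSF 116.6 ± 28.4,
#' IL-17F 125.2 ± 37.5, IL-6 129.6 ± 24.3, IL-22 182.6 ± 33.3 and IFN-γ
#' 186.6 ± 25.2 minutes. Responder fractions reproduce the reduced n of
#' 29/44 (IL-17F), 41/44 (IL-6) and 26/44 (IL-22); IL-6 carries a finite
#' upper quantification limit so occasional saturation occurs. Amplitudes,
#' pulse shapes and floors are order-of-magnitude realistic for rat plasma
#' and are documented in the methods vignette.
#'
#' @param route `"IP"` (default). An `"IV"` variant with earlier, tighter
#'   IL-10/TNF-α onsets (48.1 ± 14.6 and 30.3 ± 7.9 min) is provided for
#'   route-contrast demonstrations.
#' @return Tibble of [cytokine_spec()] rows.
#' @export
default_cytokine_panel_spec <- function(route = c("IP", "IV")) {
  route <- match.arg(route)
  if (route == "IP") {
    dplyr::bind_rows(
      cytokine_spec("IL-10", 49.2, 18.6, amp_mean = 2500, rise_tau = 75,
                    decay_tau = 150, baseline_floor = 30),
      cytokine_spec("TNF-a", 72.2, 22.9, amp_mean = 4000, rise_tau = 85,
                    decay_tau = 170, baseline_floor = 20),
      cytokine_spec("GM-CSF", 116.6, 28.4, amp_mean = 150, rise_tau = 80,
                    decay_tau = 160, baseline_floor = 10),
      cytokine_spec("IL-17F", 125.2, 37.5, amp_mean = 100, rise_tau = 80,
                    decay_tau = 160, baseline_floor = 10, p_respond = 29 / 44),
      cytokine_spec("IL-6", 129.6, 24.3, amp_mean = 40000, rise_tau = 90,
                    decay_tau = 180, baseline_floor = 50, sat_limit = 1.2e5,
                    p_respond = 41 / 44),
      cytokine_spec("IL-22", 182.6, 33.3, amp_mean = 200, rise_tau = 80,
                    decay_tau = 160, baseline_floor = 15, p_respond = 26 / 44),
      cytokine_spec("IFN-g", 186.6, 25.2, amp_mean = 1500, rise_tau = 75,
                    decay_tau = 150, baseline_floor = 20)
    )
  } else {
    dplyr::bind_rows(
      cytokine_spec("IL-10", 48.1, 14.6, amp_mean = 2500, rise_tau = 75,
                    decay_tau = 150, baseline_floor = 30),
      cytokine_spec("TNF-a", 30.3, 7.9, amp_mean = 4000, rise_tau = 75,
                    decay_tau = 150, baseline_floor = 20)
    )
  }
}

#' Specification of a synthetic endotoxin-challenge cohort
#'
#' Defines the generative model: per-animal shared time shift
#' `delta_i ~ N(0, shared_shift_sd)` applied to every cytokine of that animal
#' (the dominant source of onset variability — when one cytokine elevates
#' early in an animal the whole cascade does), plus per-(animal, cytokine)
#' residual jitter. By default the residual SD is derived per cytokine as
#' `sqrt(sd_onset^2 - shared_shift_sd^2)`, so the marginal onset SD matches
#' each cytokine's specified `sd_onset` exactly.
#'
#' @param n_animals Number of animals (default 44, the published IP n).
#' @param schedule Sampling schedule, minutes ([default_schedule()]).
#' @param cytokines Tibble of [cytokine_spec()] rows
#'   ([default_cytokine_panel_spec()]).
#' @param shared_shift_sd SD of the animal-level shared onset shift, minutes
#'   (default 15).
#' @param resid_jitter_sd Per-cytokine residual onset SD, minutes; `NULL`
#'   (default) derives it from each cytokine's `sd_onset` budget. A supplied
#'   value is used for all cytokines, with a consistency warning when
#'   `shared_shift_sd^2 + resid_jitter_sd^2` strays from the `sd_onset^2`
#'   budget by more than 20%.
#' @param seed Integer master seed; identical specs give bit-identical
#'   cohorts.
#' @param dose_mg_kg,route,subgroup Metadata / labels.
#' @return A `cyto_cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 44, schedule = default_schedule(),
                        cytokines = default_cytokine_panel_spec(),
                        shared_shift_sd = 15, resid_jitter_sd = NULL,
                        seed = 1L, dose_mg_kg = 5, route = "IP",
                        subgroup = "SubD-Sham") {
  stopifnot(n_animals >= 1, shared_shift_sd >= 0)
  validate_schedule(schedule)
  if (!is.null(resid_jitter_sd)) {
    tot <- shared_shift_sd^2 + resid_jitter_sd^2
    off <- abs(tot - cytokines$sd_onset^2) / pmax(cytokines$sd_onset^2, 1e-12)
    if (any(off > 0.2)) {
      warn(paste0("shared_shift_sd^2 + resid_jitter_sd^2 deviates >20% from the ",
                  "sd_onset^2 budget for: ",
                  paste(cytokines$name[off > 0.2], collapse = ", ")))
    }
  }
  structure(
    list(n_animals = as.integer(n_animals), schedule = schedule,
         cytokines = cytokines, shared_shift_sd = shared_shift_sd,
         resid_jitter_sd = resid_jitter_sd, seed = as.integer(seed),
         dose_mg_kg = dose_mg_kg, route = route, subgroup = subgroup),
    class = "cyto_cohort_spec"
  )
}

# residual onset SD for one cytokine under the spec's variance budget
resid_sd_for <- function(spec, sd_onset) {
  if (!is.null(spec$resid_jitter_sd)) return(spec$resid_jitter_sd)
  sqrt(max(sd_onset^2 - spec$shared_shift_sd^2, 0))
}

# Draw all latent truth (shared shifts, onsets, amplitudes, responder status).
# Consumes a fixed number of random draws regardless of the sampling schedule,
# so sparse and dense cohorts generated from the same spec share ground truth.
simulate_truth <- function(spec) {
  set.seed(spec$seed)
  cyt <- spec$cytokines
  rows <- vector("list", spec$n_animals)
  for (i in seq_len(spec$n_animals)) {
    delta <- rnorm(1, 0, spec$shared_shift_sd)
    eps <- rnorm(nrow(cyt), 0, vapply(cyt$sd_onset, function(s)
      resid_sd_for(spec, s), numeric(1)))
    # lognormal amplitude with the requested mean and CV
    sdl <- sqrt(log(1 + cyt$amp_cv^2))
    amp <- cyt$amp_mean * exp(rnorm(nrow(cyt)) * sdl - sdl^2 / 2)
    responder <- runif(nrow(cyt)) < cyt$p_respond
    rows[[i]] <- tibble::tibble(
      animal_id = sprintf("%s-%03d", spec$subgroup, i),
      cytokine = cyt$name,
      shared_shift = delta,
      true_onset_min = cyt$mu_onset + delta + eps,
      true_amp = amp,
      responder = responder
    )
  }
  dplyr::bind_rows(rows)
}

# Noiseless continuous profile for one series (vectorized over t). The drawn
# onset is placed at the pulse's 5%-of-peak crossing, the scale the pipeline
# estimates, by back-shifting the latent pulse start.
profile_values <- function(t, onset, amp, cs, onset_fraction = 0.05,
                           k_rise = 5) {
  k_decay <- cs$rise_tau / cs$decay_tau
  t0 <- onset - cs$rise_tau * pulse_crossing(k_rise, onset_fraction)
  cs$baseline_floor + amp * pulse_asym((t - t0) / cs$rise_tau, k_decay, k_rise)
}

#' Simulate a synthetic endotoxin-challenge cohort
#'
#' Generates per-animal, per-cytokine pulse-shaped concentration profiles with
#' a dominant animal-level shared onset shift, samples them on the spec's
#' schedule, applies multiplicative lognormal measurement noise, floor-censors
#' values below half the baseline floor and clips values above the saturation
#' limit (with flags). Non-responders (probability `1 - p_respond`) show
#' baseline only. The returned ground truth records every latent onset,
#' amplitude and responder status.
#'
#' The onset parameters are placed on the scale the analysis pipeline
#' estimates: each drawn onset is the time the noiseless profile crosses 5% of
#' its peak amplitude, so pipeline estimates can be compared to the generative
#' means directly.
#'
#' @param spec A [cohort_spec()].
#' @param schedule Optional override of the spec's sampling schedule (used by
#'   [dense_sample()]); ground truth is unchanged by the schedule.
#' @return List with `cohort` (a `cyto_cohort`) and `truth` (tibble:
#'   `animal_id`, `cytokine`, `shared_shift`, `true_onset_min`, `true_amp`,
#'   `responder`).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_animals = 4, seed = 7))
#' sim$cohort
#' @export
simulate_cohort <- function(spec, schedule = NULL) {
  stopifnot(inherits(spec, "cyto_cohort_spec"))
  sched <- schedule %||% spec$schedule
  validate_schedule(sched)
  truth <- simulate_truth(spec)
  cyt <- spec$cytokines

  set.seed(spec$seed + 1L) # measurement-noise stream, separate from truth
  rows <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    cs <- cyt[cyt$name == truth$cytokine[r], ]
    clean <- if (truth$responder[r]) {
      profile_values(sched, truth$true_onset_min[r], truth$true_amp[r], cs)
    } else {
      rep(cs$baseline_floor, length(sched))
    }
    sdl <- sqrt(log(1 + cs$meas_cv^2))
    noisy <- clean * exp(rnorm(length(sched)) * sdl - sdl^2 / 2)
    flag <- rep("ok", length(sched))
    lod <- 0.5 * cs$baseline_floor
    low <- noisy < lod
    noisy[low] <- lod
    flag[low] <- "below_floor"
    sat <- noisy > cs$sat_limit
    noisy[sat] <- cs$sat_limit
    flag[sat] <- "saturated"
    rows[[r]] <- tibble::tibble(
      animal_id = truth$animal_id[r], subgroup = spec$subgroup,
      cytokine = truth$cytokine[r], time_min = sched,
      conc_pg_ml = noisy, flag = flag
    )
  }
  cohort <- as_cohort(dplyr::bind_rows(rows), dose_mg_kg = spec$dose_mg_kg,
                      route = spec$route,
                      provenance = sprintf("synthetic (seed %d)", spec$seed))
  list(cohort = cohort, truth = truth)
}

#' Sample the same generative model on a dense schedule
#'
#' Used by the offset-subsampling validation harness: identical ground truth
#' to the sparse cohort under the same spec/seed, sampled every `step`
#' minutes over the spec schedule's span.
#'
#' @param spec A [cohort_spec()].
#' @param step Dense sampling step, minutes; must divide the schedule span.
#' @return As [simulate_cohort()].
#' @export
dense_sample <- function(spec, step = 10) {
  stopifnot(inherits(spec, "cyto_cohort_spec"), step > 0)
  lo <- min(spec$schedule); hi <- max(spec$schedule)
  if (abs((hi - lo) / step - round((hi - lo) / step)) > 1e-9) {
    abort("step must divide the schedule span")
  }
  simulate_cohort(spec, schedule = seq(lo, hi, by = step))
}

#' Build a multi-subgroup cohort with known group effects
#'
#' Generates one subgroup per row-set of `effects` plus the reference
#' subgroup, scaling pulse amplitudes by the given multipliers so every
#' intended percent change (`100 * (multiplier - 1)`) is known ground truth
#' for end-to-end tests of the effect matrix.
#'
#' @param base A [cohort_spec()] describing one subgroup (animal count,
#'   schedule, panel, seed).
#' @param effects Tibble with columns `subgroup`, `cytokine`, `multiplier`
#'   (> 0); cytokines not listed for a subgroup keep multiplier 1.
#' @param reference Reference subgroup label (amplitudes unscaled).
#' @return List with `cohort` (all subgroups combined), `truth`, and
#'   `intended` (tibble `subgroup`, `cytokine`, `multiplier`,
#'   `intended_pct_change`).
#' @export
make_effect_scenario <- function(base, effects, reference = "SubD-Sham") {
  stopifnot(inherits(base, "cyto_cohort_spec"))
  stopifnot(all(c("subgroup", "cytokine", "multiplier") %in% names(effects)))
  if (any(effects$multiplier <= 0)) abort("multipliers must be > 0")
  effects$cytokine <- normalize_cytokine(effects$cytokine)
  unknown <- setdiff(effects$cytokine, base$cytokines$name)
  if (length(unknown) > 0) {
    abort(paste0("effect cytokine(s) not in the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  groups <- c(reference, setdiff(unique(effects$subgroup), reference))
  sims <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    cyts <- base$cytokines
    if (g != reference) {
      eff <- effects[effects$subgroup == g, ]
      m <- eff$multiplier[match(cyts$name, eff$cytokine)]
      m[is.na(m)] <- 1
      cyts$amp_mean <- cyts$amp_mean * m
      # saturation limits stay fixed: larger responses may saturate, as in assays
    }
    spec_g <- cohort_spec(
      n_animals = base$n_animals, schedule = base$schedule, cytokines = cyts,
      shared_shift_sd = base$shared_shift_sd,
      resid_jitter_sd = base$resid_jitter_sd,
      seed = base$seed + 7919L * gi, dose_mg_kg = base$dose_mg_kg,
      route = base$route, subgroup = g
    )
    sims[[gi]] <- simulate_cohort(spec_g)
  }
  cohort <- as_cohort(
    dplyr::bind_rows(lapply(sims, function(s) tibble::as_tibble(s$cohort))),
    dose_mg_kg = base$dose_mg_kg, route = base$route,
    provenance = sprintf("synthetic effect scenario (seed %d)", base$seed)
  )
  truth <- dplyr::bind_rows(lapply(seq_along(sims), function(i) {
    dplyr::mutate(sims[[i]]$truth, subgroup = groups[i])
  }))
  intended <- effects |>
    dplyr::mutate(intended_pct_change = 100 * (.data$multiplier - 1))
  list(cohort = cohort, truth = truth, intended = intended)
}

#' Write a simulated cohort and its ground truth to disk
#'
#' @param sim Result of [simulate_cohort()] / [make_effect_scenario()].
#' @param cohort_path,truth_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, cohort_path, truth_path) {
  write_cohort(sim$cohort, cohort_path)
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  invisible(c(cohort_path, truth_path))
}
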