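#' Split a densely sampled series into offset sparse subsets
#'
#' For each offset o, keeps the dense samples lying on the arithmetic grid
#' \{o + k interval\} (any integer k) — e.g. a 10-min dense series split with
#' interval 30 and offsets 60, 70, 50 yields the three staggered 30-min
#' subsets used to certify curve fitting against denser sampling.
#'
#' @param dense Data frame for one series with columns `time_min`,
#'   `conc_pg_ml` (and optionally `flag` and identifiers).
#' @param interval Sparse sampling interval, minutes.
#' @param offsets Numeric vector of offsets, minutes; each must lie on the
#'   dense sampling lattice and yield at least 4 points.
#' @return Named list of sparse series tibbles, one per offset.
#' @export
subsample_offsets <- function(dense, interval, offsets) {
  stopifnot(interval > 0, length(offsets) >= 1)
  t <- dense$time_min
  out <- vector("list", length(offsets))
  names(out) <- paste0("offset_", offsets)
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    on_lattice <- abs(((t - o) / interval) - round((t - o) / interval)) < 1e-9
    sel <- dense[on_lattice, , drop = FALSE]
    if (nrow(sel) < 4) {
      abort(sprintf(
        "offset %g yields %d point(s) (< 4); is it aligned to the dense grid?",
        o, nrow(sel)))
    }
    out[[i]] <- tibble::as_tibble(sel[order(sel$time_min), , drop = FALSE])
  }
  out
}

#' Onset / AUC stability across offset subsamplings
#'
#' The verification procedure for the curve-fitting + alignment chain: each
#' densely sampled series is split into staggered sparse subsets
#' ([subsample_offsets()]); the full fit -> peak -> onset -> AUC chain runs on
#' every subset; and the report gives, per series, the spread (max - min) and
#' SD of the onset estimates across subsets, and the relative spread
#' `100 * (max - min) / mean` and relative SD of the effective AUCs. AUCs are
#' made comparable across subsets by integrating each subset from its own
#' onset over the series' common duration `min(t_last - t_onset)`, mirroring
#' the alignment rule. Series without a detectable elevation in every subset
#' are skipped and counted.
#'
#' @param dense_cohort A `cyto_cohort` sampled on a dense schedule.
#' @param interval Sparse interval in minutes (default 30).
#' @param offsets Offsets in minutes (default `c(50, 60, 70)`).
#' @param config An [analysis_config()].
#' @return A `cyto_offset_report`: list with `per_series` (tibble:
#'   identifiers, per-offset onsets, `onset_spread_min`, `onset_sd_min`,
#'   `auc_rel_spread_pct`, `auc_rel_sd_pct`), `summary` (one-row tibble of
#'   averages over series), and `n_skipped`.
#' @export
offset_invariance <- function(dense_cohort, interval = 30,
                              offsets = c(50, 60, 70),
                              config = analysis_config()) {
  ser <- cohort_series(dense_cohort)
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(ser))) {
    d <- ser$data[[i]]
    d$animal_id <- ser$animal_id[i]
    d$subgroup <- ser$subgroup[i]
    d$cytokine <- ser$cytokine[i]
    subsets <- subsample_offsets(d, interval, offsets)
    res <- tryCatch({
      onsets <- lapply(subsets, function(s) {
        crv <- fit_curve(s, config)
        detect_onset(crv, config = config)
      })
      curves <- lapply(subsets, fit_curve, config = config)
      spans <- mapply(function(crv, on) tail(crv$grid, 1) - on$t_onset,
                      curves, onsets)
      D <- min(spans)
      aucs <- mapply(function(crv, on) {
        shifted <- crv$grid - on$t_onset
        aligned <- tibble::tibble(
          time_min = shifted, value_pg_ml = crv$values - on$baseline)
        compute_auc(aligned[shifted >= -1e-9 & shifted <= D + 1e-9, ], D)
      }, curves, onsets)
      ons <- vapply(onsets, `[[`, numeric(1), "t_onset")
      list(ons = ons, aucs = aucs)
    }, cyto_no_elevation = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      animal_id = ser$animal_id[i], subgroup = ser$subgroup[i],
      cytokine = ser$cytokine[i],
      onsets = list(setNames(res$ons, names(subsets))),
      aucs = list(setNames(res$aucs, names(subsets))),
      onset_spread_min = max(res$ons) - min(res$ons),
      onset_sd_min = if (length(res$ons) > 1) sd(res$ons) else 0,
      auc_rel_spread_pct = 100 * (max(res$aucs) - min(res$aucs)) / mean(res$aucs),
      auc_rel_sd_pct = if (length(res$aucs) > 1)
        100 * sd(res$aucs) / mean(res$aucs) else 0
    )
  }
  per_series <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(animal_id = character(), subgroup = character(),
                   cytokine = character(), onsets = list(), aucs = list(),
                   onset_spread_min = numeric(), onset_sd_min = numeric(),
                   auc_rel_spread_pct = numeric(), auc_rel_sd_pct = numeric())
  summary <- tibble::tibble(
    n_series = nrow(per_series),
    n_skipped = n_skipped,
    mean_onset_spread_min = mean(per_series$onset_spread_min),
    mean_onset_sd_min = mean(per_series$onset_sd_min),
    mean_auc_rel_spread_pct = mean(per_series$auc_rel_spread_pct),
    mean_auc_rel_sd_pct = mean(per_series$auc_rel_sd_pct)
  )
  structure(list(per_series = per_series, summary = summary,
                 n_skipped = n_skipped, interval = interval,
                 offsets = offsets),
            class = "cyto_offset_report")
}

#' @export
print.cyto_offset_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<cyto_offset_report> %d series (%d skipped), interval %g min, ",
           "offsets {%s}\n  mean onset spread %.2f min (SD %.2f); ",
           "mean AUC spread %.2f%% (SD %.2f%%)\n"),
    s$n_series, s$n_skipped, x$interval,
    paste(x$offsets, collapse = ", "),
    s$mean_onset_spread_min, s$mean_onset_sd_min,
    s$mean_auc_rel_spread_pct, s$mean_auc_rel_sd_pct))
  invisible(x)
}
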