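#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cascade analysis
#'
#' One row per (animal, cytokine) series with its landmarks and effective AUC.
#'
#' @param x A `cyto_analysis` from [analyze_cohort()].
#' @param ... Unused.
#' @return Tibble: `animal_id`, `subgroup`, `cytokine`, `elevated`,
#'   `t_onset`, `t_peak`, `peak_amp`, `baseline`, `effective_peak_is_last`,
#'   `left_censored`, `auc_pg_min_ml`, `auc_lower_bound`.
#' @export
tidy.cyto_analysis <- function(x, ...) {
  dplyr::left_join(
    x$onsets,
    dplyr::select(x$aucs, "animal_id", "cytokine", "auc_pg_min_ml",
                  "auc_lower_bound"),
    by = c("animal_id", "cytokine")
  )
}

#' One-row overview of a cascade analysis
#'
#' @param x A `cyto_analysis`.
#' @param ... Unused.
#' @return One-row tibble: series counts, censoring counts, number of
#'   cytokines and subgroups, and the earliest/latest mean onset.
#' @export
glance.cyto_analysis <- function(x, ...) {
  s <- x$onset_summary
  tibble::tibble(
    n_series = x$counts$n_series,
    n_no_elevation = x$counts$n_no_elevation,
    n_left_censored = x$counts$n_left_censored,
    n_cytokines = nrow(s),
    n_subgroups = length(unique(x$onsets$subgroup)),
    first_onset_min = min(s$mean_onset_min),
    last_onset_min = max(s$mean_onset_min)
  )
}

#' @rdname tidy.cyto_analysis
#' @export
tidy.cyto_onset <- function(x, ...) {
  tibble::tibble(
    animal_id = x$animal_id, subgroup = x$subgroup, cytokine = x$cytokine,
    baseline = x$baseline, t_peak = x$t_peak, peak_amp = x$peak_amp,
    effective_peak_is_last = x$effective_peak_is_last,
    threshold_value = x$threshold_value, t_onset = x$t_onset,
    left_censored = x$left_censored
  )
}

#' @rdname tidy.cyto_analysis
#' @export
tidy.cyto_offset_report <- function(x, ...) {
  dplyr::select(x$per_series, -"onsets", -"aucs")
}

#' @rdname glance.cyto_analysis
#' @export
glance.cyto_offset_report <- function(x, ...) {
  x$summary
}
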