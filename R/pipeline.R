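#' Run the full cascade analysis on a cohort
#'
#' Orchestrates the whole statistic chain: spline fit per series, peak and 5%
#' onset detection (series without an elevation are counted and dropped from
#' alignment), per-cytokine onset alignment across all animals, effective AUC
#' over each cytokine's common duration, per-(subgroup, cytokine) summaries,
#' one-way ANOVA across subgroups on onsets and on AUCs, and — when a
#' `reference` subgroup is named — the percent-change / post-hoc t-test effect
#' matrix.
#'
#' Alignment pools all subgroups of a cytokine so every animal's AUC is
#' integrated over the same common duration and subgroup AUCs are comparable.
#'
#' @param cohort A `cyto_cohort`.
#' @param config An [analysis_config()].
#' @param reference Optional reference subgroup label for the effect matrix.
#' @return A `cyto_analysis` list: `onsets` (per-series landmarks),
#'   `onset_summary` (per-cytokine cascade table), `aligned` (named list of
#'   `cyto_aligned`, one per cytokine), `aucs` (per-series effective AUCs),
#'   `group_summary`, `anova_onset`, `anova_auc`, `effects` (or `NULL`),
#'   `counts` (no-elevation / left-censored / saturated bookkeeping),
#'   `config`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_animals = 4, seed = 1))
#' fit <- analyze_cohort(sim$cohort)
#' fit$onset_summary
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           reference = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort")
  onsets <- cohort_onsets(cohort, config)
  if (!any(onsets$elevated)) abort("no series shows an elevation above baseline")

  aligned <- list()
  for (cy in unique(onsets$cytokine[onsets$elevated])) {
    members <- onsets[onsets$elevated & onsets$cytokine == cy, ]
    aligned[[cy]] <- align_set(members, config)
  }
  aucs <- dplyr::bind_rows(lapply(aligned, function(a) {
    dplyr::select(tibble::as_tibble(a), -"aligned")
  }))

  gs <- group_summary(aucs)

  anova_by_cytokine <- function(value_col) {
    out <- list()
    for (cy in unique(aucs$cytokine)) {
      sub <- aucs[aucs$cytokine == cy, ]
      groups <- split(sub[[value_col]], sub$subgroup)
      groups <- groups[vapply(groups, length, integer(1)) >= 2]
      if (length(groups) >= 2) {
        out[[cy]] <- dplyr::mutate(anova_oneway(groups), cytokine = cy,
                                   .before = 1)
      }
    }
    if (length(out)) dplyr::bind_rows(out) else NULL
  }
  anova_onset <- anova_by_cytokine("t_onset")
  anova_auc <- anova_by_cytokine("auc_pg_min_ml")

  effects <- NULL
  if (!is.null(reference)) {
    effects <- effect_matrix(aucs, reference, config)
  }

  counts <- tibble::tibble(
    n_series = nrow(onsets),
    n_no_elevation = sum(!onsets$elevated),
    n_left_censored = sum(onsets$left_censored %in% TRUE),
    n_saturated_series = sum(vapply(onsets$curve, function(c)
      isTRUE(c$has_saturated), logical(1)))
  )

  structure(
    list(
      onsets = dplyr::select(onsets, -"data", -"curve", -"onset"),
      onset_summary = onset_table(cohort, config),
      aligned = aligned,
      aucs = aucs,
      group_summary = gs,
      anova_onset = anova_onset,
      anova_auc = anova_auc,
      effects = effects,
      counts = counts,
      config = config
    ),
    class = "cyto_analysis"
  )
}

#' @export
print.cyto_analysis <- function(x, ...) {
  cat(sprintf(
    "<cyto_analysis> %d series (%d without elevation, %d left-censored)\n",
    x$counts$n_series, x$counts$n_no_elevation, x$counts$n_left_censored))
  cat("Cascade (mean onset, min):\n")
  s <- x$onset_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %6.1f ± %.1f s.e.m. (n = %d)\n", s$cytokine[i],
                s$mean_onset_min[i], s$sem_onset_min[i], s$n[i]))
  }
  if (!is.null(x$effects)) {
    format_effect_matrix(x$effects)
  }
  invisible(x)
}

# --- file-level orchestration (manifest-writing command surface) -------------

digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
}

write_manifest <- function(out_dir, stage, inputs, outputs, config = NULL,
                           seed = NULL, timings = NULL, warnings = NULL) {
  manifest <- list(
    stage = stage,
    inputs = digest_files(inputs),
    outputs = digest_files(outputs),
    config = if (!is.null(config)) unclass(config),
    seed = seed,
    timings_sec = timings,
    warnings = warnings
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a cohort-generator spec from YAML
#'
#' Top-level keys mirror [cohort_spec()] arguments; `cytokines` is a list of
#' [cytokine_spec()] argument sets. Omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `cyto_cohort_spec`.
#' @export
spec_from_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("spec file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort(paste0("not a mapping-style YAML spec: ", path))
  if (!is.null(vals$cytokines)) {
    vals$cytokines <- dplyr::bind_rows(lapply(vals$cytokines, function(cs)
      do.call(cytokine_spec, cs)))
  }
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) abort(paste0("unknown spec keys: ",
                                    paste(bad, collapse = ", ")))
  if (!is.null(vals$schedule)) vals$schedule <- as.numeric(vals$schedule)
  do.call(cohort_spec, vals)
}

#' Simulate a cohort to disk
#'
#' Writes `cohort.csv`, `ground_truth.csv` and `manifest.json` to `out_dir`.
#'
#' @param spec A `cyto_cohort_spec`, or path to a YAML spec.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  t0 <- proc.time()[["elapsed"]]
  spec_path <- NULL
  if (is.character(spec)) {
    spec_path <- spec
    spec <- spec_from_yaml(spec)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(spec)
  cohort_path <- file.path(out_dir, "cohort.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_simulation(sim, cohort_path, truth_path)
  write_manifest(out_dir, "simulate", inputs = spec_path %||% character(0),
                 outputs = c(cohort_path, truth_path), seed = spec$seed,
                 timings = proc.time()[["elapsed"]] - t0)
  invisible(out_dir)
}

#' Analyze a cohort file to disk
#'
#' Runs [analyze_cohort()] and persists every intermediate table:
#' `onsets.csv`, `onset_summary.csv`, `aucs.csv`, `group_summary.csv`,
#' `anova_onset.csv`, `anova_auc.csv`, `effects.csv` (when a reference is
#' given) and `manifest.json`.
#'
#' @param cohort_path Cohort CSV path.
#' @param out_dir Output directory.
#' @param config_path Optional YAML config path ([read_config()]).
#' @param reference Optional reference subgroup for the effect matrix.
#' @return Invisibly, the output directory.
#' @export
analyze_to_dir <- function(cohort_path, out_dir, config_path = NULL,
                           reference = NULL) {
  t0 <- proc.time()[["elapsed"]]
  config <- if (is.null(config_path)) analysis_config() else read_config(config_path)
  cohort <- read_cohort(cohort_path)
  fit <- analyze_cohort(cohort, config, reference = reference)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  save_tbl <- function(tbl, name) {
    if (is.null(tbl)) return()
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(tbl), p, progress = FALSE)
    outs <<- c(outs, p)
  }
  save_tbl(fit$onsets, "onsets.csv")
  save_tbl(fit$onset_summary, "onset_summary.csv")
  save_tbl(fit$aucs, "aucs.csv")
  save_tbl(fit$group_summary, "group_summary.csv")
  save_tbl(fit$anova_onset, "anova_onset.csv")
  save_tbl(fit$anova_auc, "anova_auc.csv")
  if (!is.null(fit$effects)) save_tbl(fit$effects, "effects.csv")
  write_manifest(out_dir, "analyze", inputs = c(cohort_path, config_path),
                 outputs = outs, config = config,
                 timings = proc.time()[["elapsed"]] - t0,
                 warnings = as.list(fit$counts))
  invisible(out_dir)
}

#' Run the offset-subsampling validation to disk
#'
#' Writes `offset_per_series.csv`, `offset_summary.csv` and `manifest.json`.
#'
#' @param cohort_path Dense cohort CSV path.
#' @param out_dir Output directory.
#' @param interval,offsets Passed to [offset_invariance()].
#' @param config_path Optional YAML config path.
#' @return Invisibly, the output directory.
#' @export
validate_to_dir <- function(cohort_path, out_dir, interval = 30,
                            offsets = c(50, 60, 70), config_path = NULL) {
  t0 <- proc.time()[["elapsed"]]
  config <- if (is.null(config_path)) analysis_config() else read_config(config_path)
  cohort <- read_cohort(cohort_path)
  rep <- offset_invariance(cohort, interval, offsets, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per <- dplyr::select(rep$per_series, -"onsets", -"aucs")
  p1 <- file.path(out_dir, "offset_per_series.csv")
  p2 <- file.path(out_dir, "offset_summary.csv")
  readr::write_csv(per, p1, progress = FALSE)
  readr::write_csv(rep$summary, p2, progress = FALSE)
  write_manifest(out_dir, "validate", inputs = c(cohort_path, config_path),
                 outputs = c(p1, p2), config = config,
                 timings = proc.time()[["elapsed"]] - t0,
                 warnings = list(n_skipped = rep$n_skipped))
  invisible(out_dir)
}
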