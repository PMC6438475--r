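#' Interquartile-range outlier screen
#'
#' Tukey fence: values outside \[Q1 - k IQR, Q3 + k IQR\] are removed, with
#' quartiles computed by the linear-interpolation convention
#' ([stats::quantile()] type 7). With fewer than 4 values the screen is the
#' identity (with a warning) since quartiles are not meaningful.
#'
#' @param values Numeric vector.
#' @param config An [analysis_config()]; `iqr_multiplier` is k (default 1.5;
#'   `Inf` disables removal).
#' @return List with `kept` and `removed` numeric vectors
#'   (`kept` preserves input order).
#' @examples
#' remove_outliers_iqr(c(1, 2, 3, 4, 100))$removed # 100
#' @export
remove_outliers_iqr <- function(values, config = analysis_config()) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warn("fewer than 4 values: IQR screen skipped")
    return(list(kept = values, removed = numeric(0)))
  }
  k <- config$iqr_multiplier
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  if (is.infinite(k)) { lo <- -Inf; hi <- Inf }
  keep <- values >= lo & values <= hi
  list(kept = values[keep], removed = values[!keep])
}

#' One-way fixed-effects ANOVA
#'
#' Classical equal-variance one-way ANOVA across two or more groups, as used
#' to compare mean elevation starting points and mean effective AUCs between
#' subgroups.
#'
#' @param groups List of numeric vectors, each of length >= 2 (named or not).
#' @return Tibble with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' anova_oneway(list(a = c(1, 2), b = c(3, 4))) # F = 8 on (1, 2) df
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) abort("every group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = n))
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  Fv <- unname(ft$statistic)
  p <- unname(ft$p.value)
  # degenerate all-equal data: zero between and within SS -> F = 0, p = 1
  if (!is.finite(Fv)) {
    Fv <- 0; p <- 1
  }
  tibble::tibble(F = Fv, p = p,
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]))
}

#' Two-sample Student's t-test
#'
#' Pooled-variance, two-sided Student's t-test (the post-hoc comparison used
#' after the group ANOVA). `welch = TRUE` in the config switches to Welch's
#' unequal-variance form. The degenerate case of zero variance in both groups
#' with equal means returns t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param config An [analysis_config()].
#' @return Tibble with `t`, `p`, `df`.
#' @examples
#' ttest_two_sample(c(1, 2), c(3, 4)) # |t| = 2.828, df = 2
#' @export
ttest_two_sample <- function(a, b, config = analysis_config()) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, p = 1, df = length(a) + length(b) - 2))
    }
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                          df = length(a) + length(b) - 2))
  }
  tt <- t.test(a, b, var.equal = !config$welch)
  tibble::tibble(t = unname(tt$statistic), p = unname(tt$p.value),
                 df = unname(tt$parameter))
}

#' Percent change of a group mean versus a reference mean
#'
#' `100 * (group_mean - ref_mean) / ref_mean`: +73 means the group averaged
#' 73% higher than the reference.
#'
#' @param group_mean,ref_mean Numbers; `ref_mean` must be > 0.
#' @return Percent change (scalar, vectorized over `group_mean`).
#' @export
pct_change <- function(group_mean, ref_mean) {
  if (any(ref_mean <= 0)) abort("reference mean must be positive")
  100 * (group_mean - ref_mean) / ref_mean
}

grade_significance <- function(p, alpha_levels) {
  alphas <- sort(alpha_levels) # most stringent first
  for (a in alphas) {
    if (p < a) return(paste0("p<", format(a, trim = TRUE)))
  }
  "none"
}

#' Per-(subgroup, cytokine) summaries of onsets and AUCs
#'
#' @param aucs Tibble with columns `subgroup`, `cytokine`, `t_onset`,
#'   `auc_pg_min_ml` (one row per animal), e.g. the `aucs` component of
#'   [analyze_cohort()].
#' @return Tibble with `subgroup`, `cytokine`, `n`, `mean_auc`, `sem_auc`,
#'   `mean_onset`, `sem_onset`.
#' @export
group_summary <- function(aucs) {
  aucs |>
    dplyr::group_by(.data$subgroup, .data$cytokine) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_auc = mean(.data$auc_pg_min_ml),
      sem_auc = sd(.data$auc_pg_min_ml) / sqrt(dplyr::n()),
      mean_onset = mean(.data$t_onset),
      sem_onset = sd(.data$t_onset) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Effect-direction matrix versus a reference subgroup
#'
#' For every (subgroup, cytokine) cell: percent change of the mean effective
#' AUC versus the reference subgroup, a post-hoc two-sample t-test on the
#' per-animal AUCs, a direction call (`up` / `down` / `no_change`, where
#' `no_change` means |percent change| below `no_change_band` regardless of the
#' p-value), and a significance grade against `alpha_levels`. Outliers are
#' screened from each cell's AUCs by the IQR rule first.
#'
#' @param aucs Tibble with columns `subgroup`, `cytokine`, `auc_pg_min_ml`
#'   (one row per animal), e.g. the `aucs` component of [analyze_cohort()].
#' @param reference Reference subgroup label (must be present for every
#'   cytokine being compared).
#' @param config An [analysis_config()].
#' @return A `cyto_effects` tibble: `subgroup`, `cytokine`, `n`, `n_ref`,
#'   `pct_change`, `p_value`, `direction`, `significance`, `marker`
#'   (an up/down/diamond glyph with significance stars).
#' @export
effect_matrix <- function(aucs, reference, config = analysis_config()) {
  if (!reference %in% aucs$subgroup) {
    abort(paste0("reference subgroup not present: ", reference))
  }
  screen <- function(x) {
    if (length(x) >= 4 && is.finite(config$iqr_multiplier)) {
      remove_outliers_iqr(x, config)$kept
    } else x
  }
  cells <- aucs |>
    dplyr::distinct(.data$subgroup, .data$cytokine) |>
    dplyr::filter(.data$subgroup != reference)
  rows <- purrr::pmap(list(cells$subgroup, cells$cytokine), function(sg, cy) {
    ref <- screen(aucs$auc_pg_min_ml[aucs$subgroup == reference & aucs$cytokine == cy])
    grp <- screen(aucs$auc_pg_min_ml[aucs$subgroup == sg & aucs$cytokine == cy])
    if (length(ref) < 2) {
      abort(paste0("reference subgroup has <2 AUCs for cytokine ", cy))
    }
    pc <- pct_change(mean(grp), mean(ref))
    p <- if (length(grp) >= 2) ttest_two_sample(grp, ref, config)$p else NA_real_
    tibble::tibble(subgroup = sg, cytokine = cy, n = length(grp),
                   n_ref = length(ref), pct_change = pc, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (config$p_adjust_method != "none") {
    out$p_value <- p.adjust(out$p_value, method = config$p_adjust_method)
  }
  out$direction <- dplyr::case_when(
    abs(out$pct_change) < config$no_change_band ~ "no_change",
    out$pct_change > 0 ~ "up",
    TRUE ~ "down"
  )
  out$significance <- vapply(out$p_value, function(p) {
    if (is.na(p)) "none" else grade_significance(p, config$alpha_levels)
  }, character(1))
  stars <- c("none" = "", "p<0.1" = "#", "p<0.05" = "*", "p<0.01" = "**")
  glyph <- c(up = "↑", down = "↓", no_change = "♦")
  out$marker <- paste0(glyph[out$direction],
                       ifelse(out$direction == "no_change", "",
                              stars[out$significance]))
  class(out) <- c("cyto_effects", class(out))
  attr(out, "reference") <- reference
  attr(out, "no_change_band") <- config$no_change_band
  out
}

#' Render an effect matrix as a compact text table
#'
#' Rows are subgroups, columns cytokines; cells show an up/down/diamond glyph
#' with `#`/`*`/`**` significance markers (p < 0.1 / 0.05 / 0.01).
#'
#' @param effects A `cyto_effects` from [effect_matrix()].
#' @return Character vector of table lines (also printed).
#' @export
format_effect_matrix <- function(effects) {
  wide <- effects |>
    dplyr::select("subgroup", "cytokine", "marker") |>
    tidyr::pivot_wider(names_from = "cytokine", values_from = "marker")
  header <- sprintf("Effects vs %s (no-change band: |Δ| < %g%%)",
                    attr(effects, "reference"), attr(effects, "no_change_band"))
  widths <- pmax(nchar(names(wide)), vapply(wide, function(col)
    max(nchar(as.character(col)), 0L), integer(1)))
  fmt_row <- function(vals) paste(mapply(formatC, as.character(vals),
                                         width = widths), collapse = "  ")
  lines <- c(header, fmt_row(names(wide)),
             vapply(seq_len(nrow(wide)), function(i) fmt_row(wide[i, ]),
                    character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
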