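#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col geom_errorbar geom_tile geom_text labs theme_minimal
#'   scale_y_log10 facet_wrap
#' @export
ggplot2::autoplot

#' Plot a fitted curve with its source samples
#'
#' @param object A `cyto_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_curve <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$time_min, y = .data$value_pg_ml)) +
    geom_line(colour = "steelblue") +
    geom_point(data = tibble::tibble(time_min = object$sample_times,
                                     value_pg_ml = object$sample_values)) +
    labs(x = "Time after injection (min)", y = "Concentration (pg/mL)",
         title = paste(object$animal_id, object$cytokine, sep = " / ")) +
    theme_minimal()
}

#' Plot onset-aligned curves with the group mean and s.e.m. band
#'
#' Individual aligned curves in grey; mean across members with a +/- s.e.m.
#' ribbon on top. Time zero is the 5%-of-peak starting point.
#'
#' @param object A `cyto_aligned` from [align_set()].
#' @param log_scale Log-scale the concentration axis (useful when plotting
#'   cytokines of very different magnitudes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_aligned <- function(object, log_scale = FALSE, ...) {
  members <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    dplyr::mutate(object$aligned[[i]], animal_id = object$animal_id[i])
  }))
  band <- members |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(mean = mean(.data$value_pg_ml),
                     sem = sd(.data$value_pg_ml) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot(members, aes(x = .data$time_min, y = .data$value_pg_ml)) +
    geom_line(aes(group = .data$animal_id), colour = "grey70", linewidth = 0.3) +
    geom_ribbon(data = band,
                aes(x = .data$time_min, ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                inherit.aes = FALSE, fill = "steelblue", alpha = 0.3) +
    geom_line(data = band, aes(x = .data$time_min, y = .data$mean),
              inherit.aes = FALSE, colour = "steelblue", linewidth = 0.9) +
    labs(x = "Time after 5%-of-peak onset (min)",
         y = "Concentration above baseline (pg/mL)") +
    theme_minimal()
  if (log_scale) p <- p + scale_y_log10()
  p
}

#' Cascade-order plot: mean onset per cytokine with s.e.m. bars
#'
#' @param onset_summary Output of [onset_table()] (or the `onset_summary`
#'   component of a `cyto_analysis`).
#' @return A ggplot.
#' @export
plot_onset_summary <- function(onset_summary) {
  df <- dplyr::mutate(onset_summary,
                      cytokine = factor(.data$cytokine,
                                        levels = .data$cytokine))
  ggplot(df, aes(x = .data$cytokine, y = .data$mean_onset_min)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean_onset_min - .data$sem_onset_min,
                      ymax = .data$mean_onset_min + .data$sem_onset_min),
                  width = 0.25) +
    labs(x = NULL, y = "Elevation starting point (min after injection)") +
    theme_minimal()
}

#' Effect matrix heat-map
#'
#' Tiles coloured by direction (up / down / no change) and labelled with the
#' significance-marked glyphs.
#'
#' @param object A `cyto_effects` from [effect_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_effects <- function(object, ...) {
  ggplot(object, aes(x = .data$cytokine, y = .data$subgroup,
                     fill = .data$direction)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$marker)) +
    ggplot2::scale_fill_manual(values = c(up = "#7ba7d4", down = "#d47b7b",
                                          no_change = "#e8d47a")) +
    labs(x = NULL, y = NULL,
         title = paste("Effects vs", attr(object, "reference"))) +
    theme_minimal()
}
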