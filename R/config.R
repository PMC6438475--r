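#' Analysis configuration
#'
#' Bundles every tunable parameter of the onset/alignment/AUC chain. Defaults
#' reproduce the reference protocol: pass-through spline interpolation
#' (`smoothing_parameter = 1`), minute-resolution resampling, onset defined as
#' the time the baseline-corrected curve reaches 5% of its peak amplitude, and
#' Tukey's 1.5 x IQR outlier fence.
#'
#' @param onset_fraction Fraction of the peak above-baseline amplitude that
#'   defines the elevation starting point. Dimensionless, in (0, 1); default
#'   0.05 (the "5% of peak" rule).
#' @param smoothing_parameter Spline smoothing parameter in \[0, 1\]; 1 (the
#'   default) means a pure interpolant that preserves every sample value.
#'   Values < 1 blend toward a smoothing fit for sensitivity analysis.
#' @param resample_step Resolution of the fitted-curve grid, minutes; default 1.
#' @param prominence_fraction Minimum prominence of a candidate peak, as a
#'   fraction of the baseline-corrected curve's global range; default 0.2.
#'   Filters assay jitter out of the "first peak" rule.
#' @param baseline_mode `"subtract_baseline"` (default) corrects each curve by
#'   the mean of its pre-injection (t < 0) values before peak/onset logic;
#'   `"raw"` applies the 5% rule to uncorrected concentrations.
#' @param min_elevation_ratio A series only counts as elevated when its peak
#'   above-baseline amplitude is at least this multiple of the baseline level
#'   (default 1, i.e. the response must at least double the pre-injection
#'   concentration). This is the noise-floor criterion that excludes
#'   non-responders and reduces n; 0 disables it. Ignored when the baseline
#'   is zero or unavailable.
#' @param iqr_multiplier Tukey fence multiplier k: values outside
#'   \[Q1 - k IQR, Q3 + k IQR\] are outliers; default 1.5. `Inf` disables
#'   removal.
#' @param no_change_band Absolute percent-change below which a group effect is
#'   called "no change" regardless of p-value; default 15 (%).
#' @param alpha_levels Significance thresholds used to grade p-values;
#'   default `c(0.1, 0.05, 0.01)`.
#' @param p_adjust_method Multiple-testing correction applied to the effect
#'   matrix p-values; `"none"` (default, matching the single-comparison
#'   framing) or any [stats::p.adjust] method such as `"BH"`.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's test; default `FALSE`.
#'
#' @return An object of class `cyto_config`: a validated named list.
#' @examples
#' cfg <- analysis_config()
#' cfg$onset_fraction
#' @export
analysis_config <- function(onset_fraction = 0.05,
                            smoothing_parameter = 1,
                            resample_step = 1,
                            prominence_fraction = 0.2,
                            baseline_mode = c("subtract_baseline", "raw"),
                            min_elevation_ratio = 1,
                            iqr_multiplier = 1.5,
                            no_change_band = 15,
                            alpha_levels = c(0.1, 0.05, 0.01),
                            p_adjust_method = "none",
                            welch = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(
    "onset_fraction must be in (0, 1)" =
      is.numeric(onset_fraction) && length(onset_fraction) == 1 &&
      onset_fraction > 0 && onset_fraction < 1,
    "smoothing_parameter must be in (0, 1]" =
      is.numeric(smoothing_parameter) && smoothing_parameter > 0 &&
      smoothing_parameter <= 1,
    "resample_step must be > 0" = is.numeric(resample_step) && resample_step > 0,
    "prominence_fraction must be in [0, 1]" =
      prominence_fraction >= 0 && prominence_fraction <= 1,
    "min_elevation_ratio must be >= 0" = min_elevation_ratio >= 0,
    "iqr_multiplier must be >= 0" = iqr_multiplier >= 0,
    "no_change_band must be >= 0" = no_change_band >= 0,
    "alpha_levels must be probabilities" = all(alpha_levels > 0 & alpha_levels < 1)
  )
  structure(
    list(
      onset_fraction = onset_fraction,
      smoothing_parameter = smoothing_parameter,
      resample_step = resample_step,
      prominence_fraction = prominence_fraction,
      baseline_mode = baseline_mode,
      min_elevation_ratio = min_elevation_ratio,
      iqr_multiplier = iqr_multiplier,
      no_change_band = no_change_band,
      alpha_levels = sort(alpha_levels, decreasing = TRUE),
      p_adjust_method = p_adjust_method,
      welch = isTRUE(welch)
    ),
    class = "cyto_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the [analysis_config()] argument names; absent keys
#' keep their defaults and unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `cyto_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param config A `cyto_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cyto_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.cyto_config <- function(x, ...) {
  cat("<cyto_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
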