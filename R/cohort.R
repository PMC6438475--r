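#' Canonical cytokine panel
#'
#' The 13 analytes of the multiplex rat Th-cytokine panel the data model
#' normalizes names against. Unknown cytokine names elsewhere in the package
#' trigger a warning, never an error, so other panels still work.
#'
#' @return Character vector of 13 canonical cytokine names.
#' @export
cytokine_panel <- function() {
  c("IL-2", "IL-4", "IL-5", "IL-6", "IL-9", "IL-10", "IL-13",
    "IL-17A", "IL-17F", "IL-22", "GM-CSF", "IFN-g", "TNF-a")
}

# Map loose spellings (unicode greek, case, missing dash) to canonical names.
normalize_cytokine <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]+", "", x))
  key <- gsub("Α", "A", gsub("Γ", "G", key)) # capital alpha/gamma
  canon <- cytokine_panel()
  canon_key <- toupper(gsub("[^A-Za-z0-9]+", "", canon))
  # unicode alpha/gamma variants collapse onto the ascii forms
  alias <- c(
    "IFNγ" = "IFN-g", "IFNG" = "IFN-g", "IFNGAMMA" = "IFN-g",
    "TNFα" = "TNF-a", "TNFA" = "TNF-a", "TNFALPHA" = "TNF-a"
  )
  alias_key <- toupper(gsub("[^A-Za-z0-9]+", "", names(alias)))
  out <- x
  unknown <- character(0)
  for (i in seq_along(x)) {
    hit <- match(key[i], canon_key)
    if (!is.na(hit)) {
      out[i] <- canon[hit]
    } else {
      ahit <- match(key[i], alias_key)
      if (!is.na(ahit)) out[i] <- unname(alias[ahit]) else unknown <- c(unknown, x[i])
    }
  }
  if (length(unknown) > 0) {
    warn(paste0("cytokine name(s) not in the canonical 13-plex panel, kept as-is: ",
                paste(unique(unknown), collapse = ", ")))
  }
  out
}

#' Default blood-sampling schedule
#'
#' Twelve samples relative to the LPS injection at t = 0: one baseline draw at
#' -30 min, one at injection, then every 30 min out to 300 min. Times are
#' minutes; the injection is always time zero and baseline times are negative.
#'
#' @return Numeric vector of 12 sampling times (minutes).
#' @examples
#' default_schedule()
#' @export
default_schedule <- function() {
  seq(-30, 300, by = 30)
}

#' Validate a sampling schedule
#'
#' A schedule must be strictly increasing, contain at least 4 points, and
#' include at least one pre-injection (negative) time.
#'
#' @param times Numeric vector of sampling times in minutes.
#' @return `times`, invisibly, if valid; otherwise an error.
#' @export
validate_schedule <- function(times) {
  if (!is.numeric(times) || length(times) < 4) {
    abort("schedule must be numeric with at least 4 points")
  }
  if (any(diff(times) <= 0)) abort("schedule times must be strictly increasing")
  if (!any(times < 0)) abort("schedule must contain a baseline (t < 0) sample")
  invisible(times)
}

cohort_columns <- function() {
  c("animal_id", "subgroup", "cytokine", "time_min", "conc_pg_ml", "flag")
}

valid_flags <- function() c("ok", "below_floor", "saturated")

#' Construct a cohort table
#'
#' A cohort is a long tibble with one row per measurement and columns
#' `animal_id`, `subgroup`, `cytokine`, `time_min`, `conc_pg_ml`, `flag`
#' (flag in `ok`, `below_floor`, `saturated`). Rows are ordered by
#' (animal, cytokine, time) and the table carries dose/route/provenance
#' metadata as attributes.
#'
#' @param data Data frame with the cohort columns.
#' @param dose_mg_kg Endotoxin dose in mg/kg (metadata; default 5).
#' @param route Injection route label, `"IP"` or `"IV"` (metadata).
#' @param provenance Free-text provenance note (metadata).
#' @param validate Check invariants and fail on violations (default `TRUE`).
#' @return A `cyto_cohort` tibble.
#' @export
as_cohort <- function(data, dose_mg_kg = 5, route = "IP",
                      provenance = "unspecified", validate = TRUE) {
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing cohort column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)[, cohort_columns()]
  if (!is.numeric(out$time_min)) abort("time_min must be numeric")
  if (!is.numeric(out$conc_pg_ml)) {
    suppressWarnings(conv <- as.numeric(out$conc_pg_ml))
    if (anyNA(conv) && !anyNA(out$conc_pg_ml)) {
      bad <- which(is.na(conv))[1]
      abort(paste0("non-numeric concentration in row ", bad,
                   " (animal ", out$animal_id[bad], ", ", out$cytokine[bad],
                   ", t=", out$time_min[bad], ")"))
    }
    out$conc_pg_ml <- conv
  }
  out$animal_id <- as.character(out$animal_id)
  out$subgroup <- as.character(out$subgroup)
  out$cytokine <- normalize_cytokine(as.character(out$cytokine))
  out$flag <- as.character(out$flag)
  out <- dplyr::arrange(out, .data$animal_id, .data$cytokine, .data$time_min)
  attr(out, "dose_mg_kg") <- dose_mg_kg
  attr(out, "route") <- route
  attr(out, "provenance") <- provenance
  class(out) <- c("cyto_cohort", class(out))
  if (validate) {
    report <- validate_cohort(out)
    if (nrow(report) > 0) {
      abort(paste0("invalid cohort:\n  ",
                   paste(report$message, collapse = "\n  ")))
    }
  }
  out
}

#' Read a cohort from CSV
#'
#' Expects a UTF-8 CSV with header `animal_id, subgroup, cytokine, time_min,
#' conc_pg_ml, flag`. Rows are grouped into per-(animal, cytokine) series and
#' sorted by time; all data-model invariants are enforced.
#'
#' @param path CSV file path.
#' @inheritParams as_cohort
#' @return A validated `cyto_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, dose_mg_kg = 5, route = "IP",
                        provenance = NULL) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing cohort column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  suppressWarnings({
    time_num <- as.numeric(raw$time_min)
    conc_num <- as.numeric(raw$conc_pg_ml)
  })
  if (anyNA(time_num)) {
    abort(paste0("non-numeric time_min at row ", which(is.na(time_num))[1]))
  }
  if (anyNA(conc_num)) {
    bad <- which(is.na(conc_num))[1]
    abort(paste0("non-numeric concentration '", raw$conc_pg_ml[bad],
                 "' at row ", bad, " (animal ", raw$animal_id[bad], ")"))
  }
  raw$time_min <- time_num
  raw$conc_pg_ml <- conc_num
  as_cohort(raw, dose_mg_kg = dose_mg_kg, route = route,
            provenance = provenance %||% path)
}

#' Write a cohort to CSV
#'
#' One row per measurement, deterministic (animal, cytokine, time) row order,
#' so identical cohorts always produce byte-identical files.
#'
#' @param cohort A `cyto_cohort` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "cyto_cohort")) cohort <- as_cohort(cohort)
  out <- dplyr::arrange(tibble::as_tibble(cohort)[, cohort_columns()],
                        .data$animal_id, .data$cytokine, .data$time_min)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Report every data-model violation in a cohort
#'
#' Total reporting operation: it never raises, and returns an empty tibble
#' iff the cohort satisfies every invariant (complete columns, non-negative
#' concentrations, strictly increasing times with >= 4 points and a baseline
#' sample per series, unique (animal, cytokine) series, one shared schedule
#' per animal, known flags).
#'
#' @param cohort Data frame in cohort layout.
#' @return Tibble with columns `animal_id`, `cytokine`, `rule`, `message`;
#'   zero rows when valid.
#' @export
validate_cohort <- function(cohort) {
  empty <- tibble::tibble(animal_id = character(), cytokine = character(),
                          rule = character(), message = character())
  viol <- function(animal, cyt, rule, msg) {
    tibble::tibble(animal_id = animal, cytokine = cyt, rule = rule, message = msg)
  }
  out <- list()
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    return(viol(NA_character_, NA_character_, "columns",
                paste0("missing column(s): ", paste(missing_cols, collapse = ", "))))
  }
  df <- tibble::as_tibble(cohort)

  bad_flag <- !df$flag %in% valid_flags()
  if (any(bad_flag)) {
    out[[length(out) + 1]] <- viol(
      df$animal_id[bad_flag][1], df$cytokine[bad_flag][1], "flag",
      paste0("unknown flag value(s): ",
             paste(unique(df$flag[bad_flag]), collapse = ", ")))
  }
  neg <- which(df$conc_pg_ml < 0)
  for (i in head(neg, 5)) {
    out[[length(out) + 1]] <- viol(
      df$animal_id[i], df$cytokine[i], "conc_nonneg",
      paste0("negative concentration ", df$conc_pg_ml[i], " (animal ",
             df$animal_id[i], ", ", df$cytokine[i], ", t=", df$time_min[i], ")"))
  }

  by_series <- split(df, paste(df$animal_id, df$cytokine, sep = "\r"))
  for (s in by_series) {
    a <- s$animal_id[1]; c0 <- s$cytokine[1]
    tms <- s$time_min
    if (anyDuplicated(tms)) {
      out[[length(out) + 1]] <- viol(a, c0, "dup_time",
        paste0("duplicate time(s) ", paste(unique(tms[duplicated(tms)]), collapse = ", "),
               " for animal ", a, " / ", c0))
    }
    if (length(unique(tms)) < 4) {
      out[[length(out) + 1]] <- viol(a, c0, "min_points",
        paste0("series ", a, " / ", c0, " has fewer than 4 distinct times"))
    }
    if (!any(tms < 0)) {
      out[[length(out) + 1]] <- viol(a, c0, "baseline",
        paste0("series ", a, " / ", c0, " has no pre-injection (t < 0) sample"))
    }
    if (length(unique(s$subgroup)) > 1) {
      out[[length(out) + 1]] <- viol(a, c0, "subgroup",
        paste0("series ", a, " / ", c0, " spans multiple subgroups"))
    }
  }
  # all series of one animal share one schedule
  for (a in unique(df$animal_id)) {
    sub <- df[df$animal_id == a, ]
    scheds <- lapply(split(sub$time_min, sub$cytokine), function(t) sort(unique(t)))
    if (length(unique(vapply(scheds, paste, character(1), collapse = ","))) > 1) {
      out[[length(out) + 1]] <- viol(a, NA_character_, "schedule",
        paste0("animal ", a, " has differing schedules across cytokines"))
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Split a cohort into per-(animal, cytokine) series
#'
#' @param cohort A `cyto_cohort`.
#' @return Tibble nested by series: columns `animal_id`, `subgroup`,
#'   `cytokine`, and a list-column `data` of per-series tibbles
#'   (`time_min`, `conc_pg_ml`, `flag`) sorted by time.
#' @export
cohort_series <- function(cohort) {
  tibble::as_tibble(cohort) |>
    dplyr::arrange(.data$animal_id, .data$cytokine, .data$time_min) |>
    tidyr::nest(data = c("time_min", "conc_pg_ml", "flag"))
}

#' @export
print.cyto_cohort <- function(x, ...) {
  n_animal <- length(unique(x$animal_id))
  n_cyt <- length(unique(x$cytokine))
  cat(sprintf("<cyto_cohort> %d rows | %d animals x %d cytokines | dose %s mg/kg %s\n",
              nrow(x), n_animal, n_cyt,
              format(attr(x, "dose_mg_kg") %||% NA), attr(x, "route") %||% "?"))
  NextMethod()
}
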