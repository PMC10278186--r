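#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation; the
#' scale-free dispersion of replicate measurements.
#'
#' @param values Numeric vector of at least two finite values with non-zero
#'   mean.
#' @return CV in percent.
#' @export
cv <- function(values) {
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values))) {
    abort("CV needs >= 2 finite values.",
      class = "interlab_insufficient_data_error"
    )
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV undefined for zero-mean data.", class = "interlab_value_error")
  }
  100 * sd(values) / m
}

#' Intralab and interlab CV per condition
#'
#' Computes the coefficient of variation of a metric for every (strain,
#' regime, time) condition over the first seven hours of the assay, either
#' within each laboratory over its biological replicates (`intralab`) or over
#' all replicates of all laboratories (`interlab`). For `nrfu` the standard
#' strain PJ23100 is excluded: its uninduced nRFU is 1 by construction.
#'
#' @param records For metrics `nrfu`, `rfu`, `fu_bc`: normalized records from
#'   [normalize_plate_reader()]. For `spec_od730`: a dilution-corrected
#'   measurement table (the spectrophotometer OD730 rows are used).
#' @param metric One of `"nrfu"`, `"rfu"`, `"fu_bc"`, `"spec_od730"`.
#' @param scope `"intralab"` or `"interlab"`.
#' @param time_window Hours kept in the comparison (default first seven
#'   hours).
#' @return A tibble of CV records: `scope`, `laboratory` (`NA` for interlab),
#'   `metric`, `strain`, `regime`, `time_h`, `cv_percent`, `n`. Conditions
#'   with fewer than two values are skipped, with a message giving the count.
#' @export
cv_table <- function(records, metric = c("nrfu", "rfu", "fu_bc", "spec_od730"),
                     scope = c("intralab", "interlab"),
                     time_window = c(0, 2, 4, 5, 6, 7)) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  if (metric == "spec_od730") {
    df <- tibble::as_tibble(records) |>
      dplyr::filter(
        .data$device == "spectrophotometer", .data$channel == "OD730",
        !.data$is_blank
      ) |>
      dplyr::mutate(metric_value = .data$value)
  } else {
    df <- tibble::as_tibble(records)
    if (!metric %in% names(df)) {
      abort(
        sprintf("Records carry no '%s' column; run the normalization chain.",
          metric
        ),
        class = "interlab_schema_error"
      )
    }
    df <- dplyr::mutate(df, metric_value = .data[[metric]])
    if (metric == "nrfu") {
      df <- dplyr::filter(df, .data$strain != STANDARD_STRAIN)
    }
  }
  df <- dplyr::filter(df, .data$time_h %in% time_window)
  group_cols <- c(
    if (scope == "intralab") "laboratory", "strain", "regime", "time_h"
  )
  grouped <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      cv_percent = if (dplyr::n() >= 2) {
        100 * sd(.data$metric_value) / mean(.data$metric_value)
      } else {
        NA_real_
      },
      n = dplyr::n(), .groups = "drop"
    )
  skipped <- sum(is.na(grouped$cv_percent))
  if (skipped > 0) {
    inform(sprintf("Skipped %d group(s) with fewer than 2 values.", skipped))
  }
  grouped |>
    dplyr::filter(!is.na(.data$cv_percent)) |>
    dplyr::mutate(
      scope = .env$scope, metric = .env$metric,
      laboratory = if (.env$scope == "interlab") {
        NA_character_
      } else {
        .data$laboratory
      }
    ) |>
    dplyr::select(dplyr::all_of(c(
      "scope", "laboratory", "metric", "strain", "regime", "time_h",
      "cv_percent", "n"
    )))
}

#' Summarize a CV distribution
#'
#' @param cv_records Output of [cv_table()].
#' @param threshold_percent Reproducibility threshold; the fraction of
#'   conditions with CV strictly below it is reported.
#' @return A one-row tibble: `median_cv`, `fraction_below_threshold`,
#'   `n_groups`.
#' @export
summarize_cv <- function(cv_records, threshold_percent = 20) {
  if (nrow(cv_records) == 0) {
    abort("No CV records to summarize.",
      class = "interlab_insufficient_data_error"
    )
  }
  tibble::tibble(
    median_cv = median(cv_records$cv_percent),
    fraction_below_threshold =
      mean(cv_records$cv_percent < threshold_percent),
    n_groups = nrow(cv_records)
  )
}
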