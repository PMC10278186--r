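#' @section Normalization chain:
#' Plate-reader readings pass through a fixed sequence of stages:
#' blank subtraction, per-run minimum-FU offset, per-well RFU (FU per OD730),
#' technical-replicate averaging, and division by the internal biological
#' standard (the constitutive PJ23100 strain grown without inducer) to give
#' nRFU. Each stage tags its output; calling the stages out of order is an
#' error.
#' @name normalization
#' @keywords internal
NULL

stage_of <- function(x) attr(x, "stage") %||% "raw"

require_stage <- function(x, expected, fn) {
  st <- stage_of(x)
  if (!identical(st, expected)) {
    abort(
      sprintf(
        paste0(
          "%s() expects input at stage '%s' but got '%s'. The chain is ",
          "subtract_blanks -> apply_min_offset -> compute_rfu -> ",
          "average_technical -> normalize_internal_standard."
        ),
        fn, expected, st
      ),
      class = "interlab_stage_error"
    )
  }
}

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  x
}

#' Subtract plate-reader blank readings
#'
#' Every non-blank plate-reader value has the mean of the matching blank wells
#' (same laboratory, run, time point and channel) subtracted. Blank rows are
#' consumed; spectrophotometer rows pass through unchanged (those instruments
#' are blanked at measurement time).
#'
#' @param table A measurement table (dilution-corrected).
#' @return The blank-corrected measurement table, blanks removed.
#' @export
subtract_blanks <- function(table) {
  validate_measurements(table)
  require_stage(table, "raw", "subtract_blanks")
  df <- tibble::as_tibble(table)
  blank_means <- df |>
    dplyr::filter(.data$is_blank, .data$device == "plate_reader") |>
    dplyr::group_by(
      .data$laboratory, .data$run, .data$time_h, .data$channel
    ) |>
    dplyr::summarise(blank_mean = mean(.data$value), .groups = "drop")

  plate <- df |>
    dplyr::filter(!.data$is_blank, .data$device == "plate_reader") |>
    dplyr::left_join(blank_means,
      by = c("laboratory", "run", "time_h", "channel")
    )
  if (anyNA(plate$blank_mean)) {
    bad <- plate |>
      dplyr::filter(is.na(.data$blank_mean)) |>
      dplyr::distinct(
        .data$laboratory, .data$run, .data$time_h, .data$channel
      )
    abort(
      paste0(
        "No blank wells for: ",
        paste(
          sprintf(
            "%s run %d t=%gh %s", bad$laboratory, bad$run, bad$time_h,
            bad$channel
          ),
          collapse = "; "
        )
      ),
      class = "interlab_missing_blank_error"
    )
  }
  plate <- plate |>
    dplyr::mutate(value = .data$value - .data$blank_mean) |>
    dplyr::select(-"blank_mean")
  out <- dplyr::bind_rows(
    dplyr::filter(df, .data$device == "spectrophotometer", !.data$is_blank),
    plate
  )
  set_stage(retag(out, table), "blanked")
}

#' Shift fluorescence by the per-run minimum
#'
#' After blank subtraction some FU wells can be negative. Within each
#' (laboratory, run) group, let `m` be the smallest blank-corrected FU value
#' across all strains, regimes, time points and wells. The shipped rule adds
#' `-m` to every FU value of the group when `m < 0` (and nothing otherwise),
#' which fulfils the offset's purpose of removing negative fluorescence while
#' leaving all-positive groups untouched. `literal = TRUE` instead adds `m`
#' itself to every FU value — the verbatim reading of the protocol sentence —
#' for comparison against analyses that used it. OD730 values are never
#' shifted.
#'
#' @param table A blank-corrected measurement table.
#' @param literal Use the verbatim add-the-minimum rule instead of the
#'   add-if-negative rule.
#' @return The offset-shifted measurement table.
#' @export
apply_min_offset <- function(table, literal = FALSE) {
  require_stage(table, "blanked", "apply_min_offset")
  df <- tibble::as_tibble(table)
  offsets <- df |>
    dplyr::filter(.data$device == "plate_reader", .data$channel == "FU") |>
    dplyr::group_by(.data$laboratory, .data$run) |>
    dplyr::summarise(m = min(.data$value), .groups = "drop") |>
    dplyr::mutate(offset = if (literal) .data$m else pmax(-.data$m, 0))
  out <- df |>
    dplyr::left_join(offsets[, c("laboratory", "run", "offset")],
      by = c("laboratory", "run")
    ) |>
    dplyr::mutate(
      value = ifelse(
        .data$device == "plate_reader" & .data$channel == "FU" &
          !is.na(.data$offset),
        .data$value + .data$offset, .data$value
      )
    ) |>
    dplyr::select(-"offset")
  set_stage(retag(out, table), "offset")
}

#' Per-well relative fluorescence units
#'
#' Pairs the FU and OD730 readings of each plate well by its `tech_rep` index
#' and divides: `rfu = fu_bc / od_bc`, fluorescence per unit optical density.
#' Wells whose blank-corrected OD730 is not positive cannot be divided and are
#' dropped with a warning giving the count.
#'
#' @param table An offset-shifted measurement table.
#' @return A tibble with one row per well: coordinates, `tech_rep`, `fu_bc`,
#'   `od_bc`, `rfu`.
#' @export
compute_rfu <- function(table) {
  require_stage(table, "offset", "compute_rfu")
  df <- dplyr::filter(tibble::as_tibble(table), .data$device == "plate_reader")
  coords <- c("laboratory", "run", "strain", "regime", "time_h", "tech_rep")
  fu <- df |>
    dplyr::filter(.data$channel == "FU") |>
    dplyr::select(dplyr::all_of(coords), fu_bc = "value")
  od <- df |>
    dplyr::filter(.data$channel == "OD730") |>
    dplyr::select(dplyr::all_of(coords), od_bc = "value")
  wells <- dplyr::inner_join(fu, od, by = coords)
  bad <- wells$od_bc <= 0
  if (any(bad)) {
    warn(sprintf(
      "Dropping %d well(s) with non-positive blank-corrected OD730.",
      sum(bad)
    ))
    wells <- wells[!bad, ]
  }
  wells <- dplyr::mutate(wells, rfu = .data$fu_bc / .data$od_bc)
  set_stage(wells, "rfu")
}

#' Average technical replicates
#'
#' Arithmetic mean of the per-well `rfu` (and `fu_bc`, `od_bc`) over the
#' surviving wells of each biological replicate and time point.
#'
#' @param wells Per-well RFU tibble from [compute_rfu()].
#' @return A tibble with one row per (laboratory, run, strain, regime,
#'   time_h), carrying `od_bc`, `fu_bc`, `rfu` means and the well count `n`.
#' @export
average_technical <- function(wells) {
  require_stage(wells, "rfu", "average_technical")
  if (nrow(wells) == 0) {
    abort("No wells to average.", class = "interlab_integrity_error")
  }
  out <- wells |>
    dplyr::group_by(
      .data$laboratory, .data$run, .data$strain, .data$regime, .data$time_h
    ) |>
    dplyr::summarise(
      od_bc = mean(.data$od_bc), fu_bc = mean(.data$fu_bc),
      rfu = mean(.data$rfu), n = dplyr::n(), .groups = "drop"
    )
  set_stage(out, "averaged")
}

#' Normalize by the internal biological standard
#'
#' Divides each replicate's RFU by the RFU of the uninduced constitutive
#' PJ23100 culture of the same laboratory, run and time point, giving nRFU.
#' Because standard and sample share the plate reader, its gain and OD scale
#' cancel, making nRFU comparable across instruments. The standard's own nRFU
#' is exactly 1; the induced PJ23100 culture is normalized like any other.
#'
#' @param records Averaged records from [average_technical()].
#' @return A tibble of normalized records with an `nrfu` column.
#' @export
normalize_internal_standard <- function(records) {
  require_stage(records, "averaged", "normalize_internal_standard")
  std <- records |>
    dplyr::filter(
      .data$strain == STANDARD_STRAIN, .data$regime == STANDARD_REGIME
    ) |>
    dplyr::select(
      dplyr::all_of(c("laboratory", "run", "time_h")), std_rfu = "rfu"
    )
  out <- records |>
    dplyr::left_join(std, by = c("laboratory", "run", "time_h"))
  if (anyNA(out$std_rfu)) {
    bad <- out |>
      dplyr::filter(is.na(.data$std_rfu)) |>
      dplyr::distinct(.data$laboratory, .data$run, .data$time_h)
    abort(
      paste0(
        "No uninduced PJ23100 standard for: ",
        paste(sprintf("%s run %d t=%gh", bad$laboratory, bad$run, bad$time_h),
          collapse = "; "
        )
      ),
      class = "interlab_missing_standard_error"
    )
  }
  out <- out |>
    dplyr::mutate(
      nrfu = ifelse(
        .data$strain == STANDARD_STRAIN & .data$regime == STANDARD_REGIME,
        1, .data$rfu / .data$std_rfu
      )
    ) |>
    dplyr::select(-"std_rfu")
  set_stage(out, "normalized")
}

#' Run the full plate-reader normalization pipeline
#'
#' Convenience wrapper: dilution correction, exclusion of the unreliable 24 h
#' sample, then the fixed normalization chain.
#'
#' @param table A raw measurement table.
#' @param drop_hours Hours to exclude from the plate-reader analysis
#'   (default 24).
#' @param literal_offset Passed to [apply_min_offset()].
#' @return A tibble of normalized records with an `nrfu` column.
#' @export
normalize_plate_reader <- function(table, drop_hours = 24,
                                   literal_offset = FALSE) {
  out <- correct_dilution(table)
  if (length(drop_hours) > 0 && any(out$time_h %in% drop_hours)) {
    out <- exclude_timepoints(out, drop_hours)
  }
  out |>
    subtract_blanks() |>
    apply_min_offset(literal = literal_offset) |>
    compute_rfu() |>
    average_technical() |>
    normalize_internal_standard()
}

#' Chlorophyll-a concentration from methanol-extract absorbance
#'
#' Linear conversion of the 665 nm absorbance of a 100% methanol extract
#' (1 mL culture pelleted and resuspended in 1 mL methanol) to chlorophyll-a
#' concentration, using the methanol calibration coefficient of Ritchie
#' (2006). The coefficient ships in `inst/extdata/sim_defaults.yaml`.
#'
#' @param a665 Absorbance at 665 nm (>= 0); vectorized.
#' @param coef Micrograms chlorophyll-a per mL per absorbance unit.
#' @return Chlorophyll-a concentration in ug/mL.
#' @export
chlorophyll_from_a665 <- function(a665, coef = NULL) {
  if (any(a665 < 0)) {
    abort("Absorbance must be >= 0.", class = "interlab_value_error")
  }
  coef <- coef %||% sim_defaults()$chlorophyll$coef_ug_per_ml_per_a665
  coef * a665
}
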