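#' The standardized measurement sheet
#'
#' All raw data enter the pipeline as a long (tidy) table with one instrument
#' reading per row. The columns are, in order:
#'
#' * `laboratory` — free identifier of the participating laboratory (two
#'   operators in one institute count as two laboratories, e.g.
#'   `"Duesseldorf_I"` / `"Duesseldorf_II"`).
#' * `run` — biological replicate / experimental run, positive integer.
#' * `strain` — one of `EVC`, `PJ23100`, `PpetE`, `PrhaBAD`.
#' * `regime` — `induced` or `uninduced`. For `EVC` and `PJ23100` this labels
#'   the sham flask treatment (new vs washed flask), not an actual inducer.
#' * `time_h` — sampling time in hours since induction.
#' * `device` — `spectrophotometer` or `plate_reader`.
#' * `channel` — `OD730` or `FU` (fluorescence units; plate reader only).
#' * `tech_rep` — plate-reader well index (1..3); `NA` for the
#'   spectrophotometer, which reads one cuvette per sample.
#' * `dilution_factor` — the sample was diluted 1:`dilution_factor` before
#'   reading (1 = undiluted).
#' * `is_blank` — `TRUE` for medium-only blank wells; their `strain`/`regime`
#'   fields are present but carry no meaning.
#' * `value` — the raw instrument reading. Blank-unsubtracted readings may be
#'   any real number after instrument noise.
#'
#' @name measurement-table
#' @keywords internal
NULL

MEASUREMENT_COLS <- c(
  "laboratory", "run", "strain", "regime", "time_h", "device", "channel",
  "tech_rep", "dilution_factor", "is_blank", "value"
)

KEY_COLS <- c(
  "laboratory", "run", "strain", "regime", "time_h", "device", "channel",
  "tech_rep", "is_blank"
)

#' Assemble and validate a measurement table
#'
#' Coerces a data frame to the standardized column layout, validates it, and
#' attaches provenance. Most users get measurement tables from
#' [read_measurements()] or [generate_experiment()] instead.
#'
#' @param records Data frame with the columns described in
#'   [measurement-table].
#' @param provenance Free-text origin of the data (file path or generator
#'   description).
#' @return A tibble of class `interlab_measurements`.
#' @export
measurement_table <- function(records, provenance = "in-memory") {
  records <- tibble::as_tibble(records)
  missing <- setdiff(MEASUREMENT_COLS, names(records))
  if (length(missing) > 0) {
    abort(
      paste0("Missing measurement column(s): ", paste(missing, collapse = ", ")),
      class = "interlab_schema_error"
    )
  }
  records <- records[MEASUREMENT_COLS]
  records$run <- as.integer(records$run)
  records$tech_rep <- as.integer(records$tech_rep)
  records$time_h <- as.numeric(records$time_h)
  records$dilution_factor <- as.numeric(records$dilution_factor)
  records$is_blank <- as.logical(records$is_blank)
  records$value <- as.numeric(records$value)
  out <- new_measurement_table(records, provenance)
  validate_measurements(out)
  out
}

new_measurement_table <- function(records, provenance) {
  out <- tibble::as_tibble(records)
  class(out) <- c("interlab_measurements", class(tibble::tibble()))
  attr(out, "provenance") <- provenance
  out
}

# Re-tag a tibble produced by dplyr verbs from an existing table.
retag <- function(records, template) {
  new_measurement_table(records, attr(template, "provenance"))
}

#' Validate a measurement table
#'
#' Checks the structural invariants of the standardized sheet: known
#' vocabulary for strain/regime/device/channel, `tech_rep` present exactly for
#' plate-reader rows, positive dilution factors, uniqueness of the
#' experimental-coordinate key, non-emptiness, and a common time grid across
#' laboratories.
#'
#' @param table A measurement table.
#' @return Invisibly `TRUE`; aborts with a classed error otherwise.
#' @export
validate_measurements <- function(table) {
  if (nrow(table) == 0) {
    abort("Measurement table is empty.", class = "interlab_integrity_error")
  }
  check_enum <- function(col, allowed) {
    bad <- which(!(table[[col]] %in% allowed))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Unknown %s token '%s' at row %d (allowed: %s).",
          col, table[[col]][bad[1]], bad[1], paste(allowed, collapse = ", ")
        ),
        class = "interlab_value_error"
      )
    }
  }
  check_enum("strain", STRAINS)
  check_enum("regime", REGIMES)
  check_enum("device", DEVICES)
  check_enum("channel", CHANNELS)

  spec <- table$device == "spectrophotometer"
  if (any(!is.na(table$tech_rep[spec]))) {
    abort("Spectrophotometer rows must have tech_rep = NA.",
      class = "interlab_value_error"
    )
  }
  if (any(is.na(table$tech_rep[!spec]))) {
    abort("Plate-reader rows must have an integer tech_rep.",
      class = "interlab_value_error"
    )
  }
  if (any(spec & table$channel == "FU")) {
    abort("Spectrophotometer rows cannot carry the FU channel.",
      class = "interlab_value_error"
    )
  }
  if (any(is.na(table$dilution_factor) | table$dilution_factor <= 0)) {
    abort("dilution_factor must be a positive number.",
      class = "interlab_value_error"
    )
  }
  if (any(table$run < 1L, na.rm = TRUE)) {
    abort("run must be a positive integer.", class = "interlab_value_error")
  }

  key <- do.call(paste, c(table[KEY_COLS], sep = "\r"))
  if (anyDuplicated(key) > 0) {
    abort(
      sprintf(
        "Duplicate experimental coordinates at row %d.",
        which(duplicated(key))[1]
      ),
      class = "interlab_integrity_error"
    )
  }

  grids <- tapply(table$time_h, table$laboratory,
    function(x) paste(sort(unique(x)), collapse = ","),
    default = NA_character_
  )
  if (length(unique(grids)) > 1) {
    abort("All laboratories must share the same time grid.",
      class = "interlab_integrity_error"
    )
  }
  invisible(TRUE)
}

#' Read a standardized measurement sheet from CSV
#'
#' @param path Path to a CSV file whose header names every column of
#'   [measurement-table].
#' @return A validated measurement table with `provenance = path`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "interlab_io_error")
  }
  # warnings about absent columns are superseded by the schema check below
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      laboratory = readr::col_character(),
      run = readr::col_integer(),
      strain = readr::col_character(),
      regime = readr::col_character(),
      time_h = readr::col_character(),
      device = readr::col_character(),
      channel = readr::col_character(),
      tech_rep = readr::col_integer(),
      dilution_factor = readr::col_character(),
      is_blank = readr::col_logical(),
      value = readr::col_character()
    ),
    progress = FALSE
  ))
  # base strtod is correctly rounded; vroom's fast parser can be 1 ulp off
  for (col in intersect(c("time_h", "dilution_factor", "value"), names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  missing <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("CSV is missing column(s): ", paste(missing, collapse = ", ")),
      class = "interlab_schema_error"
    )
  }
  measurement_table(raw, provenance = path)
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: `read_measurements(write_measurements(t))`
#' reproduces `t` exactly.
#'
#' @param table A valid measurement table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  df <- tibble::as_tibble(table)[MEASUREMENT_COLS]
  # 17 significant digits round-trip IEEE doubles exactly.
  for (col in c("time_h", "dilution_factor", "value")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Undo sample dilution
#'
#' Samples were diluted before reading (1:2 for same-day spectrophotometer
#' readings, 1:5 at 24 h). All downstream analysis is written on
#' undiluted-equivalent values, so every non-blank reading is multiplied by its
#' dilution factor once, centrally, and the factor is reset to 1. Blank wells
#' are medium only and are never diluted. Idempotent after the first
#' application.
#'
#' @param table A measurement table.
#' @return The dilution-corrected measurement table.
#' @export
correct_dilution <- function(table) {
  validate_measurements(table)
  if (any(table$dilution_factor <= 0)) {
    abort("dilution_factor must be > 0.", class = "interlab_value_error")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    value = ifelse(.data$is_blank, .data$value,
      .data$value * .data$dilution_factor
    ),
    dilution_factor = ifelse(.data$is_blank, .data$dilution_factor, 1)
  )
  retag(out, table)
}

#' Drop sampling time points
#'
#' The plate-reader analysis excludes the 24 h sample: at 24 h dense cultures
#' exceeded the linear range of some plate readers while the 1:5 dilution put
#' sparse cultures below the sensitivity floor of others. Growth-rate fitting
#' keeps all time points and never calls this.
#'
#' @param table A measurement table.
#' @param drop Numeric vector of hours to remove.
#' @return The measurement table without the dropped hours.
#' @export
exclude_timepoints <- function(table, drop) {
  validate_measurements(table)
  out <- dplyr::filter(tibble::as_tibble(table), !(.data$time_h %in% drop))
  if (nrow(out) == 0) {
    abort("Dropping these time points empties the table.",
      class = "interlab_integrity_error"
    )
  }
  retag(out, table)
}
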