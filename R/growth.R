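#' @section Growth-rate estimation:
#' Growth rates come from the spectrophotometer OD730 series of each
#' biological replicate by ordinary least squares on the log-transformed
#' exponential growth model, `ln OD730(t) = mu * t + ln OD730(0)`. Unlike the
#' plate-reader analysis, growth fitting uses all time points including 24 h.
#' The slope is invariant to the instrument's OD scale, so growth rates are
#' comparable across laboratories even when their spectrophotometers are not.
#' @name growth
#' @keywords internal
NULL

#' Fit the growth rate of one biological replicate
#'
#' @param table A dilution-corrected measurement table.
#' @param laboratory,run,strain,regime Coordinates selecting one replicate.
#' @return A one-row tibble: coordinates, `mu` (h^-1), `ln_od0`, `r_squared`,
#'   `n_points`.
#' @export
fit_growth_rate <- function(table, laboratory, run, strain, regime) {
  df <- tibble::as_tibble(table) |>
    dplyr::filter(
      .data$device == "spectrophotometer", .data$channel == "OD730",
      !.data$is_blank,
      .data$laboratory == .env$laboratory, .data$run == .env$run,
      .data$strain == .env$strain, .data$regime == .env$regime
    )
  fit_loglinear(df$time_h, df$value, laboratory, run, strain, regime)
}

fit_loglinear <- function(time_h, od, laboratory, run, strain, regime) {
  if (length(od) < 3) {
    abort(
      sprintf(
        "Need >= 3 OD730 points to fit %s run %d %s/%s (got %d).",
        laboratory, run, strain, regime, length(od)
      ),
      class = "interlab_insufficient_data_error"
    )
  }
  if (any(od <= 0)) {
    abort(
      sprintf(
        "Non-positive OD730 in %s run %d %s/%s; cannot log-transform.",
        laboratory, run, strain, regime
      ),
      class = "interlab_value_error"
    )
  }
  fit <- lm(log(od) ~ time_h)
  # R^2 by hand: summary.lm() warns on noise-free (perfect) fits
  tss <- sum((log(od) - mean(log(od)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  tibble::tibble(
    laboratory = laboratory, run = run, strain = strain, regime = regime,
    mu = unname(coef(fit)[2]), ln_od0 = unname(coef(fit)[1]),
    r_squared = r2, n_points = length(od)
  )
}

#' Fit growth rates for every biological replicate
#'
#' @param table A dilution-corrected measurement table.
#' @return A tibble with one fit per (laboratory, run, strain, regime).
#' @export
fit_growth_rates <- function(table) {
  df <- tibble::as_tibble(table) |>
    dplyr::filter(
      .data$device == "spectrophotometer", .data$channel == "OD730",
      !.data$is_blank
    )
  if (nrow(df) == 0) {
    abort("No spectrophotometer OD730 records.",
      class = "interlab_insufficient_data_error"
    )
  }
  df |>
    dplyr::group_by(
      .data$laboratory, .data$run, .data$strain, .data$regime
    ) |>
    dplyr::group_modify(function(g, key) {
      fit_loglinear(
        g$time_h, g$value, key$laboratory, key$run, key$strain, key$regime
      )[, c("mu", "ln_od0", "r_squared", "n_points")]
    }) |>
    dplyr::ungroup()
}

#' Assay starting OD730 per laboratory
#'
#' Mean dilution-corrected spectrophotometer OD730 at t = 0 over all runs,
#' strains and regimes of each laboratory.
#'
#' @param table A dilution-corrected measurement table.
#' @return A tibble with columns `laboratory`, `od0`.
#' @export
initial_od_by_lab <- function(table) {
  df <- tibble::as_tibble(table) |>
    dplyr::filter(
      .data$device == "spectrophotometer", .data$channel == "OD730",
      !.data$is_blank, .data$time_h == 0
    )
  if (nrow(df) == 0) {
    abort("No t = 0 spectrophotometer records.",
      class = "interlab_insufficient_data_error"
    )
  }
  df |>
    dplyr::group_by(.data$laboratory) |>
    dplyr::summarise(od0 = mean(.data$value), .groups = "drop")
}

#' Normalize assay starting OD by the stock cross-calibration
#'
#' Each laboratory started its assay at OD730 0.5 on its own
#' spectrophotometer; instruments reading the same cells differently thus
#' started at different true biomass. Dividing the assay starting OD by the
#' laboratory's reading of the common glycerol-stock dilution gives a
#' dimensionless relative initial biomass that is comparable across
#' laboratories.
#'
#' @param initial_od Tibble with `laboratory`, `od0` (see
#'   [initial_od_by_lab()]).
#' @param stock_calibration Tibble with `laboratory`, `od730` readings of the
#'   common stock (see [generate_stock_calibration()]).
#' @return A tibble with `laboratory`, `rel_od0`.
#' @export
normalize_initial_od <- function(initial_od, stock_calibration) {
  stock <- stock_calibration |>
    dplyr::group_by(.data$laboratory) |>
    dplyr::summarise(stock_od = mean(.data$od730), .groups = "drop")
  missing <- c(
    setdiff(initial_od$laboratory, stock$laboratory),
    setdiff(stock$laboratory, initial_od$laboratory)
  )
  if (length(missing) > 0) {
    abort(
      paste0(
        "Laboratories present in only one input: ",
        paste(unique(missing), collapse = ", ")
      ),
      class = "interlab_value_error"
    )
  }
  out <- dplyr::inner_join(initial_od, stock, by = "laboratory") |>
    dplyr::mutate(rel_od0 = .data$od0 / .data$stock_od) |>
    dplyr::select(dplyr::all_of(c("laboratory", "rel_od0")))
  stopifnot(all(out$rel_od0 > 0))
  out
}

#' Correlate growth rate with relative initial biomass
#'
#' Pearson product-moment correlation (two-sided t-test) between the per-lab
#' mean growth rate and the relative initial OD, testing whether differences
#' in starting photon dose per cell explain growth-rate differences.
#'
#' @param mu_by_lab Tibble with `laboratory`, `mu` (per-lab mean growth rate).
#' @param rel_od0_by_lab Tibble with `laboratory`, `rel_od0`.
#' @return A one-row tibble: `pearson_r`, `p_value`, `n`.
#' @export
correlate_growth_initial_od <- function(mu_by_lab, rel_od0_by_lab) {
  df <- dplyr::inner_join(mu_by_lab, rel_od0_by_lab, by = "laboratory")
  if (nrow(df) < 3) {
    abort("Need >= 3 paired laboratories.",
      class = "interlab_insufficient_data_error"
    )
  }
  if (sd(df$mu) == 0 || sd(df$rel_od0) == 0) {
    abort("Zero variance in one input; correlation undefined.",
      class = "interlab_value_error"
    )
  }
  ct <- cor.test(df$mu, df$rel_od0, method = "pearson")
  tibble::tibble(
    pearson_r = unname(ct$estimate), p_value = ct$p.value, n = nrow(df)
  )
}
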