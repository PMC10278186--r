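#' @section Synthetic ring-trial generator:
#' The generator produces measurement tables with the hierarchical structure
#' of the interlaboratory experiment: laboratory-level effects (incubator
#' growth rate, instrument scale factors and backgrounds, residual copper),
#' run-level biological effects (starting biomass, realized growth rate,
#' per-cell expression), well-level technical effects, and per-record read
#' noise. All noise is multiplicative lognormal with mean 1, so values stay
#' positive and coefficients of variation are scale-free.
#' @name synthetic-data
#' @keywords internal
NULL

sim_defaults <- function() {
  yaml::read_yaml(
    system.file("extdata", "sim_defaults.yaml", package = "interlab",
      mustWork = TRUE
    )
  )
}

#' Laboratory ground-truth profile
#'
#' One row of generator-side truth for a laboratory: realized growth rate,
#' instrument transfer functions, plate-reader backgrounds, and the residual
#' copper multiplier acting on basal PpetE activity.
#'
#' @param laboratory Identifier.
#' @param mu Exponential growth rate (h^-1), > 0.
#' @param spec_scale Spectrophotometer OD730 units per true-biomass unit.
#' @param pr_od_scale Plate-reader OD730 units per true-biomass unit.
#' @param fu_gain Plate-reader fluorescence units per (per-cell signal x
#'   biomass).
#' @param od_blank,fu_blank Mean blank readings of the plate-reader OD730 and
#'   FU channels.
#' @param cu_residual Multiplier (>= 1) on basal PpetE activity from residual
#'   copper in the laboratory's medium.
#' @param temperature_C Incubation temperature, metadata only.
#' @return A one-row tibble.
#' @export
lab_profile <- function(laboratory, mu, spec_scale, pr_od_scale, fu_gain,
                        od_blank, fu_blank, cu_residual = 1,
                        temperature_C = 30) {
  stopifnot(mu > 0, spec_scale > 0, pr_od_scale > 0, fu_gain > 0,
    cu_residual >= 1
  )
  tibble::tibble(
    laboratory = laboratory, mu = mu, spec_scale = spec_scale,
    pr_od_scale = pr_od_scale, fu_gain = fu_gain, od_blank = od_blank,
    fu_blank = fu_blank, cu_residual = cu_residual,
    temperature_C = temperature_C
  )
}

#' Per-strain expression model
#'
#' Per-cell reporter signal in arbitrary per-cell units. The OFF state is
#' time-constant basal activity (times the laboratory's `cu_residual` for
#' PpetE); the ON state rises from basal to a plateau with saturating
#' first-order kinetics, lumping transcription, translation and fluorophore
#' maturation. EVC carries no reporter; PJ23100 is constitutive, so its
#' `f_basal` equals `f_induced`.
#'
#' @param strain One of `EVC`, `PJ23100`, `PpetE`, `PrhaBAD`.
#' @param f_basal Per-cell signal in the OFF state.
#' @param f_induced Per-cell signal plateau in the ON state.
#' @param k_ind First-order induction rate (h^-1).
#' @param autofluorescence Per-cell background signal common to all strains.
#' @return A one-row tibble.
#' @export
strain_model <- function(strain, f_basal, f_induced, k_ind,
                         autofluorescence = 1) {
  strain <- match.arg(strain, STRAINS)
  stopifnot(f_basal >= 0, f_induced >= f_basal, k_ind >= 0,
    autofluorescence >= 0
  )
  if (strain == "EVC" && (f_basal != 0 || f_induced != 0)) {
    abort("EVC carries no reporter: f_basal and f_induced must be 0.",
      class = "interlab_config_error"
    )
  }
  if (strain == "PJ23100" && f_basal != f_induced) {
    abort("PJ23100 is constitutive: f_basal must equal f_induced.",
      class = "interlab_config_error"
    )
  }
  tibble::tibble(
    strain = strain, f_basal = f_basal, f_induced = f_induced,
    k_ind = k_ind, autofluorescence = autofluorescence
  )
}

#' Default laboratory profiles and strain models
#'
#' Read from `inst/extdata/sim_defaults.yaml`; see that file for the
#' calibration rationale.
#' @return A tibble with one row per laboratory (or strain).
#' @export
default_lab_profiles <- function() {
  dplyr::bind_rows(lapply(sim_defaults()$lab_profiles, tibble::as_tibble))
}

#' @rdname default_lab_profiles
#' @export
default_strain_models <- function() {
  dplyr::bind_rows(lapply(sim_defaults()$strain_models, tibble::as_tibble))
}

#' Simulation configuration
#'
#' Bundles laboratory profiles, strain models, the replication design and the
#' noise levels of one simulated ring trial. Defaults emulate the study
#' design: 4 biological replicates (runs), 3 plate wells per sample, sampling
#' at 0, 2, 4, 5, 6, 7 and 24 h, cultures started at OD730 0.5 on the local
#' spectrophotometer.
#'
#' @param lab_profiles Tibble of [lab_profile()] rows; default
#'   [default_lab_profiles()].
#' @param strain_models Tibble of [strain_model()] rows; default
#'   [default_strain_models()].
#' @param n_runs Biological replicates per laboratory (>= 2).
#' @param n_tech Plate wells per sample.
#' @param time_grid Sampling times in hours.
#' @param cv_bio Run-level biological coefficient of variation (fraction);
#'   applied as independent lognormal perturbations of starting biomass,
#'   realized growth rate, and per-cell expression.
#' @param cv_tech Well-level technical CV (shared by both channels of a well).
#' @param cv_read Per-record instrument read-noise CV.
#' @param od_start_spec Target starting OD730 on the local spectrophotometer.
#' @param stock_biomass True biomass of the common glycerol-stock dilution
#'   used for instrument cross-calibration.
#' @param seed Integer seed; the generator is reproducible given the seed.
#' @return A list of class `interlab_sim_config`.
#' @export
simulation_config <- function(lab_profiles = default_lab_profiles(),
                              strain_models = default_strain_models(),
                              n_runs = NULL, n_tech = NULL, time_grid = NULL,
                              cv_bio = NULL, cv_tech = NULL, cv_read = NULL,
                              od_start_spec = NULL, stock_biomass = NULL,
                              seed = 1L) {
  d <- sim_defaults()$simulation
  cfg <- list(
    lab_profiles = tibble::as_tibble(lab_profiles),
    strain_models = tibble::as_tibble(strain_models),
    n_runs = as.integer(n_runs %||% d$n_runs),
    n_tech = as.integer(n_tech %||% d$n_tech),
    time_grid = as.numeric(time_grid %||% d$time_grid),
    cv_bio = cv_bio %||% d$cv_bio,
    cv_tech = cv_tech %||% d$cv_tech,
    cv_read = cv_read %||% d$cv_read,
    od_start_spec = od_start_spec %||% d$od_start_spec,
    stock_biomass = stock_biomass %||% d$stock_biomass,
    seed = as.integer(seed)
  )
  if (cfg$n_runs < 2) {
    abort("n_runs must be >= 2 (CVs need at least two replicates).",
      class = "interlab_config_error"
    )
  }
  if (any(c(cfg$cv_bio, cfg$cv_tech, cfg$cv_read) < 0)) {
    abort("Coefficients of variation must be >= 0.",
      class = "interlab_config_error"
    )
  }
  stopifnot(
    cfg$n_tech >= 1, cfg$od_start_spec > 0, cfg$stock_biomass > 0,
    nrow(cfg$lab_profiles) >= 1, nrow(cfg$strain_models) >= 1
  )
  structure(cfg, class = "interlab_sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean-1 lognormal noise multipliers at a given CV.
rln <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' True biomass of one culture over time
#'
#' Deterministic exponential growth from the laboratory's starting biomass.
#' Cultures are started at `od_start_spec` on the local spectrophotometer, so
#' true starting biomass is `od_start_spec / spec_scale`, times a run-level
#' multiplier; growth proceeds at `mu` times a run-level rate multiplier.
#'
#' @param profile One-row [lab_profile()] tibble.
#' @param config An [simulation_config()] object.
#' @param t Time(s) in hours.
#' @param start_multiplier,mu_multiplier Run-level perturbations (1 = none).
#' @return True biomass (arbitrary units) at each `t`.
#' @export
simulate_biomass <- function(profile, config, t, start_multiplier = 1,
                             mu_multiplier = 1) {
  stopifnot(all(t >= 0))
  (config$od_start_spec / profile$spec_scale) * start_multiplier *
    exp(profile$mu * mu_multiplier * t)
}

# Vectorized per-cell signal; shared by simulate_expression() and the
# generator so the two can never drift apart.
percell_signal <- function(strain, regime, f_basal, f_induced, k_ind,
                           autofluorescence, cu_residual, t) {
  off <- autofluorescence + f_basal * ifelse(strain == "PpetE", cu_residual, 1)
  on <- autofluorescence + f_basal + (f_induced - f_basal) *
    (1 - exp(-k_ind * t))
  ifelse(strain %in% c("EVC", "PJ23100") | regime == "uninduced", off, on)
}

#' Per-cell reporter signal over time
#'
#' @param model One-row [strain_model()] tibble.
#' @param profile One-row [lab_profile()] tibble (supplies `cu_residual`).
#' @param regime `"induced"` or `"uninduced"`; ignored for EVC and PJ23100.
#' @param t Time(s) in hours since induction.
#' @return Per-cell signal at each `t` (arbitrary per-cell units).
#' @export
simulate_expression <- function(model, profile, regime, t) {
  stopifnot(all(t >= 0))
  regime <- match.arg(regime, REGIMES)
  percell_signal(
    rep(model$strain, length(t)), rep(regime, length(t)), model$f_basal,
    model$f_induced, model$k_ind, model$autofluorescence,
    profile$cu_residual, t
  )
}

#' Generate a full synthetic ring-trial experiment
#'
#' For every (laboratory, run, strain, regime, time) the generator emits one
#' spectrophotometer OD730 reading (sample diluted 1:2, 1:5 at 24 h), `n_tech`
#' plate-reader OD730 wells and `n_tech` plate-reader FU wells (undiluted,
#' 1:5 at 24 h, with additive instrument background), plus `n_tech`
#' medium-only blank wells per (laboratory, run, time) and channel. The well
#' multiplier is shared between the OD730 and FU channels of a well, as both
#' read the same pipetted culture volume.
#'
#' @param config An [simulation_config()] object.
#' @return A list with `table` (a validated measurement table) and `truth`
#'   (the `lab_profiles`, `strain_models` and `config` that produced it), for
#'   parameter-recovery tests.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "interlab_sim_config"))
  if (config$n_runs < 2) {
    abort("n_runs must be >= 2.", class = "interlab_config_error")
  }
  labs <- config$lab_profiles
  strains <- config$strain_models
  withr::with_seed(config$seed, {
    run_fx <- tidyr::expand_grid(
      laboratory = labs$laboratory, run = seq_len(config$n_runs)
    )
    run_fx$start_mult <- rln(nrow(run_fx), config$cv_bio)
    run_fx$mu_mult <- rln(nrow(run_fx), config$cv_bio)

    expr_fx <- tidyr::expand_grid(
      laboratory = labs$laboratory, run = seq_len(config$n_runs),
      strain = strains$strain, regime = REGIMES
    )
    expr_fx$expr_mult <- rln(nrow(expr_fx), config$cv_bio)

    samples <- tidyr::expand_grid(
      laboratory = labs$laboratory, run = seq_len(config$n_runs),
      strain = strains$strain, regime = REGIMES, time_h = config$time_grid
    ) |>
      dplyr::left_join(labs, by = "laboratory") |>
      dplyr::left_join(strains, by = "strain") |>
      dplyr::left_join(run_fx, by = c("laboratory", "run")) |>
      dplyr::left_join(expr_fx,
        by = c("laboratory", "run", "strain", "regime")
      ) |>
      dplyr::mutate(
        biomass = (config$od_start_spec / .data$spec_scale) *
          .data$start_mult * exp(.data$mu * .data$mu_mult * .data$time_h),
        percell = percell_signal(
          .data$strain, .data$regime, .data$f_basal, .data$f_induced,
          .data$k_ind, .data$autofluorescence, .data$cu_residual,
          .data$time_h
        ) * .data$expr_mult
      )

    spec <- samples |>
      dplyr::mutate(
        dilution_factor = ifelse(.data$time_h == 24, 5, 2),
        value = .data$spec_scale * .data$biomass / .data$dilution_factor *
          rln(dplyr::n(), config$cv_read),
        device = "spectrophotometer", channel = "OD730",
        tech_rep = NA_integer_, is_blank = FALSE
      )

    wells <- tidyr::expand_grid(samples,
      tech_rep = seq_len(config$n_tech)
    ) |>
      dplyr::mutate(
        well_mult = rln(dplyr::n(), config$cv_tech),
        dilution_factor = ifelse(.data$time_h == 24, 5, 1),
        diluted = .data$biomass / .data$dilution_factor,
        device = "plate_reader", is_blank = FALSE
      )
    pr_od <- wells |>
      dplyr::mutate(
        channel = "OD730",
        value = .data$pr_od_scale * .data$diluted * .data$well_mult *
          rln(dplyr::n(), config$cv_read) +
          .data$od_blank * rln(dplyr::n(), config$cv_read)
      )
    pr_fu <- wells |>
      dplyr::mutate(
        channel = "FU",
        value = .data$fu_gain * .data$diluted * .data$percell *
          .data$well_mult * rln(dplyr::n(), config$cv_read) +
          .data$fu_blank * rln(dplyr::n(), config$cv_read)
      )

    blanks <- tidyr::expand_grid(
      laboratory = labs$laboratory, run = seq_len(config$n_runs),
      time_h = config$time_grid, channel = CHANNELS,
      tech_rep = seq_len(config$n_tech)
    ) |>
      dplyr::left_join(labs, by = "laboratory") |>
      dplyr::mutate(
        value = ifelse(.data$channel == "OD730", .data$od_blank,
          .data$fu_blank
        ) * rln(dplyr::n(), config$cv_read),
        strain = "EVC", regime = "uninduced", device = "plate_reader",
        dilution_factor = 1, is_blank = TRUE
      )

    records <- dplyr::bind_rows(spec, pr_od, pr_fu, blanks) |>
      dplyr::select(dplyr::all_of(MEASUREMENT_COLS)) |>
      dplyr::arrange(
        .data$laboratory, .data$run, .data$strain, .data$regime,
        .data$time_h, .data$device, .data$channel, .data$is_blank,
        .data$tech_rep
      )
    table <- measurement_table(
      records,
      provenance = sprintf("interlab::generate_experiment(seed = %d)",
        config$seed
      )
    )
    list(
      table = table,
      truth = list(
        lab_profiles = labs, strain_models = strains, config = config
      )
    )
  })
}

#' Generate glycerol-stock cross-calibration readings
#'
#' Emulates reading one common stock dilution (no growth allowed) on every
#' laboratory's spectrophotometer: each instrument reports its own scale times
#' the shared true biomass, so between-laboratory spread reflects instrument
#' differences only.
#'
#' @param config An [simulation_config()] object.
#' @return A tibble with columns `laboratory`, `strain`, `od730`.
#' @export
generate_stock_calibration <- function(config) {
  stopifnot(inherits(config, "interlab_sim_config"))
  labs <- config$lab_profiles
  withr::with_seed(config$seed + 1L, {
    out <- tidyr::expand_grid(
      laboratory = labs$laboratory,
      strain = config$strain_models$strain
    ) |>
      dplyr::left_join(labs[, c("laboratory", "spec_scale")],
        by = "laboratory"
      ) |>
      dplyr::mutate(
        od730 = .data$spec_scale * config$stock_biomass *
          rln(dplyr::n(), config$cv_read)
      ) |>
      dplyr::select(dplyr::all_of(c("laboratory", "strain", "od730")))
    out
  })
}

#' Expected row count of a generated experiment
#'
#' Bookkeeping helper: one spectrophotometer reading plus `2 * n_tech` plate
#' wells per sample, plus `2 * n_tech` blank wells per (laboratory, run,
#' time).
#'
#' @param config An [simulation_config()] object.
#' @return Integer row count.
#' @export
expected_row_count <- function(config) {
  n_lab <- nrow(config$lab_profiles)
  n_strain <- nrow(config$strain_models)
  n_time <- length(config$time_grid)
  n_lab * config$n_runs * n_strain * 2L * n_time * (1L + 2L * config$n_tech) +
    n_lab * config$n_runs * n_time * 2L * config$n_tech
}
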