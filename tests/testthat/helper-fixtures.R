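# Shared fixtures: all test data is built in code.

# Two small laboratories with distinct instruments and growth rates.
tiny_profiles <- function(fu_gain = c(500, 2500), spec_scale = c(1, 1.6),
                          mu = c(0.05, 0.04), cu_residual = c(1, 1)) {
  dplyr::bind_rows(
    lab_profile("LabA",
      mu = mu[1], spec_scale = spec_scale[1], pr_od_scale = 0.6,
      fu_gain = fu_gain[1], od_blank = 0.04, fu_blank = 50,
      cu_residual = cu_residual[1]
    ),
    lab_profile("LabB",
      mu = mu[2], spec_scale = spec_scale[2], pr_od_scale = 0.9,
      fu_gain = fu_gain[2], od_blank = 0.05, fu_blank = 80,
      cu_residual = cu_residual[2]
    )
  )
}

tiny_config <- function(seed = 1, noise_free = FALSE, ...) {
  args <- list(
    lab_profiles = tiny_profiles(), n_runs = 2, seed = seed, ...
  )
  if (noise_free) {
    args$cv_bio <- 0
    args$cv_tech <- 0
    args$cv_read <- 0
  }
  do.call(simulation_config, args)
}

# Build a small valid measurement table from partial row specs; unspecified
# fields get sensible defaults.
mk_table <- function(..., provenance = "test") {
  rows <- dplyr::bind_rows(...)
  defaults <- tibble::tibble(
    laboratory = "LabA", run = 1L, strain = "PJ23100", regime = "uninduced",
    time_h = 0, device = "plate_reader", channel = "FU", tech_rep = 1L,
    dilution_factor = 1, is_blank = FALSE, value = 1
  )
  for (col in names(defaults)) {
    if (!col %in% names(rows)) {
      rows[[col]] <- defaults[[col]]
    } else {
      rows[[col]][is.na(rows[[col]])] <- defaults[[col]]
    }
  }
  rows$tech_rep[rows$device == "spectrophotometer"] <- NA_integer_
  measurement_table(rows, provenance = provenance)
}

# One-lab, one-run plate-reader table: FU and OD wells for given strains at
# given times, plus matching blanks. Values are deterministic functions of
# the inputs so expectations can be written by hand.
plate_fixture <- function(strains = c("PJ23100", "PrhaBAD"),
                          regimes = "uninduced", times = c(0, 7),
                          fu = function(strain, regime, t, rep) 100,
                          od = function(strain, regime, t, rep) 0.4,
                          blank_fu = 20, blank_od = 0.05, n_tech = 2) {
  grid <- tidyr::expand_grid(
    strain = strains, regime = regimes, time_h = times,
    tech_rep = seq_len(n_tech)
  )
  sample_rows <- dplyr::bind_rows(
    dplyr::mutate(grid,
      channel = "FU",
      value = mapply(fu, strain, regime, time_h, tech_rep)
    ),
    dplyr::mutate(grid,
      channel = "OD730",
      value = mapply(od, strain, regime, time_h, tech_rep)
    )
  )
  blank_rows <- tidyr::expand_grid(
    time_h = times, channel = c("FU", "OD730"), tech_rep = 1L
  ) |>
    dplyr::mutate(
      strain = "EVC", regime = "uninduced", is_blank = TRUE,
      value = ifelse(channel == "FU", blank_fu, blank_od)
    )
  mk_table(sample_rows, blank_rows)
}

# Strip class and provenance/stage tags for pure-content comparison.
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  attr(x, "stage") <- NULL
  x
}

# Mean-1 lognormal noise, as the generator uses.
ln_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}
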