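test_that("blank subtraction removes the per-group mean blank", {
  tbl <- mk_table(
    tibble::tibble(value = c(100, 50, 60), tech_rep = 1:3),
    tibble::tibble(value = c(20, 20, 20), channel = "OD730",
      tech_rep = 1:3, is_blank = TRUE
    ),
    tibble::tibble(value = c(30, 40), tech_rep = 1:2, is_blank = TRUE),
    tibble::tibble(value = 0.7, device = "spectrophotometer",
      channel = "OD730"
    )
  )
  out <- subtract_blanks(tbl)
  fu <- dplyr::filter(out, channel == "FU")
  expect_equal(sort(fu$value), c(15, 25, 65)) # mean blank 35 subtracted
  expect_false(any(out$is_blank))
  expect_equal(
    dplyr::filter(out, device == "spectrophotometer")$value, 0.7
  )
})

test_that("missing blanks abort with the offending group named", {
  tbl <- mk_table(tibble::tibble(value = 100))
  err <- expect_error(subtract_blanks(tbl),
    class = "interlab_missing_blank_error"
  )
  expect_match(conditionMessage(err), "LabA run 1 t=0h FU")
})

test_that("minimum-FU offset: shipped rule lifts negatives, literal adds m", {
  blanked <- subtract_blanks(
    mk_table(
      tibble::tibble(value = c(-5, 0, 10), tech_rep = 1:3),
      tibble::tibble(value = c(0.2, 0.3, 0.4), channel = "OD730",
        tech_rep = 1:3
      ),
      tibble::tibble(value = 0, is_blank = TRUE),
      tibble::tibble(value = 0, is_blank = TRUE, channel = "OD730")
    )
  )
  shipped <- apply_min_offset(blanked)
  expect_equal(
    sort(dplyr::filter(shipped, channel == "FU")$value), c(0, 5, 15)
  )
  # OD730 untouched by the offset
  expect_equal(
    sort(dplyr::filter(shipped, channel == "OD730")$value), c(0.2, 0.3, 0.4)
  )
  literal <- apply_min_offset(blanked, literal = TRUE)
  expect_equal(
    sort(dplyr::filter(literal, channel == "FU")$value), c(-10, -5, 5)
  )

  # all-positive group is unchanged under the shipped rule
  pos <- blanked
  pos$value[pos$channel == "FU"] <- c(2, 4, 9)
  attr(pos, "stage") <- "blanked"
  expect_equal(apply_min_offset(pos)$value, pos$value)

  # single-value boundary: {-3} -> {0}
  single <- blanked[blanked$channel == "FU", ][1, ]
  single$value <- -3
  attr(single, "stage") <- "blanked"
  expect_equal(
    dplyr::filter(apply_min_offset(single), channel == "FU")$value, 0
  )
})

test_that("stage tags reject out-of-order normalization calls", {
  tbl <- generate_experiment(tiny_config())$table
  expect_error(apply_min_offset(tbl), class = "interlab_stage_error")
  expect_error(compute_rfu(tbl), class = "interlab_stage_error")
  blanked <- subtract_blanks(correct_dilution(tbl))
  expect_error(subtract_blanks(blanked), class = "interlab_stage_error")
  expect_error(compute_rfu(blanked), class = "interlab_stage_error")
  expect_error(normalize_internal_standard(blanked),
    class = "interlab_stage_error"
  )
})

test_that("RFU divides per-well fluorescence by per-well OD", {
  fu_vals <- c(`1` = 60, `2` = 90, `3` = 120)
  od_vals <- c(`1` = 0.3, `2` = 0.3, `3` = 0.4)
  tbl <- plate_fixture(
    strains = "PJ23100", times = 0, n_tech = 3,
    fu = function(s, r, t, rep) fu_vals[[as.character(rep)]] + 20,
    od = function(s, r, t, rep) od_vals[[as.character(rep)]] + 0.05,
    blank_fu = 20, blank_od = 0.05
  )
  wells <- compute_rfu(apply_min_offset(subtract_blanks(
    correct_dilution(tbl)
  )))
  expect_equal(sort(wells$rfu), c(200, 300, 300))

  avg <- average_technical(wells)
  expect_equal(avg$rfu, mean(c(200, 300, 300)))
  expect_equal(avg$n, 3L)

  # zero fluorescence gives zero RFU
  zero <- plate_fixture(
    strains = "PJ23100", times = 0, n_tech = 1,
    fu = function(s, r, t, rep) 20, od = function(s, r, t, rep) 0.45,
    blank_fu = 20, blank_od = 0.05
  )
  wells0 <- compute_rfu(apply_min_offset(subtract_blanks(
    correct_dilution(zero)
  )))
  expect_equal(wells0$rfu, 0)
})

test_that("wells with non-positive corrected OD are dropped with a warning", {
  tbl <- plate_fixture(
    strains = "PJ23100", times = 0, n_tech = 2,
    fu = function(s, r, t, rep) 100,
    od = function(s, r, t, rep) if (rep == 1) 0.02 else 0.45,
    blank_fu = 20, blank_od = 0.05
  )
  expect_warning(
    wells <- compute_rfu(apply_min_offset(subtract_blanks(
      correct_dilution(tbl)
    ))),
    "1 well"
  )
  expect_equal(nrow(wells), 1L)
})

test_that("technical averaging is a permutation-invariant mean", {
  tbl <- generate_experiment(tiny_config(seed = 2))$table
  wells <- compute_rfu(apply_min_offset(subtract_blanks(correct_dilution(
    exclude_timepoints(tbl, 24)
  ))))
  shuffled <- wells[sample(nrow(wells)), ]
  attr(shuffled, "stage") <- "rfu"
  a <- dplyr::arrange(
    average_technical(wells), laboratory, run, strain, regime, time_h
  )
  b <- dplyr::arrange(
    average_technical(shuffled), laboratory, run, strain, regime, time_h
  )
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("internal standard normalization divides by uninduced PJ23100", {
  tbl <- plate_fixture(
    strains = c("PJ23100", "PrhaBAD"), times = 0, n_tech = 1,
    fu = function(s, r, t, rep) if (s == "PJ23100") 0.45 * 250 + 20 else
      0.45 * 500 + 20,
    od = function(s, r, t, rep) 0.5,
    blank_fu = 20, blank_od = 0.05
  )
  norm <- normalize_plate_reader(tbl)
  expect_identical(norm$nrfu[norm$strain == "PJ23100"], 1)
  expect_equal(norm$nrfu[norm$strain == "PrhaBAD"], 2)
})

test_that("a missing internal standard is reported with coordinates", {
  tbl <- plate_fixture(strains = "PrhaBAD", times = c(0, 7))
  err <- expect_error(normalize_plate_reader(tbl),
    class = "interlab_missing_standard_error"
  )
  expect_match(conditionMessage(err), "LabA run 1 t=0h")
})

test_that("nRFU is invariant to laboratory-wise fluorescence gain", {
  tbl <- generate_experiment(tiny_config(seed = 9))$table
  norm1 <- normalize_plate_reader(tbl)
  gained <- tibble::as_tibble(tbl)
  sel <- gained$laboratory == "LabA" & gained$channel == "FU"
  gained$value[sel] <- gained$value[sel] * 37.5
  norm2 <- normalize_plate_reader(measurement_table(gained))
  expect_equal(norm2$nrfu, norm1$nrfu, tolerance = 1e-12)
})

test_that("noise-free nRFU equals the planted per-cell signal ratio", {
  cfg <- tiny_config(seed = 4, noise_free = TRUE)
  norm <- normalize_plate_reader(generate_experiment(cfg)$table)
  models <- cfg$strain_models
  std <- models[models$strain == "PJ23100", ]
  prof <- cfg$lab_profiles[1, ]
  for (strain in c("EVC", "PpetE", "PrhaBAD")) {
    for (regime in c("induced", "uninduced")) {
      got <- norm |>
        dplyr::filter(
          .data$laboratory == "LabA", .data$run == 1,
          .data$strain == .env$strain, .data$regime == .env$regime
        ) |>
        dplyr::arrange(.data$time_h)
      expected <- simulate_expression(
        models[models$strain == strain, ], prof, regime, got$time_h
      ) / simulate_expression(std, prof, "uninduced", got$time_h)
      expect_equal(got$nrfu, expected, tolerance = 1e-9)
    }
  }
})

test_that("chlorophyll conversion is linear with the shipped coefficient", {
  expect_equal(chlorophyll_from_a665(0), 0)
  expect_equal(chlorophyll_from_a665(0.5), 0.5 * 12.9447)
  expect_equal(chlorophyll_from_a665(2 * 0.3), 2 * chlorophyll_from_a665(0.3))
  expect_error(chlorophyll_from_a665(-0.1), class = "interlab_value_error")
})
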