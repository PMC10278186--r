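norm_fixture <- function(df) {
  # Minimal normalized-records tibble for metric unit tests.
  defaults <- tibble::tibble(
    laboratory = "LabA", run = 1L, strain = "PrhaBAD", regime = "induced",
    time_h = 0, od_bc = 0.4, fu_bc = 40, rfu = 100, nrfu = 1, n = 3L
  )
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  df
}

test_that("fold change divides the 7 h nRFU by the starting nRFU", {
  recs <- norm_fixture(tibble::tibble(
    time_h = c(0, 7, 0, 7), regime = rep(c("induced", "uninduced"), each = 2),
    nrfu = c(0.2, 0.6, 0.5, 0.5)
  ))
  fc <- fold_change_7h(recs)
  expect_equal(fc$fold_change[fc$regime == "induced"], 3)
  expect_equal(fc$fold_change[fc$regime == "uninduced"], 1)

  missing <- norm_fixture(tibble::tibble(time_h = 0, nrfu = 0.2))
  err <- expect_error(fold_change_7h(missing),
    class = "interlab_value_error"
  )
  expect_match(conditionMessage(err), "LabA run 1 PrhaBAD/induced")
})

test_that("relative strength restates induced 7 h nRFU in percent", {
  recs <- norm_fixture(tibble::tibble(
    time_h = c(7, 7, 7),
    strain = c("PrhaBAD", "PpetE", "PJ23100"),
    regime = "induced",
    nrfu = c(0.32, 1.06, 1.0)
  ))
  st <- relative_strength_7h(recs)
  expect_equal(st$strength_pct[st$strain == "PrhaBAD"], 32)
  expect_equal(st$strength_pct[st$strain == "PpetE"], 106)
  # does not pick up uninduced rows
  unind <- norm_fixture(tibble::tibble(
    time_h = 7, strain = "PrhaBAD", regime = "uninduced", nrfu = 0.9
  ))
  expect_equal(nrow(relative_strength_7h(unind)), 0L)
})

test_that("leakiness is the uninduced ratio to EVC, on rfu or nrfu alike", {
  recs <- norm_fixture(tibble::tibble(
    strain = c("EVC", "PrhaBAD", "PpetE"), regime = "uninduced", time_h = 7,
    rfu = c(100, 400, 840), nrfu = c(100, 400, 840) / 250
  ))
  lk <- leakiness_7h(recs)
  expect_equal(lk$leakiness[lk$strain == "PrhaBAD"], 4)
  expect_equal(lk$leakiness[lk$strain == "PpetE"], 8.4)
  lk2 <- leakiness_7h(recs, on = "nrfu")
  expect_equal(
    dplyr::arrange(lk2, strain)$leakiness,
    dplyr::arrange(lk, strain)$leakiness,
    tolerance = 1e-12
  )

  neg <- recs
  neg$rfu[neg$strain == "EVC"] <- 0
  expect_warning(out <- leakiness_7h(neg), "non-positive EVC")
  expect_equal(nrow(out), 0L)
})

test_that("a strain emitting only autofluorescence has leakiness 1", {
  models <- dplyr::bind_rows(
    strain_model("EVC", 0, 0, 0, autofluorescence = 1),
    strain_model("PJ23100", 10, 10, 0, autofluorescence = 1),
    strain_model("PrhaBAD", 0, 0, 0, autofluorescence = 1)
  )
  cfg <- simulation_config(
    lab_profiles = tiny_profiles(), strain_models = models,
    n_runs = 2, cv_bio = 0, cv_tech = 0, cv_read = 0, seed = 15
  )
  norm <- normalize_plate_reader(generate_experiment(cfg)$table)
  lk <- leakiness_7h(norm, strains = "PrhaBAD")
  expect_equal(lk$leakiness, rep(1, nrow(lk)), tolerance = 1e-9)
})

test_that("cross-laboratory summaries use lab means and a t interval", {
  per_rep <- tibble::tibble(
    laboratory = rep(c("L1", "L2", "L3"), each = 2),
    fold_change = c(0.9, 1.1, 1.9, 2.1, 2.9, 3.1)
  )
  s <- summarize_across_labs(per_rep, "fold_change")
  expect_equal(s$grand_mean, 2)
  half <- qt(0.975, df = 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(s$ci_low, 2 - half)
  expect_equal(s$ci_high, 2 + half)
  expect_equal(s$n_labs, 3L)
  expect_true(s$ci_low <= s$grand_mean && s$grand_mean <= s$ci_high)

  equal_means <- tibble::tibble(
    laboratory = c("L1", "L2"), fold_change = c(2, 2)
  )
  s0 <- summarize_across_labs(equal_means, "fold_change")
  expect_equal(s0$ci_low, s0$ci_high)

  expect_error(
    summarize_across_labs(
      tibble::tibble(laboratory = "L1", fold_change = 1:3), "fold_change"
    ),
    class = "interlab_insufficient_data_error"
  )
})

test_that("labs with identical growth distributions share a letter", {
  withr::local_seed(31)
  fits <- tibble::tibble(
    laboratory = rep(c("A", "B"), each = 16),
    strain = "EVC", regime = "uninduced",
    mu = 0.05 + rnorm(32, sd = 0.002)
  )
  cmp <- compare_groups(fits)
  expect_equal(unname(cmp$letters["A"]), unname(cmp$letters["B"]))
})

test_that("a clearly distinct lab gets its own letter; CLD matches multcomp", {
  withr::local_seed(32)
  fits <- tibble::tibble(
    laboratory = rep(c("A", "B", "C"), each = 12),
    strain = "EVC", regime = "uninduced",
    mu = rep(c(0.056, 0.055, 0.037), each = 12) + rnorm(36, sd = 0.002)
  )
  cmp <- compare_groups(fits, model = "one_way")
  expect_equal(unname(cmp$letters["A"]), unname(cmp$letters["B"]))
  expect_false(cmp$letters["C"] %in% cmp$letters[c("A", "B")])

  skip_if_not_installed("multcomp")
  fit <- aov(mu ~ laboratory, data = transform(
    as.data.frame(fits), laboratory = factor(laboratory)
  ))
  ref <- multcomp::cld(
    multcomp::glht(fit, linfct = multcomp::mcp(laboratory = "Tukey"))
  )$mcletters$Letters
  share <- function(l, a, b) {
    any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
  }
  for (a in c("A", "B", "C")) {
    for (b in setdiff(c("A", "B", "C"), a)) {
      expect_equal(
        share(cmp$letters, a, b), share(ref, a, b),
        info = paste(a, b)
      )
    }
  }
})

test_that("compact letters resolve overlap chains correctly", {
  # A-B and B-C not significant, A-C significant: B bridges with "ab".
  pw <- tibble::tibble(
    lab_a = c("A", "A", "B"), lab_b = c("B", "C", "C"),
    p_adj = c(0.6, 0.01, 0.4)
  )
  letters <- compact_letters(pw, c(A = 3, B = 2, C = 1))
  expect_equal(unname(letters), c("a", "ab", "b"))

  # all different: three distinct letters
  all_sig <- tibble::tibble(
    lab_a = c("A", "A", "B"), lab_b = c("B", "C", "C"), p_adj = 0.001
  )
  expect_equal(
    unname(compact_letters(all_sig, c(A = 3, B = 2, C = 1))),
    c("a", "b", "c")
  )

  # none different: everyone shares "a"
  none_sig <- tibble::tibble(
    lab_a = c("A", "A", "B"), lab_b = c("B", "C", "C"), p_adj = 0.9
  )
  expect_equal(
    unname(compact_letters(none_sig, c(A = 3, B = 2, C = 1))),
    c("a", "a", "a")
  )
})

test_that("three-factor ANOVA reports per-factor p-values", {
  tbl <- correct_dilution(generate_experiment(
    simulation_config(seed = 16, n_runs = 3,
      lab_profiles = tiny_profiles(mu = c(0.057, 0.037))
    )
  )$table)
  cmp <- compare_groups(fit_growth_rates(tbl))
  expect_named(cmp$anova_p, c("strain", "regime", "laboratory"))
  expect_lt(cmp$anova_p[["laboratory"]], 0.001)
  expect_false(cmp$letters[["LabA"]] == cmp$letters[["LabB"]])
})
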