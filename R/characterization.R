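#' @section Promoter characterization:
#' Three per-replicate metrics summarize an inducible promoter: the induction
#' fold change (nRFU at 7 h over nRFU at 0 h), the relative strength (nRFU at
#' 7 h of the induced culture, as a percentage of the constitutive PJ23100
#' standard), and the leakiness (RFU of the uninduced culture at 7 h relative
#' to the empty vector control; 1 means no detectable basal expression).
#' Cross-laboratory summaries average replicates within each laboratory first
#' and then treat laboratory means as the unit of replication.
#' @name characterization
#' @keywords internal
NULL

#' Induction fold change at 7 h
#'
#' Per biological replicate, divides the nRFU at seven hours by the nRFU at
#' the start of the assay, for both induction regimes.
#'
#' @param records Normalized records from [normalize_plate_reader()].
#' @param t_start,t_end Endpoint hours (defaults 0 and 7).
#' @return A tibble with one row per (laboratory, run, strain, regime) and a
#'   `fold_change` column.
#' @export
fold_change_7h <- function(records, t_start = 0, t_end = 7) {
  df <- tibble::as_tibble(records) |>
    dplyr::filter(.data$time_h %in% c(t_start, t_end)) |>
    dplyr::select(dplyr::all_of(
      c("laboratory", "run", "strain", "regime", "time_h", "nrfu")
    )) |>
    tidyr::pivot_wider(
      names_from = "time_h", values_from = "nrfu", names_prefix = "t"
    )
  start_col <- paste0("t", t_start)
  end_col <- paste0("t", t_end)
  for (col in c(start_col, end_col)) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  miss <- df[is.na(df[[start_col]]) | is.na(df[[end_col]]), ]
  if (nrow(miss) > 0) {
    abort(
      paste0(
        "Missing endpoint nRFU for replicate(s): ",
        paste(
          sprintf("%s run %s %s/%s", miss$laboratory, miss$run, miss$strain,
            miss$regime
          ),
          collapse = "; "
        )
      ),
      class = "interlab_value_error"
    )
  }
  if (any(df[[start_col]] <= 0)) {
    abort("Non-positive starting nRFU; fold change undefined.",
      class = "interlab_value_error"
    )
  }
  dplyr::mutate(df, fold_change = .data[[end_col]] / .data[[start_col]]) |>
    dplyr::select(dplyr::all_of(
      c("laboratory", "run", "strain", "regime", "fold_change")
    ))
}

#' Relative promoter strength at 7 h
#'
#' The nRFU of an induced culture at seven hours, expressed as a percentage
#' of the internal PJ23100 standard (which is 100% by construction).
#'
#' @param records Normalized records from [normalize_plate_reader()].
#' @param t_end Hour at which strength is read (default 7).
#' @return A tibble with one row per (laboratory, run, strain) of the induced
#'   regime and a `strength_pct` column.
#' @export
relative_strength_7h <- function(records, t_end = 7) {
  tibble::as_tibble(records) |>
    dplyr::filter(.data$regime == "induced", .data$time_h == t_end) |>
    dplyr::mutate(strength_pct = 100 * .data$nrfu) |>
    dplyr::select(dplyr::all_of(
      c("laboratory", "run", "strain", "strength_pct")
    ))
}

#' Promoter leakiness at 7 h
#'
#' Ratio of the uninduced culture's fluorescence per OD730 at seven hours to
#' the empty vector control of the same laboratory, run and (sham) regime.
#' A ratio of 1 means the strain emits nothing beyond cellular
#' autofluorescence. Because the internal-standard divisor is common to both
#' strains of a replicate, the ratio is identical whether computed on `rfu`
#' or on `nrfu`.
#'
#' @param records Normalized records from [normalize_plate_reader()].
#' @param strains Strains to assess (default the two inducible promoters).
#' @param on One of `"rfu"` or `"nrfu"` — the column the ratio is computed
#'   on; the result is the same up to floating-point error.
#' @param regime Sham/induction regime of both numerator and denominator
#'   cultures (default `"uninduced"`).
#' @param t_end Hour at which leakiness is read (default 7).
#' @return A tibble with one row per (laboratory, run, strain) and a
#'   `leakiness` column. Replicates whose EVC reading is not positive are
#'   dropped with a warning.
#' @export
leakiness_7h <- function(records, strains = c("PpetE", "PrhaBAD"),
                         on = c("rfu", "nrfu"), regime = "uninduced",
                         t_end = 7) {
  on <- match.arg(on)
  df <- tibble::as_tibble(records) |>
    dplyr::filter(.data$regime == .env$regime, .data$time_h == t_end)
  evc <- df |>
    dplyr::filter(.data$strain == "EVC") |>
    dplyr::select(
      dplyr::all_of(c("laboratory", "run")), evc_value = dplyr::all_of(on)
    )
  bad <- evc$evc_value <= 0
  if (any(bad)) {
    warn(sprintf("Dropping %d replicate(s) with non-positive EVC signal.",
      sum(bad)
    ))
    evc <- evc[!bad, ]
  }
  df |>
    dplyr::filter(.data$strain %in% strains) |>
    dplyr::inner_join(evc, by = c("laboratory", "run")) |>
    dplyr::mutate(leakiness = .data[[on]] / .data$evc_value) |>
    dplyr::select(dplyr::all_of(
      c("laboratory", "run", "strain", "leakiness")
    ))
}

#' Cross-laboratory summary of a per-replicate metric
#'
#' Averages the metric over the runs of each laboratory, then reports the
#' grand mean over laboratory means with a 95% confidence interval based on
#' the t distribution with `n_labs - 1` degrees of freedom — laboratories,
#' not replicates, are the unit of replication for interlaboratory claims.
#'
#' @param per_replicate Tibble with columns `laboratory` and the metric.
#' @param value Name of the metric column.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `grand_mean`, `ci_low`, `ci_high`, `n_labs`,
#'   plus a list-column `per_lab` of laboratory means.
#' @export
summarize_across_labs <- function(per_replicate, value, conf_level = 0.95) {
  per_lab <- per_replicate |>
    dplyr::group_by(.data$laboratory) |>
    dplyr::summarise(
      lab_mean = mean(.data[[value]]), n_runs = dplyr::n(), .groups = "drop"
    )
  n_labs <- nrow(per_lab)
  if (n_labs < 2) {
    abort("Need >= 2 laboratories for a cross-laboratory summary.",
      class = "interlab_insufficient_data_error"
    )
  }
  grand <- mean(per_lab$lab_mean)
  half <- qt(1 - (1 - conf_level) / 2, df = n_labs - 1) *
    sd(per_lab$lab_mean) / sqrt(n_labs)
  tibble::tibble(
    grand_mean = grand, ci_low = grand - half, ci_high = grand + half,
    n_labs = n_labs, per_lab = list(per_lab)
  )
}

#' Compare growth rates between laboratories
#'
#' Fits an ANOVA on the per-replicate growth rates — by default the
#' three-factor main-effects model (strain + regime + laboratory) — then runs
#' Tukey's HSD on the laboratory factor at `alpha` and condenses the pairwise
#' results into a compact letter display: laboratories sharing a letter do
#' not differ significantly.
#'
#' @param fits Growth fits from [fit_growth_rates()].
#' @param model `"three_factor"` (strain + regime + laboratory) or
#'   `"one_way"` (laboratory only).
#' @param alpha Significance level for the Tukey comparisons.
#' @return A list of class `interlab_group_comparison`: `anova_p` (named
#'   per-factor p-values), `tukey` (pairwise tibble), `group_means`,
#'   `letters` (named character vector).
#' @export
compare_groups <- function(fits, model = c("three_factor", "one_way"),
                           alpha = 0.05) {
  model <- match.arg(model)
  df <- tibble::as_tibble(fits)
  if (dplyr::n_distinct(df$laboratory) < 2) {
    abort("Need >= 2 laboratories.",
      class = "interlab_insufficient_data_error"
    )
  }
  df$laboratory <- factor(df$laboratory)
  form <- if (model == "three_factor" &&
    dplyr::n_distinct(df$strain) > 1 && dplyr::n_distinct(df$regime) > 1) {
    mu ~ strain + regime + laboratory
  } else {
    mu ~ laboratory
  }
  fit <- aov(form, data = df)
  av <- summary(fit)[[1]]
  factors <- trimws(rownames(av))
  anova_p <- stats::setNames(
    av[["Pr(>F)"]][factors != "Residuals"],
    factors[factors != "Residuals"]
  )
  tk <- TukeyHSD(fit, which = "laboratory")$laboratory
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble::tibble(
    lab_a = vapply(pairs, `[`, "", 1),
    lab_b = vapply(pairs, `[`, "", 2),
    diff = tk[, "diff"], p_adj = tk[, "p adj"]
  )
  group_means <- tapply(df$mu, df$laboratory, mean)
  letters <- compact_letters(tukey, group_means, alpha = alpha)
  structure(
    list(
      anova_p = anova_p, tukey = tukey,
      group_means = group_means[order(-group_means)], letters = letters
    ),
    class = "interlab_group_comparison"
  )
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb assignment of letters to groups so that two groups share
#' a letter exactly when their pairwise comparison is not significant at
#' `alpha`. Groups are processed in descending order of their mean, so the
#' letter `a` always marks the top group; absorbed (redundant) letter sets
#' are removed.
#'
#' @param pairwise Tibble with columns `lab_a`, `lab_b`, `p_adj`.
#' @param group_means Named numeric vector of group means (defines ordering).
#' @param alpha Significance level.
#' @return Named character vector mapping each group to its letters.
#' @export
compact_letters <- function(pairwise, group_means, alpha = 0.05) {
  groups <- names(sort(group_means, decreasing = TRUE))
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$lab_a[i]
    b <- pairwise$lab_b[i]
    if (pairwise$p_adj[i] < alpha) {
      sig[a, b] <- TRUE
      sig[b, a] <- TRUE
    }
  }
  # Each column of `sets` is one letter: membership flags per group.
  sets <- matrix(TRUE, nrow = k, ncol = 1, dimnames = list(groups, NULL))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (!sig[groups[i], groups[j]]) next
        violating <- which(sets[i, ] & sets[j, ])
        if (length(violating) == 0) next
        # Split each violating letter into two: one without each member.
        new_cols <- do.call(cbind, lapply(violating, function(col) {
          new1 <- sets[, col]
          new1[j] <- FALSE
          new2 <- sets[, col]
          new2[i] <- FALSE
          cbind(new1, new2)
        }))
        sets <- cbind(sets[, -violating, drop = FALSE], new_cols)
        # Absorb: drop letters whose membership is a subset of another's,
        # and deduplicate identical letters.
        keep <- rep(TRUE, ncol(sets))
        for (c1 in seq_len(ncol(sets))) {
          for (c2 in seq_len(ncol(sets))) {
            if (c1 == c2 || !keep[c1] || !keep[c2]) next
            if (all(sets[, c1] <= sets[, c2]) &&
              (any(sets[, c1] < sets[, c2]) || c1 > c2)) {
              keep[c1] <- FALSE
            }
          }
        }
        sets <- sets[, keep, drop = FALSE]
      }
    }
  }
  # Order letters by the first (highest-mean) group they contain.
  first_member <- apply(sets, 2, function(m) which(m)[1])
  sets <- sets[, order(first_member), drop = FALSE]
  labels <- vapply(seq_len(nrow(sets)), function(i) {
    paste(letters[which(sets[i, ])], collapse = "")
  }, "")
  stats::setNames(labels, groups)
}

#' @export
print.interlab_group_comparison <- function(x, ...) {
  cat("ANOVA p-values:\n")
  print(signif(x$anova_p, 4))
  cat("\nLaboratory means (descending) and compact letters:\n")
  out <- data.frame(
    mean_mu = signif(unname(x$group_means), 4),
    letters = unname(x$letters[names(x$group_means)])
  )
  rownames(out) <- names(x$group_means)
  print(out)
  invisible(x)
}
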