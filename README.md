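# interlab

Analysis pipeline for interlaboratory (ring-trial) reporter-gene assays in
the cyanobacterium *Synechocystis* sp. PCC 6803, paired with a synthetic
multi-laboratory data generator so every stage is testable without external
data.

## The problem and who this is for

When several laboratories run the same promoter-characterization protocol,
the raw numbers disagree for two very different reasons: biology (incubators
and media really do change growth and expression) and instruments
(spectrophotometers and plate readers report incompatible OD and
fluorescence scales). This package is for synthetic biologists and
biostatisticians who need to separate the two — to quantify how reproducible
an assay is within and across laboratories, and to characterize promoters on
a scale that transfers between instruments.

## What it computes

For long-format measurement tables (spectrophotometer OD730 plus
plate-reader OD730/fluorescence, with blanks and dilution factors):

* **Internal-standard normalization.** Blank correction, a per-run
  minimum-fluorescence offset, per-well RFU = FU<sub>bc</sub> /
  OD730<sub>bc</sub>, technical-replicate averaging, then
  **nRFU = RFU / RFU(P<sub>J23100</sub>, uninduced)** — division by a
  constitutively expressing strain measured in the same laboratory, run and
  time point. Instrument gain cancels exactly, making results comparable
  across plate readers without external calibrants.
* **Growth rates** per biological replicate by OLS on
  ln OD730(t) = μt + ln OD730(0), with ANOVA and a Tukey compact-letter
  display across laboratories, plus a stock-calibration check that growth
  differences are not explained by different true starting biomass.
* **Reproducibility** as coefficients of variation (100·sd/mean) per
  (strain, regime, time) condition, at intralab and interlab scope, with
  median CV and fraction below 20%.
* **Promoter metrics**: induction fold change (nRFU 7 h / nRFU 0 h),
  relative strength (% of P<sub>J23100</sub> at 7 h), and leakiness
  (uninduced RFU relative to the empty vector control), each summarized
  across laboratories with a t-based 95% CI on laboratory means.
* **Synthetic ring trials** (`generate_experiment()`): hierarchical
  lognormal noise (run / well / read), laboratory-specific growth rates and
  instrument transfer functions, saturating induction kinetics, residual
  copper effects on basal P<sub>petE</sub> activity — with ground truth
  returned for parameter-recovery tests.

See `vignettes/interlab-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(interlab)
library(dplyr)

cfg   <- simulation_config(seed = 2026)   # the default study design
trial <- generate_experiment(cfg)         # 9 operator datasets, ~16k rows
norm  <- normalize_plate_reader(trial$table)
fits  <- fit_growth_rates(correct_dilution(trial$table))

compare_groups(fits)
#> ANOVA p-values:
#>     strain     regime laboratory
#>  9.238e-01  7.450e-01 1.689e-149
#>
#> Laboratory means (descending) and compact letters:
#>                mean_mu letters
#> Tuebingen      0.05724       a
#> Seville        0.05603      ab
#> Amsterdam      0.05541      ab
#> Jena           0.05461       b
#> Edinburgh      0.04896       c
#> Berlin         0.04501       d
#> Duesseldorf_I  0.03946       e
#> Duesseldorf_II 0.03738       f
#> Leipzig        0.03464       g
```

Only the laboratory factor moves growth rates (p ≈ 1e-149; strain and
regime are null, as designed), and the letters split the fast incubator
group (~0.055–0.057 h⁻¹) from the slow one (~0.035–0.039 h⁻¹).

```r
fold_change_7h(norm) |>
  filter(strain == "PrhaBAD", regime == "induced") |>
  summarize_across_labs("fold_change")
#>   grand_mean ci_low ci_high n_labs
#> 1       2.34   2.28    2.40      9

leakiness_7h(norm) |>
  filter(strain == "PrhaBAD") |>
  summarize_across_labs("leakiness")
#>   grand_mean ci_low ci_high n_labs
#> 1       1.57   1.53    1.60      9

summarize_cv(cv_table(norm, "nrfu", "interlab"))
#>   median_cv fraction_below_threshold n_groups
#> 1      8.37                    0.833       36
```

Induced P<sub>rhaBAD</sub> rises 2.3-fold over 7 h and leaks ~1.6× above
the empty vector control; the interlab nRFU CV has a median of 8.4% across
the 36 (strain, regime, time) conditions, with 83% of conditions below the
20% reproducibility threshold. All three numbers recover the values planted
in the generator's defaults.

A thin command-line wrapper for validation, generation, normalization,
growth fitting and CV tables is in `inst/scripts/interlab.R`.

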