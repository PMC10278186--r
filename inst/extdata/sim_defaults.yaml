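# Default calibration for the synthetic ring-trial generator and for the
# chlorophyll conversion. Laboratory growth rates span the printed range of
# the study (0.035-0.058 h^-1, fast and slow incubator groups); the
# spectrophotometer scale factors span a 5-fold range, as observed when the
# same stock dilution was read on every instrument; plate-reader OD scales
# and fluorescence gains vary widely between device models; cu_residual > 1
# marks laboratories whose medium retained copper, driving basal PpetE
# activity. Strain models are solved so the noise-free pipeline returns a
# PrhaBAD leakiness of 1.6, induction fold change 2.35 and relative strength
# 32% of PJ23100, and a PpetE fold change 2.87 and strength 106%.
# These are simulation defaults, not claims about any laboratory.
chlorophyll:
  coef_ug_per_ml_per_a665: 12.9447
simulation:
  n_runs: 4
  n_tech: 3
  time_grid: [0.0, 2.0, 4.0, 5.0, 6.0, 7.0, 24.0]
  cv_bio: 0.05
  cv_tech: 0.05
  cv_read: 0.03
  od_start_spec: 0.5
  stock_biomass: 0.25
lab_profiles:
  - {laboratory: Amsterdam,      mu: 0.056, spec_scale: 1.00, pr_od_scale: 0.60, fu_gain: 800.0,  od_blank: 0.040, fu_blank: 60.0,  cu_residual: 1.0, temperature_C: 30.0}
  - {laboratory: Berlin,         mu: 0.046, spec_scale: 0.55, pr_od_scale: 0.35, fu_gain: 250.0,  od_blank: 0.035, fu_blank: 25.0,  cu_residual: 1.2, temperature_C: 30.0}
  - {laboratory: Duesseldorf_I,  mu: 0.039, spec_scale: 1.30, pr_od_scale: 0.80, fu_gain: 1300.0, od_blank: 0.050, fu_blank: 90.0,  cu_residual: 1.0, temperature_C: 30.0}
  - {laboratory: Duesseldorf_II, mu: 0.037, spec_scale: 1.25, pr_od_scale: 0.80, fu_gain: 1300.0, od_blank: 0.050, fu_blank: 90.0,  cu_residual: 1.0, temperature_C: 30.0}
  - {laboratory: Edinburgh,      mu: 0.050, spec_scale: 0.40, pr_od_scale: 0.30, fu_gain: 200.0,  od_blank: 0.030, fu_blank: 20.0,  cu_residual: 1.5, temperature_C: 30.0}
  - {laboratory: Jena,           mu: 0.057, spec_scale: 2.00, pr_od_scale: 1.50, fu_gain: 2000.0, od_blank: 0.060, fu_blank: 140.0, cu_residual: 2.0, temperature_C: 30.0}
  - {laboratory: Leipzig,        mu: 0.035, spec_scale: 0.80, pr_od_scale: 0.50, fu_gain: 450.0,  od_blank: 0.040, fu_blank: 40.0,  cu_residual: 1.0, temperature_C: 30.0}
  - {laboratory: Seville,        mu: 0.058, spec_scale: 1.60, pr_od_scale: 1.00, fu_gain: 1600.0, od_blank: 0.055, fu_blank: 110.0, cu_residual: 4.2, temperature_C: 30.0}
  - {laboratory: Tuebingen,      mu: 0.057, spec_scale: 0.95, pr_od_scale: 0.55, fu_gain: 700.0,  od_blank: 0.045, fu_blank: 55.0,  cu_residual: 7.0, temperature_C: 30.0}
strain_models:
  - {strain: EVC,     f_basal: 0.0,   f_induced: 0.0,      k_ind: 0.0,  autofluorescence: 1.0}
  - {strain: PJ23100, f_basal: 10.75, f_induced: 10.75,    k_ind: 0.0,  autofluorescence: 1.0}
  - {strain: PpetE,   f_basal: 3.34,  f_induced: 11.98044, k_ind: 0.40, autofluorescence: 1.0}
  - {strain: PrhaBAD, f_basal: 0.6,   f_induced: 2.96400,  k_ind: 0.35, autofluorescence: 1.0}
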