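# muscleqmri

Multi-parametric quantitative muscle MRI analysis for neuromuscular
disease, with a fully synthetic, ground-truthed lower-limb phantom.

In muscular dystrophies such as FKRP-related limb-girdle muscular dystrophy
(LGMD-R9), muscle is progressively replaced by fat. Natural-history imaging
studies therefore track two families of biomarkers per muscle: markers of
**disease progression** — fat fraction FF = fat/(water+fat)·100 and the
contractile cross-sectional area cCSA = (1 − 0.01·FF)·CSA — and markers of
**disease activity** that can move before fat appears: water T2, water T1,
the diffusion-tensor metrics (λ₁ ≥ λ₂ ≥ λ₃, MD = tr(D)/3, FA), and
intramuscular pH read from the pH-dependent chemical shift of the carnosine
C2H proton relative to water. `muscleqmri` implements the full processing
chain behind such a panel, for methodologists and analysts who need every
stage testable without patient data:

- **`synth_phantom`** — seedable elliptical-cylinder lower-limb phantom with
  per-muscle ground truth and forward models for every modality
  (`phantom_config()`, `generate_dixon_series()`, `generate_mse_series()`,
  `generate_dti_series()`, `generate_fingerprint_series()`,
  `generate_spectrum()`).
- **`dixon`** — three-point Dixon fat–water separation with a single-peak
  fat spectrum and a single T2* decay, field-map regularization against
  fat–water swaps, FF / CSA / cCSA (`separate_fat_water()`, `compute_ff()`,
  `compute_csa()`, `compute_ccsa()`).
- **`water_t2`** — tri-exponential fitting of 17-echo spin-echo decays
  (one free water component, fixed two-component fat), with the strict
  T2 ∈ (15, 70) ms and B1⁺ ∈ (80 %, 120 %) exclusion gates
  (`fit_triexponential()`, `fit_t2_map()`, `apply_t2_exclusions()`).
- **`water_t1_fingerprint`** — dictionary generation and exhaustive
  magnetic-resonance-fingerprinting matching for water T1 with FF and B1 as
  nuisance axes, FF > 60 % exclusion (`build_dictionary()`,
  `match_fingerprint()`, `match_t1_map()`, `apply_t1_exclusion()`).
- **`dti_dofs`** — local-PCA noise/SNR estimation, Dixon-based olefinic
  fat suppression across readout shifts, b-matrix handling, nonlinear
  tensor fit, diffusion-time bookkeeping (TM + 16.3 ms), and all DTI
  exclusion rules (`estimate_noise_and_snr()`, `dofs_decompose()`,
  `fit_tensor()`, `process_dti_series()`, `apply_dti_exclusions()`).
- **`mrs_ph`** — carnosine C2H peak location and Henderson–Hasselbalch pH,
  pH = pKa + log₁₀((δ_acid − δ)/(δ − δ_base)), with the FF > 30 % omission
  rule (`locate_peaks()`, `estimate_ph()`, `apply_mrs_omission()`).
- **`roi_stats`** — per-muscle aggregation with the < 50-voxel rule,
  pixel-weighted global/group averages, bilateral merging, longitudinal
  Δ and the standardized response mean SRM = mean(Δ)/SD(Δ), Spearman
  correlations with qualitative bands, Bonferroni levels, and tidy
  CSV/JSON export of the long-format record table
  (`aggregate_muscle()`, `weighted_average()`, `delta_over_time()`,
  `standardized_response_mean()`, `spearman_correlation()`,
  `export_long_table()`).

Imaging I/O is NIfTI-1 (via RNifti); spectra travel as JSON/CSV; record
tables as CSV with a JSON exclusion ledger. Results carry broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## Worked example

Generate a noisy (SNR 40) phantom, separate fat and water, and aggregate
per muscle:

```r
library(muscleqmri)

cfg   <- phantom_config(sigma = 1/40, seed = 42)
truth <- phantom_ground_truth(cfg)
fw    <- separate_fat_water(generate_dixon_series(cfg, truth),
                            mask = truth$labels > 0)
fw$ff
#> <quantitative_map: ff [%]> 64 x 64 x 5
#>   8760 valid voxels (42.8%); range 0 .. 65.9, median 19.8
#>   exclusions: undefined=11720

records <- aggregate_muscle(fw$ff, as_muscle_label_map(truth),
                            subject = "phantom-01")
dplyr::select(records, muscle, side, mean_value, n_voxels, excluded)
#> # A tibble: 8 × 5
#>   muscle side  mean_value n_voxels excluded
#>   <chr>  <chr>      <dbl>    <int> <lgl>
#> 1 TA     L           2.04     1095 FALSE
#> 2 SOL    L          10.0      1095 FALSE
#> 3 GM     L          30.0      1095 FALSE
#> 4 PER    L          60.1      1095 FALSE
#> 5 TA     R           2.01     1095 FALSE
#> 6 SOL    R          10.0      1095 FALSE
#> 7 GM     R          30.0      1095 FALSE
#> 8 PER    R          60.0      1095 FALSE

weighted_average(records, "global_leg")
#> [1] 25.51799
```

The true per-muscle fat fractions are 2/10/30/60 %, so the fitted means are
within a few hundredths of a point of truth at SNR 40; the global-leg value
is the pixel-weighted mean across all eight muscles. Combining with muscle
cross-sectional areas gives contractile area, e.g. for the right tibialis
anterior (true CSA ≈ 219 mm², FF ≈ 2 %):

```r
csa <- compute_csa(truth$labels, cfg$spacing)
compute_ccsa(csa$csa_mm2[5], records$mean_value[5])
#> [1] 214.6031
```

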