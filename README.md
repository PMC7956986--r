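# hrvagree

Simulated validation of wearable heart-rate and HRV devices against
reference ECG.

## The problem

Consumer wearables — chest-strap ECGs, phone-camera photoplethysmography
(PPG) apps, smart rings — report resting heart rate (HR, bpm) and rMSSD
(ms), the root-mean-square of successive differences between heartbeat
intervals and the standard short-term index of parasympathetic activity.
How much to trust those numbers is an empirical question, answered by
method-comparison studies that pair each device reading with a criterion
value derived from multi-lead ECG. `hrvagree` implements that entire
comparison pipeline as tested R functions, plus a synthetic-data
generator that replaces the human subjects, so every estimator in the
chain can be verified against known injected truth.

The pipeline stages:

1. **Ground truth** — RR-interval series from a modulation model
   `RR(t) = RR₀ + A_LF sin(2πf_LF t) + A_HF sin(2πf_HF t) + A_VLF sin(2πf_VLF t) + ε`,
   calibrated by bisection against its closed-form rMSSD so a requested
   target (e.g. 50 ms) is hit within ~10% across seeds.
2. **Reference signal** — ECG rendered at 512 Hz (QRS templates + noise at a
   chosen SNR), re-detected with a Pan–Tompkins style detector (band-pass
   5–15 Hz, derivative, squaring, 150 ms integration, adaptive dual
   thresholds, 200 ms refractory, search-back).
3. **Metrics** — epoch segmentation on half-open 3/5-min windows;
   smoothing-priors detrending, trend `(I + λ²D₂ᵀD₂)⁻¹z` with λ = 400
   (half-power cutoff ≈ 0.039 Hz at the 4 Hz effective rate);
   `rMSSD = √mean((ΔRR)²)`; mean HR `60000/mean(RR)`; windowed minimum HR
   for ring-type devices.
4. **Agreement** — per device/metric: absolute percent error
   `APE = |dev − ref|/ref × 100`; single-pass Tukey outer-fence removal
   (beyond Q3 + 3·IQR or Q1 − 3·IQR, type-7 quartiles); MAPE summaries;
   Lin's concordance `CCC = 2s_xy/(s_x² + s_y² + (x̄ − ȳ)²)`;
   Bland–Altman `bias ± 1.96·SD` limits of agreement with the 1986
   confidence-interval recipe; Bonferroni-corrected paired t-tests of
   zero bias.

Everything takes and returns tidy data frames; results come with
`tidy()`, `glance()`, `autoplot()` (Bland–Altman panels) and
`plot_ape_box()` methods.

## Worked example

Simulate the default study — 5 subjects, 148 trials, a 7-device panel
ranging from a near-perfect chest strap to a camera-PPG app — and run the
full agreement analysis:

```r
library(hrvagree)

study  <- generate_study(study_design(master_seed = 42))
report <- run_validation(study)
glance(report)
#> # A tibble: 1 × 5
#>   n_pairs n_outliers n_devices n_significant_bias n_group_errors
#>     <int>      <int>     <int>              <int>          <int>
#> 1     275          0         7                  3              0

report$ape[report$ape$metric == "rMSSD",
           c("device_label", "n", "mape_pct", "median_pct", "iqr_pct")]
#> # A tibble: 7 × 5
#>   device_label     n mape_pct median_pct iqr_pct
#> 1 HRV4TR/ECG      21     5.81       6.09    4.17
#> 2 ELT/PPG         21    11.6        7.95   15.8
#> 3 OURA            21    13.0       13.0     9.52
#> 4 HRV4TR/PPG      21    21.2       19.1    19.9
#> 5 ELT/ECG         21    22.0       19.0    22.7
#> 6 FSTBT           22    23.8       24.5    24.7
#> 7 CAMHRV          21   144.       150.    175.
```

148 trials produce 275 device–reference pairs rather than 296 because the
ring device reports a minimum, not a mean, HR and so contributes no HR
pair. The rMSSD APE table is sorted ascending by MAPE: the ECG-coupled
app recovers rMSSD to ~6% while the camera-PPG app misses by >100%,
and the concordance table tells the same story
(`report$ccc`: CCC 0.96 for the best device down to 0.04 for the worst).
`report$ba` holds the Bland–Altman biases, limits of agreement and
Bonferroni-adjusted p-values; `autoplot(report, metric = "rMSSD")` draws
the per-device Bland–Altman grid, and `write_report(report, "out/")`
emits the five CSV tables plus a full-precision `report.json`.

A command-line wrapper with `simulate` / `analyze` / `report`
subcommands lives at `inst/cli/hrvagree.R`.

## Scope

Frequency-domain HRV (LF/HF power, total power), SDNN, PPG optics
(wavelength and skin-tone physics), device firmware/Bluetooth emulation
and mixed-effects modelling of within-subject correlation are out of
scope. See `vignettes/device-agreement.Rmd` for the models, conventions,
design decisions and limitations in full.
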