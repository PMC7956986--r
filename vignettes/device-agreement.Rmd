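---
title: "Validating wearable HR and HRV devices in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable HR and HRV devices in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvagree)
```

## The problem this package addresses

Consumer wearables — chest-strap ECGs, finger-camera photoplethysmography
(PPG) apps, smart rings — report resting heart rate (HR) and the
root-mean-square of successive differences (rMSSD), the standard
time-domain index of vagally mediated heart-rate variability. Their
accuracy against a criterion electrocardiogram varies enormously between
devices, and validation studies quantify that accuracy with a standard
statistical suite: per-trial absolute percent error (APE) with extreme
outliers removed by the Tukey outer fence, mean APE (MAPE) summaries,
Lin's concordance correlation coefficient (CCC), Bland–Altman limits of
agreement (LOA), and Bonferroni-corrected paired bias tests.

`hrvagree` implements that whole chain as tested, composable functions,
together with a synthetic-data generator that plays the role of the human
subjects: it simulates ground-truth RR-interval series, renders reference
ECG, and corrupts device readings with controllable error models. Every
statistical claim the pipeline makes can therefore be checked against
known injected truth, which is impossible with raw study data alone.

## The ground-truth RR generator

The generator uses a direct modulation model. With base interval
$\mathrm{RR}_0 = 60000 / \mathrm{HR}$ (ms), the interval ending a beat at
time $t$ is

$$\mathrm{RR}(t) = \mathrm{RR}_0
  + A_\mathrm{LF}\sin(2\pi f_\mathrm{LF} t)
  + A_\mathrm{HF}\sin(2\pi f_\mathrm{HF} t)
  + A_\mathrm{VLF}\sin(2\pi f_\mathrm{VLF} t)
  + \varepsilon,\qquad \varepsilon\sim N(0,\sigma^2),$$

and beat times accumulate as $t_{i+1} = t_i + \mathrm{RR}(t_i)/1000$.
Defaults place the modulation at the band centres of short-term HRV
analysis: $f_\mathrm{LF} = 0.10$ Hz, $f_\mathrm{HF} = 0.25$ Hz, and a slow
$f_\mathrm{VLF} = 0.015$ Hz drift that the detrending step is meant to
remove. This is deliberately *not* an integral-pulse-frequency-modulation
model: the simpler form has a closed-form rMSSD, which is what makes the
generator calibratable. A sinusoid of amplitude $A$ and frequency $f$
sampled at beats $\bar T$ seconds apart contributes
$2A^2\sin^2(\pi f \bar T)$ to the mean squared successive difference and
the white component contributes $2\sigma^2$, so

$$\mathrm{rMSSD}^2 \approx 2\sigma^2
  + \sum_k 2A_k^2 \sin^2(\pi f_k \bar T).$$

`simulate_rr_series()` reaches a requested `rmssd_target_ms` by jointly
rescaling the HF amplitude and the jitter SD, with the scale factor found
by root bisection against this closed form; the LF and VLF components are
left untouched because they represent trend, not beat-to-beat
variability. If the untouched components alone exceed the target the
generator raises an explicit calibration-failure error rather than
silently under-shooting. Across seeds the realized rMSSD stays within
about 10% of the target and the realized mean HR within 2% of the
configured rate — both properties are asserted in the test suite.

## Reference ECG and R-peak detection

`render_ecg()` places a Ricker (Mexican-hat) wavelet of 80 ms nominal
width and 1 mV peak at every beat time on a uniform grid (512 Hz by
default, the rate of the reference recorder the study design emulates)
and adds white noise at a requested SNR. A single channel stands in for a
multi-lead montage; lead placement is a physical concern, not a
computational one, and any sharp biphasic template exercises a QRS
detector equally well. P and T waves, baseline wander and motion artifact
of real hardware are *not* modelled — a detector that passes these tests
has been shown to work on idealized morphology plus stationary noise,
nothing more.

`detect_r_peaks()` follows the classic Pan–Tompkins stages: zero-phase
5–15 Hz band-pass, derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with a 200 ms refractory period,
and a search-back pass at half threshold when the running RR average
suggests a missed beat. Detections are refined to the local extremum of
the band-passed signal so reported times align with the R wave. The
zero-phase filtering makes detection invariant to DC offset and keeps
clean-signal timing error within a couple of sample periods; on rendered
signals at 10 dB SNR the detector holds sensitivity and positive
predictivity at or above 99%.

Commercial analysis software performs the equivalent reference step in
real studies; the detector here is the de-facto standard choice for that
role, since validation studies rarely disclose the proprietary algorithm
actually used.

## Epochs and HRV metrics

Trials are 3 or 5 minutes (180 or 300 s), matching common device
recording windows; `segment_by_timestamps()` keeps beats in the half-open
window $[t_0, t_0 + d)$ so a boundary beat is never counted in two
adjacent epochs, and recomputes intervals from retained beats only.
Intervals outside a physiologic gate of 300–2000 ms are flagged for
per-trial exclusion, never interpolated: no ectopic-correction step is
assumed.

Very-low-frequency trend is removed with the smoothing-priors estimator:
the trend is $(I + \lambda^2 D_2^\top D_2)^{-1} z$ for the beat-indexed
interval sequence $z$, with $D_2$ the second-difference operator, and the
detrended series is $z$ minus that trend. The default $\lambda = 400$,
interpreted at a 4 Hz effective rate (the convention of the
smoothing-priors HRV literature), gives a half-power cutoff of
$\approx 0.039$ Hz — below the LF band, so LF and HF variability pass
through while slow drift is removed. `detrend_cutoff_frequency()`
evaluates the closed-form response
$G(\omega) = \lambda^2 a(\omega)/(1+\lambda^2 a(\omega))$,
$a(\omega) = 16\sin^4(\omega/2)$. Numerically the solve uses the Woodbury
identity on the $(n-2)$-sized system, which stays well conditioned even
for $\lambda \to 10^8$ (where the result provably converges to ordinary
least-squares line residuals — a test oracle). Dense solves are fine at
epoch scale (≤ ~600 beats); a banded factorization would be an
optimization, not a contract.

Metric conventions, each a documented knob:

* **rMSSD** $= \sqrt{\operatorname{mean}\big((\Delta \mathrm{RR})^2\big)}$,
  computed on the detrended sequence in the reference pipeline; the raw
  value is always reported alongside.
* **Mean HR** $= 60000/\operatorname{mean}(\mathrm{RR})$ — beats per
  elapsed time, the convention consistent with integer-bpm device
  outputs; the instantaneous-rate average is available via
  `convention = "instantaneous"`.
* **Minimum HR** — ring-type devices report the minimum rather than mean
  HR over their 5-min window. Devices do not publish their internal
  window, so `min_hr()` uses a 10 s rolling mean by default. Because a
  minimum is not comparable to a mean, such devices are excluded from
  mean-HR comparisons automatically (they keep their rMSSD comparisons).

## Device error models and the default panel

`device_error_model()` corrupts in a fixed, testable order: (1)
beat-level noise on a copy of the truth series truncated to the device
epoch — timing jitter, missed beats, spurious beats; (2) recomputation of
HR and rMSSD from the corrupted series with the same metric code the
reference uses; (3) summary-level error
$v' = v(1 + \mathrm{cv}\cdot z) + b$, $z\sim N(0,1)$, with optional
integer rounding of HR. The proportional noise accepts per-metric values
(`c(hr = ..., rmssd = ...)`) because real PPG apps show rMSSD errors an
order of magnitude larger than their HR errors.

The default `cots_device_panel()` spans the empirically observed spectrum
for a resting-state panel: two chest-strap ECG devices with sub-bpm HR
bias, two phone-PPG apps with moderate noise, one strap that rounds HR to
integers and degrades only on rMSSD, one camera-PPG app with double-digit
HR bias and >100% rMSSD error, and one ring reporting minimum HR.
`study_design()` defaults describe the emulated study conditions: 5
subjects, 148 trials, between-subject resting HR $65 \pm 7$ bpm and rMSSD
$60 \pm 18$ ms with within-subject SDs of 3 bpm and 8 ms — typical
resting values for healthy young adults. Published validation studies do
not state their device-to-trial allocation; the default splits trials
nearly equally with the extra trials going to the 3-min and ring devices,
and any other allocation can be passed explicitly.

## The agreement chain

Per device/metric group, in order:

1. **APE** $= |v_\mathrm{dev} - v_\mathrm{ref}|/v_\mathrm{ref}\times 100$.
   Device values are compared as the device reports them (integer bpm
   where the error model rounds) against the un-rounded reference;
   `round_reference = TRUE` switches to integer-vs-integer comparison.
2. **Tukey outer fence**: values beyond $Q_3 + 3\,\mathrm{IQR}$ or below
   $Q_1 - 3\,\mathrm{IQR}$ are flagged, in a single pass, and removed
   from *all* downstream statistics. Quartiles use linear interpolation
   between order statistics (type 7); the rule is configurable because
   fence membership can flip near boundaries under other quartile
   definitions, and nothing in common practice pins the choice down.
3. **MAPE summary**: n, mean, min, median, max, IQR of the kept values.
4. **Lin's CCC** with population (1/n) moments:
   $\mathrm{CCC} = 2s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$. Its
   magnitude never exceeds the Pearson correlation (bias-correction
   factor ≤ 1), an invariant the tests assert on random data.
5. **Bland–Altman** on $d = \mathrm{device} - \mathrm{reference}$ (so
   positive bias = overestimation): bias $\pm 1.96\,\mathrm{SD}$ limits
   with the sample SD, bias CI via $t\cdot\mathrm{SD}/\sqrt n$, LOA CIs
   via the $t\cdot\mathrm{SD}\sqrt{3/n}$ approximation — the classic 1986
   recipe.
6. **Paired bias t-test** of mean difference 0, Bonferroni-multiplied by
   the number of devices in the metric's family (by default the number
   present in the data; configurable), significant at adjusted p < 0.05.

Groups that degenerate (a perfect device has zero-variance differences;
tiny groups cannot support quartiles or LOA) surface as `NA` statistics
or recorded per-group errors — the run always completes.

Trials are treated as independent in all of this, mirroring common
practice in small validation panels. Within-subject correlation is real
and a mixed-effects treatment would be the statistically stricter choice;
it is deliberately out of scope, and the panel statistics should be read
with that caveat.

## What the synthetic study does and does not show

Because injected truth is known, the pipeline's estimators can be
checked end to end: a zero-error device must come out with MAPE ≈ 0,
CCC ≈ 1 and zero bias even when the reference path goes through ECG
rendering and re-detection; an injected additive bias $b$ and noise SD
$s$ must be recovered by the Bland–Altman bias and LOA width within 10%
at 200 trials; strictly ordered injected noise across a 7-device panel
must reproduce the same MAPE ordering in ≥95% of seeded runs; and null
devices must keep the Bonferroni family-wise error at or below 5%. These
are exactly the checks in `tests/testthat/test-acceptance.R`, at those
problem sizes (200 trials for recovery, 20 runs × 147 trials for
ranking, 10⁴ replicates for the error rate, 50 seeds for the detector) —
sizes chosen to make the Monte-Carlo noise comfortably smaller than the
tolerances.

What passing them does *not* show: anything about PPG optics (wavelength
and skin-tone dependence), motion artifact, real electrode noise,
device-internal filtering, or app-side preprocessing. The generator's
device models are statistical caricatures fit for testing estimators,
not emulations of firmware.

## Reproducible runs

`generate_study()` is a pure function of its design (one master seed
fans out into per-trial seeds), `run_validation()` is deterministic
given dataset and config, and the written `report.json` carries the
seed, a config hash and the package version. The same contract powers
`scripts/acceptance.R`, which recomputes the headline quantities from
scratch under a caller-supplied seed.
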