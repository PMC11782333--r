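---
title: "Linking AVF sounds to hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking AVF sounds to hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfsound)
```

## The problem

A hemodialysis arteriovenous fistula (AVF) — a surgical anastomosis between
an arm artery and vein — produces an audible bruit. Disturbed, recirculating
flow inside a remodeling fistula shifts acoustic energy toward higher
frequencies, while the overall loudness tracks the blood flow volume (BFV)
the access delivers. `avfsound` implements the quantitative chain linking
these observations: an acoustic statistic computed from stethoscope
recordings, wall-shear-stress (WSS) post-processing that quantifies flow
disturbance, Doppler-ultrasound flow volumes, and the cohort statistics
that relate the three on longitudinal patient data.

## The acoustic statistic: HLPR

A recording is trimmed to a standard 4 s, high-pass filtered, and Fourier
transformed. The **high-low peak ratio** is

$$\mathrm{HLPR} = \frac{\max_{f \in [500,700]\,\mathrm{Hz}} A(f)}
                       {\max_{f \in [100,250]\,\mathrm{Hz}} A(f)},$$

where $A(f)$ is the single-sided amplitude spectrum. The low band captures
the fundamental bruit of pulsatile flow; the high band captures the
components that appear when flow becomes disturbed. Being a ratio, HLPR is
invariant to recording gain — important because stethoscope placement and
contact pressure scale the whole waveform.

Processing choices, with rationale:

* **Trim window (4 s, centered).** Bedside recordings exceed 5 s; contact
  transients concentrate at the ends, so the centered window is the
  deterministic, symmetric choice.
* **High-pass filter: causal single-pass Butterworth, order 4, 50 Hz
  cutoff.** Butterworth for its flat passband; a *single* causal pass keeps
  the realized order at the nominal 4 (a forward–backward pass would
  square the magnitude response and double the order). The tests verify
  the measured steady-state gain against the analytic magnitude response
  on the bilinear-transform frequency axis, which is the exact gain of
  the implemented digital filter; at the 4 kHz default rate it differs
  negligibly from the continuous-time curve at the probe frequencies.
* **Spectrum: plain FFT of the full segment, rectangular window,**
  single-sided scaling $2/N$ (DC and Nyquist unscaled by 2) so a
  unit-amplitude bin-aligned sinusoid reads 1.0. No tapering is applied;
  the band-maximum statistic is insensitive to the sidelobe detail a
  taper would trade resolution for, and the ratio cancels the scaling
  convention entirely (tested to 1e-10).
* **Band peaks: endpoints inclusive, ties broken toward the lower
  frequency** — a deterministic rule that matters only for pathological
  flat spectra.
* **Maximum peak amplitude** (the loudness statistic regressed on BFV) is
  the global spectral maximum above a 50 Hz floor, excluding the stop
  band of the high-pass. Restricting it to the low band instead is a
  plausible alternative reading; it is available by calling
  `find_band_peak()` directly, but the global maximum is the default
  because the statistic is described as a property of the whole sound.
* The stethoscope's documented response shaping (amplification in
  20–2000 Hz, reduced response between 50 and 500 Hz) is **not**
  compensated: spectra are analyzed as recorded.

## Flow disturbance: OSI

Given the WSS vector $\vec\tau(t)$ on each surface element over one
cardiac cycle $[0, T]$, the oscillatory shear index is

$$\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{\left\lVert\int_0^T \vec\tau\,dt\right\rVert}
       {\int_0^T \lVert\vec\tau\rVert\,dt}\right) \in [0, 0.5],$$

0 for unidirectional shear and 0.5 for purely oscillatory shear. This is
the standard Ku-type definition; the full shear vector is used (not a
projected component). Time integrals use the trapezoidal rule on the
supplied cycle — the caller is responsible for passing a converged,
single-cycle field. An element with identically zero shear over the whole
cycle has an undefined ratio; it is reported as OSI 0 with a warning,
since no direction reversal can be attributed to it. Round-off can push
the quadrature ratio marginally past 1, so values are clamped to
$[0, 0.5]$.

The disturbance summary is the **area percentage with OSI > 0.1**
(strict inequality), area-weighted over the region of interest — the
roughly 4 cm patch around the anastomosis matching the stethoscope's
capture area. ROI delimitation is inherently a segmentation choice, so it
is caller-supplied (`roi_mask`); without a mask the whole mesh is used.

## Vessel geometry: CSA profiles

Remodeling is quantified by cross-sectional areas (CSA) sampled every
0.1 mm along the venous centerline. At each station the lumen surface is
cut by the plane normal to the local tangent; intersection segments from
the cut triangles are chained into contours, and the *closed* contour
whose centroid lies nearest the centerline point is kept — grazing cuts
through other vessel limbs near the anastomosis produce farther contours,
and boundary cuts produce open chains, both of which are rejected.
Stations with no closed contour report `NA`, never zero: a zero area
would masquerade as total stenosis and bias remodeling statistics.
Consecutive-visit changes beyond 5 mm² per station (strict) are flagged
as remodeling, in either direction (stenosis or dilatation).

On a 64×81 cylinder mesh of radius 2 mm the profile recovers the analytic
$4\pi$ mm² to ~0.2% (the inscribed-polygon bias at 64 circumferential
vertices is $(2\pi/64)^2/6 \approx 0.16\%$); the acceptance tests allow
1% at moderate resolution.

## Flow volumes

Doppler measurements give short/long lumen axes (mm) and a time-averaged
velocity (cm/s). The lumen is treated as an ellipse:
$\mathrm{CSA} = \pi\,ab/4$; the **equivalent diameter** is that of the
equal-area circle, $\sqrt{ab}$, so the pair (diameter, CSA) is
self-consistent ($A = \pi d_{eq}^2/4$ exactly, enforced by test). The
area-equivalent convention and the arithmetic mean differ by <3% for
near-circular lumens. BFV is $\bar v \times \mathrm{CSA} \times 60$
mL/min. Because flow in these fistulae is retrograde, with both radial
limbs afferent, the venous BFV is the PA + DA sum.

## Cohort statistics

* **Median split.** Visit records are partitioned at the overall median
  of the high-OSI area percentage; records strictly above go to the
  "extensive" subgroup. All quantiles (threshold, medians, IQRs) use
  linear interpolation between order statistics (R type 7). On the
  published 12-row table this reproduces the subgroup median 0.67 and
  IQR bounds 0.515→0.51, 0.87, 0.25 and 0.3375→0.34 at printed
  precision. The published "limited" subgroup median (0.31) is not
  reproducible by any order-statistic convention — the two central
  values are 0.31 and 0.33 — and is reported as computed (0.32). The
  between-group test is Student's pooled-variance t-test by default
  (Welch by flag); observations are treated as independent despite
  repeated measures, matching the original analysis.
* **Mixed model.** Amplitude–BFV associations are fit as
  $y = \beta_0 + \beta_1 x + u_{\mathrm{patient}} + \varepsilon$ with a
  Gaussian random intercept, by REML (`lme4`). The slope's 95% CI is a
  case-resampling bootstrap over *patients* — the exchangeable unit —
  with percentile endpoints; the default is 1000 refits with a mandatory
  seed, and fits are bit-reproducible for a fixed seed. Slope p-values
  use the Satterthwaite approximation (`lmerTest`). With one observation
  per patient the random intercept is unidentifiable and the model
  collapses to OLS; a singular fit reports a zero patient sd rather than
  erroring.
* **Longitudinal deltas** are later-minus-earlier differences between
  consecutive *attended* visits in the canonical schedule
  (3d < 3w < 3m < 6m < 9m < 1y); pairs missing either quantity are
  dropped.
* **Operator agreement** uses Pearson correlation with a Fisher-z CI,
  Shapiro–Wilk normality checks, and Bland–Altman mean difference with
  ±1.96 sd limits (differences taken expert − novice).

## What the generators emulate — and what they do not

* `gen_phonoangiogram()` is tones + raised-cosine cardiac modulation +
  white noise. It exercises band-peak extraction, scale invariance and
  the trim/filter chain with a known spectral truth; it does not model
  the hemoacoustic source (vortex shedding, wall vibration), murmur
  bandwidth, or heart sounds, so passing tests say nothing about
  detecting stenosis in real bruits. Defaults: 4 kHz, 6 s, 70 bpm,
  modulation depth 0.3.
* `gen_wss_field()` assigns each element either purely oscillatory shear
  (reference OSI exactly 0.5) or non-reversing steady-dominated shear
  (reference OSI exactly 0) along a random fixed direction. Real OSI
  fields are spatially correlated and take intermediate values; the
  generator's bimodality is what makes the area-fraction expectation
  exactly computable.
* `gen_cohort()` draws, per patient, a Gaussian random intercept and,
  per visit, a uniform brachial BFV and a Gaussian-noise amplitude
  around the linear truth. Defaults mirror the study conditions: 6
  patients × 6 scheduled visits, slope 0.103 amplitude-units per mL/min,
  patient sd 14.97, residual sd 31.05, BFV in 400–1600 mL/min (a
  realistic forearm-AVF brachial range). HLPR tracks the BFV excursion
  with coupling −0.001 per mL/min plus visit noise (sd 0.02), making the
  delta–delta structure exact.

## Numerical and validation choices

* **CI-coverage experiment.** The slope-recovery simulation
  (`slope_recovery_simulation()`) runs 100 cohorts at **20 patients** ×
  6 visits, bootstrap B = 200 per fit, slopes cycled over
  {0.103, 0.05, 0.25}, and requires ≥90/100 nominal-95% coverage.
  Twenty clusters, not the study's six, because percentile cluster
  bootstraps only approach nominal coverage once the number of clusters
  is moderately large; at six clusters the interval is known to
  undercover substantially (our own probe gives roughly 75% coverage).
  This is a check that the *method* is implemented correctly where its
  asymptotics apply — a known limitation is that CIs on six-patient
  cohorts should be read as optimistic. B = 200 per replicate keeps the
  experiment's cost proportionate for a coverage tally; end-user fits
  default to B = 1000.
* **Problem sizes** elsewhere: 2000-element WSS fields for area
  fractions, 1000 timesteps for quadrature-oracle agreement (1e-6),
  200 for the 0.5-limit check (1e-3), 64×81 tube meshes for geometry.
* **Degenerate inputs**: empty bands, zero low-band peaks, zero-shear
  elements, empty ROIs, single-visit patients and non-overlapping CSA
  ranges all have defined, tested behavior (error or NA, never a silent
  zero).

## Known limitations

* No public patient data ships with the package; everything empirical is
  synthetic except the 12-row published HLPR/OSI table. The headline
  regression slopes from the study (0.103, −0.001) require the original
  amplitude/BFV measurements and are therefore *parameter-recovery*
  targets here, not reproduction targets.
* The acoustic model is not physical; HLPR thresholds (e.g. 0.35 as a
  disturbance indicator) cannot be validated in silico.
* CSA extraction assumes a reasonably tubular, closed surface around the
  sampled span; self-intersecting or highly non-planar sections are out
  of scope.
* The pipeline treats each WSS file as one cardiac cycle; cycle
  convergence is the CFD upstream's responsibility.
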