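---
title: "Methods: insole transduction, gait events and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insole transduction, gait events and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insoleGait)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the choices made where the design was genuinely
open, and what a green test suite does and does not establish. No empirical
claim is made here that the tests or `scripts/acceptance.R` do not
themselves compute.

## 1. Tactel transduction

A tactel converts the load on its silicone frustum into an output voltage.
After zero-load de-offsetting, load drives the voltage negative over an
operational range of about $[-1, 0]$ V. The calibration is the quartic

$$F(V) = p_1 V^4 + p_2 V^3 + p_3 V^2 + p_4 V + p_5,$$

with default coefficients $(186.1,\ 224.5,\ 64.76,\ -18.59,\ 0)$ obtained
from quasi-static bench load–unload cycles averaged over 32 sensors.
Sensing is piecewise: voltages above the noise-floor threshold
$V_\mathrm{thresh} = -0.01$ V read zero force; at or below it, the
polynomial applies. Three consequences are deliberate:

* **The discontinuity at $V_\mathrm{thresh}$ is kept.** $F(-0.01) =
  `r round(force_from_voltage(tactel_calibration(), -0.01), 5)`$ N, so the
  piecewise map jumps by ~0.19 N at the threshold. That is the device's
  literal definition; smoothing it would silently change the detection
  threshold semantics.
* **Saturation is clamped, not extrapolated.** The polynomial is only
  trusted on its fitted range; voltages beyond `v_saturation` (default
  $-1$ V, where $F = 44.95$ N) are clamped. The bench's quoted per-tactel
  ceiling (~40 N) and the polynomial value at $-1$ V differ slightly; since
  the exact saturation voltage is not published, `v_saturation` is a
  configurable parameter of `tactel_calibration()`.
* **The inverse is defined on $[v_\mathrm{sat}, 0]$.** The polynomial's
  value at $V_\mathrm{thresh}$ is ~0.19 N, so forces in $(0, 0.19)$ N have
  no pre-image inside the sensing branch. `voltage_from_force()` therefore
  root-finds on the full monotone range (forces in the dead band invert to
  voltages above the threshold), maps $f = 0$ to $V_\mathrm{thresh}$ by
  convention, and guarantees the round trip
  $F(V(f)) = f \pm 10^{-8}\,\mathrm{N}$ for $f \ge F(V_\mathrm{thresh})$.
  The simulator maps zero allocated force to 0 V — an unloaded channel sits
  at its baseline, not at the threshold boundary.

**Calibration fitting.** `fit_calibration()` mirrors the bench workflow:
loading and unloading branches of each cycle are averaged first (removing
hysteresis at cycle level — the branch-averaging order is our choice, the
bench protocol only prescribes "mean load–unload curves"), cycles are then
averaged across sensors, and a degree-4 polynomial with the intercept
pinned to zero ($p_5 = 0$: zero force at zero de-offset voltage) is fitted
by least squares. The common voltage grid is built from the *observed*
voltages inside the curves' overlap, never an invented lattice: evaluating
at actual sample points keeps noiseless parameter recovery exact to solver
tolerance (an invented grid introduces piecewise-linear interpolation bias
of order $10^{-3}$ relative, which the recovery tests would reject).

## 2. Layout and spatial-density weights

The insole clusters its 16 tactels where gait-relevant pressures
concentrate (heel, metatarsal heads, hallux), so the CoP centroid must
de-bias sensor density: each tactel's weight is the reciprocal of the
number of tactels in its antero-posterior bin. The binning rule is
fixed-width bins (default 1 cm) anchored at the heel — deterministic, and
covariant under uniform scaling because `scale_layout()` scales the bin
width with the foot. The shipped `default_layout()` is a *synthetic*
stand-in that mimics the published sensor distribution qualitatively; the
true PCB coordinates are not public, and nothing in the package depends on
their exact values.

## 3. Per-frame biomechanics and causality

`process_stream()` applies, per frame: optional baseline subtraction
(median of a user-marked unloaded window, default the first 50 samples —
the physical device de-offsets in hardware, offline processing must do it
in software), piecewise transduction, summation to vGRF, and the weighted
CoP centroid, undefined (`NaN`, never interpolated) whenever
vGRF < vGRF$_\mathrm{thresh}$. Sample $k$ of the output depends only on
samples $\le k$; the test suite asserts batch/streaming equivalence, so
the same code path is valid for real-time use.

The default threshold is $16 \cdot F(V_\mathrm{thresh}) =
`r round(system_force_threshold(tactel_calibration(), 16), 3)`$ N
(the "~3 N" rule: all sensors simultaneously at the noise floor). It is a
per-recording configuration value because borderline recordings can warrant
raising it (the validation campaign this mirrors raised one subject's
threshold to 7 N).

## 4. Event detection

Heel-strike is the first sample with vGRF at or above threshold after a
swing; toe-off the first sample below it after a stance. Timestamps are
sample-quantized — no sub-sample interpolation — matching the real-time
device. Two deliberate additions to the bare-threshold rule:

* **Debouncing** (default `min_stance = min_swing = 0.1` s): candidate
  phases shorter than the minimum are merged into their neighbours,
  shortest first. Real signals chatter near the threshold; 0.1 s is well
  below any physiological stance or swing yet removes single-sample dips.
  Set both to 0 to recover the bare rule. Whether the on-board
  implementation debounces is not documented; ours is disable-able for that
  reason.
* **Edge discipline:** a stance that starts before the recording or runs
  past its end has an unobservable HS/TO and is dropped.

## 5. Validation battery

Alignment interpolates the 200 Hz reference linearly onto the 100 Hz
insole timeline after applying the shared-trigger offset. Strides are
paired across devices by nearest heel-strike within half the reference
median stride time; unmatched strides are counted and dropped. The metrics
are medians of absolute per-stride differences (HS, TO, stance duration; in
seconds and as % of the reference stance), Pearson correlation between
per-recording *average* stance-normalized profiles (a per-stride variant
exists but is not the reported statistic), RMSE for CoP profiles only
(vGRF amplitudes differ by ~5x between devices, making an RMSE
meaningless), within-device repeatability (per-stride RMSE about the mean
profile; body-weight- and stride-mean-normalized for vGRF, cm for CoP) and
peak vGRF in % body mass with $g = 9.81$ m/s².

Stance profiles are low-pass filtered then linearly time-normalized to 101
points. The filter is unspecified upstream; we default to a zero-phase
4th-order Butterworth characteristic at 20 Hz — standard for ground
reaction forces, zero-phase so profile comparison incurs no latency bias.
Because no recursive-filter package is assumed, the implementation applies
the squared-magnitude Butterworth response in the frequency domain on an
even (reflected) extension of the signal, which reproduces
forward–backward filtering's passband and phase behaviour; interior `NaN`
runs are bridged linearly before filtering and restored after.

## 6. The synthetic world

The simulator exists so the full chain is testable without hardware. Its
defaults are a fixed statement of the world, chosen once:

| parameter | default | why |
|---|---|---|
| body mass | 66.2 kg | mean of the validation cohort this mirrors |
| stride time | 1.1 s | normal self-selected walking |
| stance fraction | 0.60 | normative stance share of the gait cycle |
| vGRF peaks | 1.10 / 1.05 BW at 25% / 75% of stance | physiological double-bump walking vGRF |
| valley | 0.75 BW | typical mid-stance unloading |
| CoP excursion | 10% to 85% of a 26 cm foot | heel-pad to forefoot progression |
| allocation spread | 3 cm | pressure-patch scale under heel/forefoot |
| coupling | 0.2 | fraction of load reaching the sensorized area (below) |
| voltage noise | 5 mV | consistent with the −10 mV noise-floor threshold |
| sensor lag | 20 ms (asymmetry 1) | viscoelasticity surrogate |

The vGRF template is two raised-cosine bumps whose half-width is solved
analytically from the requested valley depth, times a smoothstep taper
(width 5% of stance) that enforces exact zeros at contact and release; peak
heights are attained exactly because the solved width never reaches the
opposite peak. The CoP template is a normalized logistic ramp — endpoints
exact, midpoint the mean of the extremes, strictly monotone. Ground-truth
events are the *exact* crossings of the continuous force through the
reference device's 20 N threshold (bisection to $10^{-12}$), which makes
the truth table agree with threshold detection on the 200 Hz reference to
within one sample by construction.

**Why `coupling` exists.** A 16-tactel insole saturating at ~45 N per
sensor cannot physically transmit an adult's full body weight
(1.1 BW ≈ 714 N vs a 719 N combined ceiling). Routing the full load
through the tactels drives >50% of loaded samples into saturation, and the
conservation-preserving redistribution then smears force across the whole
sole, destroying the CoP estimate — an artefact of forcing conservation,
since in reality the excess load passes through the unsensorized sole.
`coupling` is the fraction of the vGRF reaching the sensorized area. Its
default 0.2 is anchored to the ~19% insole-to-force-plate amplitude ratio
reported for this class of device, reproduces that amplitude mismatch in
the synthetic world (insole peaks ~22 BM% vs ~110 BM% reference), and
keeps tactels within range for the default walker. `coupling = 1` remains
available and is used by the end-to-end identity test: with zero noise and
lag, processing recovers the true vGRF to <1% even under saturation,
because redistribution conserves the total.

**Sensor lag** is a first-order low-pass on each channel's voltage with an
optional loading/unloading asymmetry factor — a minimal surrogate for
silicone viscoelasticity and hysteresis, kept to two interpretable
parameters rather than a full hysteresis model. Its documented effect
(asserted by tests) is a positive median heel-strike delay and a later
toe-off. The acceptance check "stance MAE within 3 samples under default
noise" is run with lag disabled: lag is a separate, deliberate
imperfection whose very purpose is to delay events, and the check names
only noise.

**What a green suite establishes — and what it does not.** The synthetic
world validates the *processing chain*: transduction inversion, weighting,
thresholding, alignment and metrics. It does not emulate across-sensor
calibration spread, temperature or humidity drift, shear coupling,
footwear mechanics, pathological gait, wireless packet loss, or true
silicone hysteresis loops; agreement numbers computed on it (e.g. CoP
correlations ≈ 0.99) characterize the pipeline under the stated world,
not any physical device's field performance.

## 7. Numerical choices and degeneracies

* Root-finding: `uniroot` at $10^{-12}$ tolerance in the public inverse;
  the simulator uses a vectorized interpolation-plus-Newton inverse polished
  to machine precision (both are exercised against each other via the
  round-trip property).
* Stride pairing tolerance: half the reference median stride time; single-
  stride tables fall back to an unbounded match.
* Empty cases are first-class: empty stride tables, zero-stride trials and
  subset evaluations on silent streams all return well-defined empty
  results or explicit errors, as specified per operation.
* Allocation with an out-of-reach CoP (kernel numerically zero everywhere)
  assigns the nearest tactel rather than dividing by zero.
* Seeding: `simulate_trial()` seeds from its config and restores the
  caller's RNG state, so trials are bit-reproducible and side-effect-free.

## 8. Sensor placement workflow

`rank_sensors()` implements the quantitative half of a sensor-reduction
study: per-event responsivity (median latency between the reference event
and the sensor's own threshold crossing — first activation after HS, last
activation before TO; both non-negative, zero meaning synchronous) and
amplitude (median peak in a ±0.15 s window, the window length being our
configurable default since none is published), combined by rank-sum with
id-ordered tie-breaks. The upstream study's subset *choice* involved
visual inspection across subjects; we deliberately do not fake that manual
step — `evaluate_subset()` takes any candidate subset and scores its
HS/TO synchrony against the full configuration, rescaling the detection
threshold with subset size ($n \cdot F(V_\mathrm{thresh})$) so comparisons
are not biased by threshold magnitude.

## 9. Known limitations

* Medio-lateral CoP, pressure maps and shear forces are out of scope; the
  device geometry only supports antero-posterior CoP.
* The default layout is illustrative; results that depend on exact sensor
  coordinates (e.g. absolute CoP RMSE in cm) should be read against the
  layout actually supplied.
* The acceptance-level agreement between simulated insole and simulated
  reference is a clean-world statement; real-device headline numbers
  (tens of ms event MAEs, moderate vGRF correlation) arise from physics
  the simulator intentionally simplifies.
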