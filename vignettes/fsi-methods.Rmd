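---
title: "The Fetal Stress Index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Fetal Stress Index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsindex)
```

## The problem

Heart rate variability (HRV) is the standard non-invasive window onto
autonomic regulation of the heart. The high-frequency (HF, > 0.15 Hz)
component of the R-R interval series reflects parasympathetic (vagal)
modulation only, so a drop in HF oscillation is the expected signature of
vagal withdrawal — in the fetal context, a candidate early marker of
hypoxia and acidosis. The classic readouts (RMSSD, FFT band powers) track
this physiology but inherit the basal heart rate, the overall variability
magnitude, and the oscillation frequency of each subject, producing
inter-subject dispersions so large that no clinical threshold can be set.

The Fetal Stress Index (FSI) implemented here addresses exactly that: it
isolates the HF oscillations by filtering, then measures their magnitude
in the time domain on a signal that has been made invariant to baseline
and to overall variability scale.

## The index, step by step

Each analysis window holds `N = 512` samples (64 s of the R-R signal
resampled at 8 Hz).

1. **Mean-centering.** `M = mean(RR)`, `RR' = RR - M`. Removes the basal
   heart rate.
2. **Euclidean normalization.** `S = sqrt(sum(RR'^2))`, `RR'' = RR' / S`.
   `RR''` has unit norm, so multiplying all deviations by any `k > 0`
   leaves it unchanged — the index cannot see the variability magnitude.
   (The norm must include the square root: a plain sum of squares would
   scale as `k^2` and the invariance would fail algebraically.)
3. **Wavelet high-pass.** A 5-level discrete wavelet transform with the
   Daubechies 4-tap filter pair; the level-5 approximation (0–0.125 Hz at
   8 Hz) is zeroed and the signal reconstructed. 0.125 Hz is the nearest
   realizable dyadic cutoff to the 0.15 Hz HF band edge; the depth is
   configurable (`levels`), each extra level halving the cutoff.
4. **Envelopes.** Local maxima (strict, plateaus at their midpoint) are
   joined by linear interpolation and held flat out to the window edges;
   likewise minima. Envelopes are clamped to bound the signal pointwise.
   Fewer than two maxima or minima invalidates the window.
5. **Sub-areas.** The envelope gap is integrated over four consecutive
   16-s quarters (`A1..A4`, left-Riemann rule, units of
   normalized-unit·seconds) and the minimum `AUCmin` retained, making the
   index react within ~16 s to transient HF suppression.
6. **Linear map.** `FSI = 100 (5.1 AUCmin + 1.2) / 12.8`, clipped to
   `[0, 100]`. The constants are empirical calibration values fitted by
   the method's authors on a large R-R corpus that is not redistributable;
   we take them as given. Two consequences worth knowing: the map's
   intercept means an FSI below 9.375 cannot occur, and clipping (not the
   map itself) enforces the upper bound.

The window slides with a 1-s step; timestamps are window centers; invalid
windows yield `NA`, never a substituted value. Period summaries
([period_mean()]) average the valid windows whose center falls in a
half-open interval and refuse to answer when fewer than half the windows
are valid.

## What the index is and is not invariant to

Baseline shifts and positive rescaling of the deviations leave every FSI
value unchanged to 1e-9 (tested). The envelope construction makes the
index largely indifferent to *where* in the HF band the oscillation sits
(≤ 15% variation across 0.3–1.5 Hz at fixed amplitude, tested). It is
**not** invariant to the spectral *composition* of the variability: since
`S` includes all bands, adding low-frequency or very-low-frequency power
dilutes the normalized HF amplitude and lowers the index. That is by
design — the index measures the HF *share* — but it means a pure
sympatholytic intervention that removes LF power will mechanically nudge
the FSI upward; only between-period physiological variability keeps that
nudge from being a consistent finding, exactly the pattern seen in the
blockade literature.

## Comparators

RMSSD is computed on the cleaned beat-to-beat intervals (resampling
distorts successive differences). Band powers come from a 256-s sliding
window: mean-centered, Bartlett-tapered, FFT, one-sided powers normalized
by `sum(w^2)` so their total estimates the signal variance in ms²; band
membership is by half-open intervals with the DC bin excluded; the HF
upper edge defaults to the 4 Hz Nyquist and is configurable
(`hrv_bands()`). Normalized HF is `HF / (HF + LF)`.

## Preprocessing

The artifact rule is a documented stand-in: the publication lineage cites
a proprietary detector without describing it. We flag beats deviating
from the running median of the 11 surrounding valid beats by more than
25% (both parameters configurable), iterate to a fixpoint so the
operation is idempotent, interpolate flagged beats linearly in beat-index
coordinates, and hold edges. A physiologic guard rejects cleaned series
with intervals outside (100, 3000) ms. Resampling is linear interpolation
onto an 8 Hz grid anchored at the first beat time.

## The synthetic cohort: what it emulates, what it does not

`generate_subject()` builds an instantaneous heart period

```
r(t) = 60000 / hr(t) + vlf(t) + a_lf(t) sin(2π f_lf t + φ1)
       + a_hf(t) sin(2π f_hf t + φ2) + ε
```

and places beats iteratively (`t_next = t + r(t)/1000`). Defaults are the
stated world of the in-silico experiments:

* `basal_hr = 156` bpm, the basal rate reported for instrumented fetal
  sheep; drug multipliers `hr x1.22` (atropine) and `x0.91` (propranolol)
  reproduce the reported rises/falls (≈156→190, ≈161→147 bpm).
* `a_lf = 7`, `a_hf = 10` ms at `f_lf = 0.08`, `f_hf = 0.5` Hz: sinusoid
  powers (`a²/2` ≈ 25 and 50 ms²) of the order of the LF/HF band powers
  reported in that preparation; 0.5 Hz sits in the fetal
  breathing-movement range.
* `a_vlf = 12` ms: a smooth Gaussian wander (25-s knots, spectrum below
  ~0.04 Hz). Real fetal HRV is dominated by such slow drift; omitting it
  makes every normalized index unrealistically stable. With it, the
  cohort's inter-subject dispersion lands in the reported regime (FSI %CV
  near 10–15%, band powers several-fold higher) rather than the few
  percent a two-sinusoid world produces.
* `jitter_sd = 3` ms per-beat noise; `artifact_rate = 0.01` (half missed
  detections, half spurious ones, injected on the beat-time vector so the
  cleaner must find them).
* `amp_mod_sd = 0.25`: lognormal drift of both modulation amplitudes on a
  60-s knot grid — fetal behavioural-state nonstationarity. This is what
  gives two 5-minute periods of the *same* subject genuinely different
  index values, and hence the drug-free scenario its null behaviour.
* `subject_sd = 0.25`: relative between-subject spread of basal rate and
  amplitudes.
* Atropine multiplies `a_hf` by 0.25; propranolol multiplies `a_lf` by
  0.35; effects ramp in over a raised-cosine 30 s. The analysis periods
  (5–10 min before and after injection) exclude ±5 min around the
  injection, so the transition shape is immaterial.

Not emulated: blood-pressure coupling, blood gases, hypoxic/acidotic
states, integral-pulse-frequency-modulation beat placement, missing-data
gaps longer than single beats. A green in-silico test therefore
establishes that the *pipeline* reproduces the blockade signature given
this physiology — not that the physiology itself is complete.

## Numerical choices

* **Wavelet boundary:** symmetric half-sample extension; the filter bank
  is redundant at the edges and reconstructs exactly (verified to ~1e-13
  in the tests). Periodization would wrap window edges into each other.
* **Sub-area integration:** each sample carries 1/8 s (left-Riemann).
  A trapezoid rule with shared endpoints cannot split 512 samples into
  four equal-measure quarters; end-weighting would bias `AUCmin` toward
  the last quarter. With this convention a constant envelope gap `c`
  gives exactly `A_k = 16 c` for every quarter.
* **Degenerate windows:** `S < 1e-6` ms (constant window) or fewer than
  two extrema per envelope → invalid, `NA` downstream.
* **Wilcoxon:** exact two-sided p by full `2^n` enumeration (average
  ranks for ties) up to n = 15, normal approximation without continuity
  correction beyond; both values are always reported because common
  statistical software prints the asymptotic one even for n = 7.
* **Quartiles:** linear interpolation of order statistics (R type 7),
  configurable, since quartiles of seven values depend visibly on the
  convention.
* **%CV with a negative mean** uses `|M|` and says so; the situation does
  not arise for these indices.
* **Determinism:** every stochastic element flows from one master seed;
  per-subject seeds are derived arithmetically and kept below 2^31.

## Known limitations

* Absolute FSI values depend on the envelope and integration conventions
  behind the calibration constants, which the original description leaves
  open; agreement is therefore expected in invariances, directions and
  dispersion patterns, not in absolute index values.
* The dyadic cutoff (0.125 Hz) admits a sliver of the upper LF band
  (0.125–0.15 Hz).
* The artifact detector is a stand-in rule, not a reimplementation of the
  original (undescribed) algorithm.
* The exact Wilcoxon enumeration is exponential in n; beyond n = 15 the
  asymptotic value is used.
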