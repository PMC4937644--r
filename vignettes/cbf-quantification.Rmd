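---
title: "Quantifying cerebral blood flow from Tc-99m ECD first-pass angiography and SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral blood flow from Tc-99m ECD first-pass angiography and SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdquant)
```

## The measurement problem

Regional cerebral blood flow (rCBF) with a Tc-99m ECD SPECT study can be
quantified non-invasively — without arterial sampling — by reading the
arterial input function off a dynamic planar acquisition of the chest during
the bolus first pass, and converting reconstructed brain SPECT counts to flow
through a calibration line anchored to a reference flow measurement.
`ecdquant` implements the two pipelines in clinical use side by side:

* **IBUR** (improved brain uptake ratio): the input ROI is placed
  *automatically* on the ascending aorta at the max-count pixel of the
  dynamic series; the second peak of the aortic time-activity curve (TAC) is
  fitted with a gamma variate whose analytic integral gives the input
  counts; Lassen-corrected SPECT segment counts divided by the input and
  scaled by a planar/SPECT cross-calibration factor (CCF) give the regional
  brain uptake ratio, and the PET-anchored line
  `rCBF = 3.23 * BUR + 4.66` converts it to flow. Mean CBF (mCBF) is the
  average over the basal-ganglia segments of the clinically normal
  hemisphere.
* **PP** (Patlak plot): aortic and hemispheric TACs from *manually* placed
  ROIs enter the Patlak graphical transform; the slope Ku, scaled to a brain
  perfusion index (BPI), gives mCBF through the Xe-133-anchored line
  `mCBF = 2.60 * BPI + 19.8`; rCBF is then distributed regionally through
  the Lassen-corrected SPECT count distribution, anchored so that the
  basal-ganglia reference equals mCBF.

Both pipelines read the regional values through a 24-segment (12 per
hemisphere) stereotaxic template: anterior, precentral, central, parietal,
angular, temporal, occipital, pericallosal, lenticular nucleus, thalamus,
hippocampus and cerebellum on each side.

The two calibration intercepts are the methods' minimum reportable flows:
4.66 ml/100g/min for IBUR versus 19.8 ml/100g/min for PP. This single
structural difference is why PP compresses (overestimates) the low-flow
range while IBUR can report it directly — the clinical motivation for
comparing the methods on the same subjects.

## Models and key steps

### Gamma-variate input model

The bolus is modelled as `C(t) = K (t - t0)^a exp(-(t - t0)/b)` for
`t > t0`, zero before the appearance time. The curve peaks at `t0 + a*b`,
and its full integral is analytic: `K b^(a+1) Gamma(a+1)`. The input counts
of the IBUR method are this analytic integral of the fitted curve — exact,
tail-inclusive and noise-robust, rather than a finite-window quadrature of
noisy samples. Whether the original software truncates at two minutes
instead is not documented; the analytic choice is ours and is exposed
through the fitted parameters for anyone who prefers to re-integrate.

The fit is bounded Levenberg-Marquardt nonlinear least squares on the
second-peak window, started from a log-linearization
(`log C` regressed on `log(t - t0)` and `t - t0` over a grid of candidate
`t0`), with multi-start perturbation on failure. Bounds `a <= 10`,
`b <= 60 s` exclude degenerate spike fits. The appearance time may lie
*inside* the fit window (the model is zero before `t0`), which matters
because the window opens at the valley between the pulmonary and aortic
peaks, before the aortic bolus arrives.

### Peak splitting

The aortic TAC's first peak is pulmonary/lung activity overlapping the
ascending aorta; only the second peak is arterial input. After a 3-point
moving average (configurable), the two tallest local maxima in time order
define the peaks; the minimum between them is the valley; the second-peak
window runs from the valley until the curve falls below 30% of the second
peak (configurable), truncating before recirculation. Fewer than two
detectable peaks is an error directing the user to manual windows — a
deliberate fail-loud choice, since silently fitting a lung peak would bias
every downstream number.

### Lassen correction

Flow-tracer retention saturates at high flow. With reference count `C_r`
and constant `alpha`, counts are linearized as
`corrected = C_r * alpha * x / (1 + alpha - x)` with `x = C/C_r`. The
reference fixed point (`corrected = C_r` at `x = 1`) and the large-`alpha`
identity limit are tested exactly. `alpha` defaults to 1.5, the classical
linearization constant; the source chain for the clinical software does not
reprint its value, so it is configuration, not a constant, here. The
reference is the basal-ganglia mean count, paralleling the PP anchor; ratios
`x >= 1 + alpha` are nonphysical and raise an error naming the segment.

### Patlak transform

For an irreversibly trapped tracer (the microsphere limit appropriate to
ECD's early retention), `Cb(t)/Ca(t)` against `(integral of Ca)/Ca(t)` is a
line with slope Ku. The cumulative input integral is trapezoidal, except
the unobserved leading segment `[0, t1]`, which uses the rectangle
`Ca(t1)*t1` — exact for a constant input and vanishing for a bolus. Points
with `Ca` below 5% of its peak are dropped; the default fit window is the
post-input-peak linear phase. BPI is `scale * Ku`; the normalization used
by the clinical PP software chain is not public, so `bpi_scale` is explicit
configuration and every cross-method test in this package uses scale-free
properties (ranks, correlations, anchors).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lassen_alpha` | 1.5 | — | classical linearization constant; config because the source value is unpublished |
| `ccf` | (supplied) | — | planar/SPECT cross-calibration; measured externally (phantom), see `estimate_ccf()` |
| `basal_ganglia_segments` | lenticular nucleus, thalamus | — | "basal ganglia" read as the two deep grey template segments |
| `normal_side` | left | — | clinically normal hemisphere used for mCBF |
| `bpi_scale` | 2000 | — | BPI per unit Ku (1/s); see below |
| `roi_diameter_px` | 4 | px | the arterial ROI diameter of both methods |
| split `tail_fraction` | 0.3 | — | second-peak truncation before recirculation |
| Patlak input threshold | 0.05 | of peak | drop ratio-unstable points |

On `bpi_scale`: with microsphere kinetics over a 2-minute acquisition, mCBF
values of 20-45 ml/100g/min correspond to Ku of roughly 0.0001-0.005 /s on
realistic count scales, where hemispheric mean counts remain far below the
aortic first-pass peak (as in real angiograms — detection of the aorta by
maximum count depends on it). Scale 2000 maps that Ku band onto the BPI
range the PP calibration line expects. The constant cancels out of every
rank- or correlation-based comparison.

## The synthetic-acquisition simulator

No public image data exist for this acquisition protocol, so the package
ships a forward simulator with known ground truth; it is first-class,
tested code.

What it emulates:

* a 64x64 (configurable to 128x128), 120-frame, 1 s/frame planar chest/brain
  view: a pulmonary disc (gamma variate appearing at 2 s, peaking ~5 s)
  partially overlapping an ascending-aorta disc (gamma variate appearing at
  14 s, peaking ~20 s, radially tapered so the max-count pixel is the vessel
  centre, radius 3.75 px — a ~30 mm vessel at 4 mm pixels), and a brain disc
  following microsphere kinetics `Cb = Ku * integral(Ca)` on the measured
  input;
* a 32^3 SPECT volume whose segment counts are the *inverse* Lassen
  transform of flow-proportional targets (solved as a scalar fixed point
  against the basal-ganglia mean reference), so the analysis pipeline's
  correction recovers flow exactly in the noiseless case;
* a consistent hidden cross-calibration factor tying the planar input
  integral to the SPECT count scale;
* optional per-pixel/per-voxel Poisson noise, with the noiseless aortic ROI
  TAC peaking at ~10^3 counts/frame — a deliberately conservative count
  scale, flagged as a tunable rather than a claim.

What it does **not** emulate: projection/reconstruction physics (OSEM,
Butterworth filtering, attenuation, scatter), collimator blur, anatomy
(the template is a geometric ellipsoid parcellation, synthetic by
construction), patient motion, recirculation, and realistic pulmonary-aortic
transit overlap — the two bolus peaks are more separated than in a real
injection so that second-peak isolation is clean. Passing recovery tests
therefore demonstrates the *analysis chain* is correct and self-consistent,
not that the methods are accurate on clinical data.

Default study conditions mirror the clinical comparison setting: cohorts of
15 subjects with true mCBF uniform on 19-45 ml/100g/min and per-segment
flows perturbed with 12% relative spread.

## Numerical choices and degenerate inputs

* ROI discs include pixels whose centres lie within `d/2` (inclusive) of
  the centre; a 4-px disc has 13 interior pixels. Masks clip at the grid.
* TAC samples sit at frame midpoints; TAC counts are ROI totals (totals
  preserve Poisson statistics), hemispheric output curves are ROI means.
* Detection ties break by earlier frame, then row-major pixel order.
* The Patlak slope is ordinary least squares; a degenerate abscissa (no
  variance in normalized integrated input) is an error, as are windows of
  fewer than 3 points (Patlak) or 5 samples (gamma fit).
* Paired comparisons: both Wilcoxon signed-rank (default — the clinical
  tables report medians/IQRs) and paired t are computed. All-zero
  differences give p = 1 with a warning; constant nonzero differences make
  the t statistic unbounded and are reported as p = 0 with a warning.
* Percentiles use linear interpolation (type 7); variances use the n - 1
  denominator; PP/IBUR ratios are reported for min, max and variance.

## Problem sizes used in the checks

Simulated subjects default to 64x64 planar / 32^3 SPECT grids — small
enough for a desk-scale run while leaving every structure several ROIs
wide. The bundled checks use one noiseless subject for the Patlak oracle, a
15-subject noiseless cohort for end-to-end IBUR recovery (segment errors
~1e-4 relative), 100 Poisson replicates for noise robustness (median mCBF
error ~2-3%), and 1000 random small regressions against a brute-force
normal-equations solver.

## Known limitations

* Decay and timing differences between the 2-minute angiogram and the
  30-minute SPECT are absorbed into the CCF, not modelled separately.
* The IBUR/PP calibration coefficients are taken as given; re-deriving them
  from PET or Xe-133 data is out of scope.
* The automatic detection is exactly the max-count rule; at low count
  scales Poisson noise can displace it a pixel or two, which the simulator
  shows as occasional multi-percent input-integral errors. Real
  implementations with higher counts are less exposed.
* No partial-volume, dispersion or recirculation correction.
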