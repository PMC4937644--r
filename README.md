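# ecdquant

Non-invasive quantification of regional cerebral blood flow (rCBF) from
Tc-99m ECD studies, for nuclear-medicine physicists and imaging researchers
who need the two clinical pipelines — and their comparison — as tested,
scriptable code rather than vendor black boxes.

Two methods are implemented side by side on the same inputs (a dynamic
planar first-pass angiogram, a reconstructed brain SPECT volume, and a
24-segment stereotaxic region template):

* **IBUR — improved brain uptake ratio.** The arterial input ROI (4-pixel
  disc) is placed automatically at the max-count pixel on the ascending
  aorta; the second peak of the input time-activity curve (the first is
  pulmonary transit) is fitted with a gamma variate
  `C(t) = K (t - t0)^a e^{-(t - t0)/b}` whose analytic integral
  `K b^{a+1} Γ(a+1)` gives the input counts; Lassen-corrected SPECT segment
  counts divided by the input and scaled by the planar/SPECT
  cross-calibration factor give the uptake ratio, converted to flow by the
  PET-anchored line

  `rCBF (ml/100g/min) = 3.23 × BUR + 4.66`

* **PP — Patlak plot.** Aortic and hemispheric TACs enter the Patlak
  transform (`Cb/Ca` against `∫Ca/Ca`); the slope Ku, normalized to a brain
  perfusion index (BPI), gives mean CBF through the Xe-133-anchored line

  `mCBF (ml/100g/min) = 2.60 × BPI + 19.8`

  and rCBF is distributed regionally through the Lassen-corrected SPECT
  count distribution, anchored at the basal ganglia.

The calibration intercepts are the methods' minimum reportable flows (4.66
vs 19.8 ml/100g/min), which is why PP compresses the low-flow range while
IBUR can resolve it — the package's comparison statistics (regression,
Pearson r, paired tests, quartile summary tables) make that structural
difference measurable.

Because no public image data exist for this acquisition protocol, the
package includes a synthetic-acquisition simulator with known ground truth
(gamma-variate aortic bolus under an overlapping pulmonary peak,
microsphere brain kinetics, inverse-Lassen SPECT counts, Poisson noise);
every pipeline stage is validated by parameter recovery against it. See the
vignette in `vignettes/cbf-quantification.Rmd` for the models, defaults and
limitations.

## Worked example

```r
library(ecdquant)

## one simulated subject with Poisson counting noise
flows <- make_segment_flows(mcbf_target = 35, seed = 7)
subj  <- simulate_subject(flows, noise = "poisson", seed = 7)
print(subj)
#> Simulated subject: true mCBF 39.9 ml/100g/min, Ku 0.00387 /s

ibur <- ibur_pipeline(subj$series, subj$volume, subj$template, subj$config)
pp   <- patlak_pipeline(subj$series, subj$volume, subj$template, subj$config)
print(ibur)
#> IBUR regional CBF: mCBF 39.7 ml/100g/min (normal side left)
#>   24 segments, rCBF 29.1-46.3 ml/100g/min
print(pp)
#> PP regional CBF: mCBF 40.1 ml/100g/min (normal side left)
#>   24 segments, rCBF 28.1-47.8 ml/100g/min
print(attr(ibur, "fit"))
#> Gamma fit (converged): integral 8950.1 counts*s, rss 7.49e+03
#> Gamma variate: K=182.3, alpha=2.458, beta=2.208 s, t0=14.48 s (peak 19.91 s)
```

Both methods recover the hidden truth (39.9) to within noise: IBUR from the
fitted input integral and calibrated uptake ratios, PP from the Patlak
slope. The fitted bolus (appearance 14.5 s, peak 19.9 s) is the aortic
second peak, isolated from the pulmonary first pass.

A 15-subject comparison, the package's analogue of a clinical method
comparison:

```r
coh <- simulate_cohort(15, seed = 11)
pps <- lapply(coh, function(s) patlak_pipeline(s$series, s$volume, s$template, s$config))
ibs <- lapply(coh, function(s) ibur_pipeline(s$series, s$volume, s$template, s$config))
mc  <- compare_cohort(pps, ibs, "mcbf")
summarize_pair(mc)
#> Method comparison (mcbf level)
#>       n  mean   sd variance   min   max median   p25   p75
#> PP   15 30.27 9.50    90.34 20.06 47.98  28.32 23.15 35.74
#> IBUR 15 29.86 9.99    99.80 17.43 47.97  28.32 23.14 35.73
#> PP/IBUR ratios: min 1.15, max 1.00, variance 0.91
#> Two-tailed p: Wilcoxon 0.000727, paired t 0.0861
```

The min-ratio above 1 with a max-ratio of 1 is the PP floor at work: the
lowest-flow subject (true mCBF below ~20) is reported as 17.4 by IBUR but
no lower than 20.1 by PP.

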