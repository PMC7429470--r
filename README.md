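# mbdwi — multi-b-value DWI models and treatment-response statistics

`mbdwi` is an R toolkit for studies that use multi-b-value diffusion-weighted
MRI (DWI) to predict tumor response to chemoradiotherapy — the setting where
a patient is scanned before treatment (T0) and again very early during
treatment (T1), tumor-ROI diffusion parameters are extracted at both
time-points, and the question is which parameter best separates eventual
complete responders (CR) from incomplete responders (non-CR).

It is aimed at imaging scientists and biostatisticians who want a tested,
scriptable re-implementation of that analysis chain: signal-model fitting,
ROI aggregation, RECIST response classification, group comparison and ROC
statistics — plus a synthetic phantom/cohort generator so the whole pipeline
can be exercised and validated without patient data.

## The models

Signals are acquired at 11 diffusion weightings
(b = 0, 10, 20, 40, 80, 150, 200, 400, 800, 1000, 1200 s/mm²) and fitted
with three decay models:

* **Mono-exponential** — `S/S₀ = exp(−b·ADC)`; the apparent diffusion
  coefficient over all b-values.
* **Bi-exponential (IVIM)** —
  `S/S₀ = (1−f_p)·exp(−b·D_slow) + f_p·exp(−b·D_fast)`; intravoxel
  incoherent motion separates tissue diffusion (`D_slow`) from capillary
  pseudo-diffusion (`D_fast`) weighted by the perfusion fraction `f_p`.
  Because `D_fast` is roughly an order of magnitude larger than `D_slow`,
  fitting is segmented: `D_slow` from b > 200 s/mm² only, then `f_p` and
  `D_fast` on the full curve with `D_slow` fixed.
* **Stretched-exponential** — `S/S₀ = exp(−(b·DDC)^α)`; the distributed
  diffusion coefficient `DDC` and the intravoxel heterogeneity index
  `α ∈ (0, 1]` (α = 1 is homogeneous mono-exponential decay).

All fits are bounded nonlinear least squares on the linear signal scale.
Downstream, parameters are averaged over the three consecutive maximal
tumor slices, patients are dichotomized CR vs non-CR by RECIST v1.1
diameter rules, groups are compared by normality-routed t / Mann-Whitney U
tests, and markers are evaluated by ROC curves with Youden-index cutoffs,
DeLong confidence intervals, and sensitivity/specificity/PPV/NPV.

## Worked example

Fit a noisy IVIM decay curve and run the full simulated study:

```r
library(mbdwi)

set.seed(10)
b <- default_bvalues()
d <- signal_decay(rician_noise(biexp_signal(b, 0.93e-3, 71.63e-3, 0.26, 100), 2))
fit_biexp_segmented(d)
#> biexp fit (converged)
#>   d_slow    0.8760 x1e-3 mm^2/s
#>   d_fast   74.1627 x1e-3 mm^2/s
#>   f_p       0.2799
#>   SSE 31.78 over 11 points
```

At SNR 50 the segmented fit recovers the tissue coefficient within a few
percent; the pseudo-diffusion coefficient is the noisiest parameter, which
is exactly what is seen clinically.

```r
res <- run_simulation_study(pipeline_config(seed = 11))
res$response_rates
#>    label  n percent
#> 1     CR 35   66.04
#> 2 non-CR 18   33.96

res$roc[res$roc$parameter %in% c("adc_t1", "alpha_delta"), ]
#>     parameter   auc ci_lower ci_upper cutoff sensitivity specificity   ppv  npv
#> 1      adc_t1 0.859    0.759    0.958  1.153        74.3        83.3  89.7 62.5
#> 8 alpha_delta 0.844    0.740    0.949  0.028        65.7       100.0 100.0 60.0
```

One simulated cohort (35 CR / 18 non-CR patients drawn from the reference
group distributions) reproduces the expected picture: the intra-treatment
ADC and the change in the heterogeneity index α are the strongest response
predictors, with AUCs in the mid-0.8s, while the perfusion parameters do
not separate the groups.

Phantom images round-trip through NIfTI with an FSL-style `.bval` sidecar:

```r
ph <- make_phantom(tissue_spec("mono", list(adc = 1.08e-3)),
                   grid_shape = c(24, 24, 7), snr = 50, seed = 1)
maps <- fit_volume(ph, "mono")
summarize_roi(maps)          # three-maximal-slice ROI mean
```

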