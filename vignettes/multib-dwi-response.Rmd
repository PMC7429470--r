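---
title: "Methods: multi-b-value DWI models and response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-b-value DWI models and response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdwi)
```

## Scope and design

`mbdwi` re-implements, as a reusable and tested pipeline, the analysis
chain of early-response-prediction DWI studies in pelvic oncology: three
signal-decay models fitted to an 11-b-value acquisition, tumor-ROI
aggregation at two treatment time-points, RECIST-based dichotomization into
complete responders (CR) and incomplete responders (non-CR), and the
associated statistical battery (two-group tests, chi-square, interobserver
ICC, ROC/Youden analysis). Because the kind of patient imaging such studies
use is not publicly deposited, the package carries a first-class synthetic
stage — a voxel-level Rician-noise phantom and a patient-level cohort
generator — whose defaults encode the reference cervical-cancer CCRT cohort
(53 patients, 35 CR / 18 non-CR) that the statistical defaults were taken
from.

The pipeline surface is a set of R functions (`pipeline_config()`,
`run_simulation_study()`, `run_on_images()`) rather than a shell
executable: the intended users script their analyses in R, and a thin CLI
would add nothing over `Rscript -e`.

## Signal models and fitting

All three models are normalized at b = 0 and strictly decreasing in b:

* mono-exponential: $S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$
* bi-exponential (IVIM):
  $S(b) = S_0\left[(1-f_p) e^{-b D_{slow}} + f_p e^{-b D_{fast}}\right]$
* stretched-exponential: $S(b) = S_0 e^{-(b \cdot \mathrm{DDC})^\alpha}$

Diffusivities are stored internally in mm²/s; user-facing tables and file
outputs use the conventional ×10⁻³ mm²/s (conversion is exactly ×1000).

**Objective.** Final estimates always come from bounded Levenberg-Marquardt
least squares on the *linear* signal scale; the log-linear OLS fit serves
only as an initializer. Log-space regression implicitly up-weights high-b
points, exactly where magnitude data hit the Rician noise floor, so it
distorts the noise weighting; linear-scale NLS does not. (Which variant the
vendor workstations use is generally undocumented; offering NLS with a
log-linear initializer covers both behaviours in the noiseless limit.)

**Amplitude.** $S_0$ is always estimated as a free nuisance amplitude
rather than fixed to the measured b = 0 sample, since that sample is itself
noisy.

**Segmented IVIM.** Because $D_{fast}$ exceeds $D_{slow}$ by roughly an
order of magnitude, the perfusion compartment is fully decayed above
b = 200 s/mm². Step 1 fits $A e^{-b D_{slow}}$ to the b > 200 points only
(on the default scheme: 400, 800, 1000, 1200); step 2 freezes $D_{slow}$
and estimates $S_0$, $f_p$, $D_{fast}$ on the full curve. A joint
refinement of all parameters is available (`joint_refine = TRUE`) but off
by default, keeping the canonical segmented behaviour. Preconditions: at
least 3 b-values strictly above and 2 at or below the threshold. Note the
segmentation assumption itself limits accuracy when $D_{fast}$ drops
toward ~10×10⁻³ mm²/s: at b = 400 the perfusion term then still carries
~2% signal, and the segmented $D_{slow}$ absorbs part of it. In the
physiological range of pelvic tumors (~30–120×10⁻³ mm²/s) the noiseless
self-inversion error is far below 0.1%.

**Bounds.** $D_{slow}, \mathrm{ADC}, \mathrm{DDC} \in [10^{-5}, 5\times
10^{-3}]$ mm²/s (ADC lower bound 0 to admit the flat-curve case),
$D_{fast} \in [D_{slow}, 0.5]$, $f_p \in [0,1]$, $\alpha \in [0.01, 1]$ —
generous physiological brackets around every tumor value the package's
defaults encode. The stretched fit is initialized at
$\mathrm{DDC}_0 = \widehat{\mathrm{ADC}}$, $\alpha_0 = 0.8$.

**Degenerate inputs.** Non-positive intensities at b > 0 (noise floor) are
clipped to $10^{-6} S_0$ before the log initializer and counted in the fit
diagnostics. A perfectly flat curve is an exact ADC = 0 solution and is
returned converged with a `zero_decay` flag; a curve with no positive
signal beyond b = 0 is returned non-converged. LM convergence uses tight
tolerances (ftol = ptol = 10⁻¹²) so noiseless round-trips recover
parameters to ≈10⁻⁶ relative error; info codes 1–4 (including gradient
orthogonality) count as convergence. No stochastic restarts are used, so
fits are fully deterministic.

## The phantom

`make_phantom()` builds an axis-aligned ellipsoidal "tumor" (spanning at
least three axial slices, so the ROI protocol is always exercised) inside a
uniform mono-exponential background of ADC 1.5×10⁻³ mm²/s — typical
non-tumor soft tissue; background voxels never enter any statistic.
Voxelwise ground-truth parameters are drawn from truncated normal
distributions around the tissue parameters with coefficient of variation
`intra_tumor_cv` (default 0.1 — true within-tumor heterogeneity is rarely
reported, and 10% keeps voxel fits well-posed while making maps visibly
non-uniform). Truncation is by rejection sampling, not clipping, so bounds
carry no point mass; bi-exponential draws additionally keep
$D_{fast} > D_{slow}$ voxel by voxel.

Noise is Rician, the correct magnitude-MRI model:
$S_{noisy} = \sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0, \sigma^2)$ with
$\sigma = S_0^{mean}/\mathrm{SNR}$. The default SNR of 50 at b = 0 is a
modelling choice (acquisition SNR is almost never reported): high enough
that mono/stretched parameters recover within a few percent, low enough
that the well-known instability of $D_{fast}$ appears — its relative
dispersion across replicates is 2–3× that of $D_{slow}$ in the package's
Monte-Carlo checks. At SNR ≥ 100 the noise is effectively additive
Gaussian (b = 0 bias < 1%).

Phantoms round-trip to disk as 4-D NIfTI + FSL-style `.bval` sidecar +
NIfTI mask and per-parameter truth maps.

**What the phantom does not emulate:** k-space/EPI artifacts, motion,
partial volume, necrotic cores, non-ellipsoidal geometry, spatially
correlated noise. Passing tests therefore validate the *estimators and
statistics*, not robustness to acquisition artifacts.

## The cohort generator

`simulate_cohort()` draws per-patient ROI-mean parameters for the two
groups from the reference distributions in `reference_group_params()`
(means ± SD for six parameters at T0, at T1, and of the change scores;
group sizes 35/18). Three generator decisions matter:

1. **Serial correlation.** The reference tables report not only T0 and T1
   but also the change-score (Δ = T1 − T0) dispersions, and for some
   parameters (α above all: Δα SD 0.02 against T0/T1 SDs of 0.10) the Δ
   dispersion is far smaller than independent draws would give. Serial
   measurements of the same tumor are strongly correlated, and the three
   SDs jointly determine that correlation:
   $\rho = (s_0^2 + s_1^2 - s_\Delta^2) / (2 s_0 s_1)$ (clamped to
   (−1, 1); ≈0.98 for α, ≈0.4 for ADC). Each parameter's (T0, T1) pair is
   drawn from the corresponding truncated bivariate normal, so all three
   stated rows are reproduced marginally. Independent draws would destroy
   the change-score findings entirely.
2. **Independence across parameters.** No cross-parameter covariance is
   published, so parameters are drawn independently per patient. (In real
   tumors ADC, D_slow and DDC are strongly mutually correlated; this
   generator therefore under-disperses any statistic that aggregates
   across parameters, which none of the shipped analyses do.)
3. **Truncation.** Diffusivities > 0, $f_p \in [0,1]$, $\alpha \in (0,1]$,
   enforced by rejection.

With these defaults the simulated study reproduces the expected inference
pattern: over repeated cohorts, ADC-T0, D_slow-T0, DDC-T0, ADC-T1,
D_slow-T1, ΔADC and Δα come out significant in the (large) majority of
replicates and the remaining eleven comparisons do not.

`simulate_two_raters()` adds independent per-rater Gaussian measurement
noise to each patient's value, giving a designed true reliability of
$\mathrm{ICC} = \sigma^2_{between}/(\sigma^2_{between} + \sigma^2_{noise})$
for ICC validation.

## ROI protocol

`select_slices()` returns the window of three consecutive axial slices
maximizing the in-mask voxel count (ties toward the lower start; masks
spanning fewer than three slices are used in full, with a warning). The ROI
mean is the **unweighted mean of the three per-slice means** — the reading
of "the mean value of the three per-slice ROIs" used by radiologists who
delineate one ROI per slice — with a pooled-voxel alternative behind
`pooled = TRUE`. Non-converged voxels are excluded and counted. Necrosis
exclusion is the mask author's responsibility; the package does not second-
guess the mask. Slice indices are 1-based throughout, the R convention.

## Response classification

`classify_recist()` implements the diameter rules as used in this setting:
CR iff no residual tumor (follow-up diameter 0); PR iff shrinkage ≥ 30% of
baseline; PD iff growth ≥ 20%; SD otherwise; both thresholds inclusive.
The full RECIST 1.1 machinery (target/non-target lesions, 5-mm absolute
increase clause) is deliberately out of scope — response labels here feed a
two-group dichotomy, nothing more. The CR group is CR only; PR, SD and PD
form the non-CR group.

## Statistics

* **Normality routing** (`ks_normality()`): Lilliefors-corrected KS by
  default (moments are estimated from the data, so the plain KS null is
  wrong); plain KS by flag. Verdict at α = 0.05 routes to the t test
  (normal) or Mann-Whitney U (non-normal). `compare_groups()` defaults to
  the conventional fixed routing for these six markers (D_slow, DDC, α →
  t; ADC, D_fast, f_p → U), with `route = "auto"` re-screening each column.
* **t test**: pooled-variance Student by default — the classical
  "independent t test" — with Welch behind a flag.
* **Mann-Whitney U**: normal approximation with tie and continuity
  correction; the reported U is the smaller of the two complementary U
  values (≤ n₁n₂/2), the convention of clinical tables. The identity
  AUC = U_favorable/(n₁n₂) ties this to the ROC module and is tested.
* **Chi-square**: Pearson, df = 1, **no continuity correction** — this is
  the variant that exactly reproduces the reference clinical-characteristics
  statistics (0.08, 1.67, 0.58) from their printed counts.
* **ICC**: two-way random-effects, absolute-agreement, single measures —
  ICC(2,1)/ICC(A,1) — with the McGraw–Wong F-based 95% CI; the
  consistency form ICC(C,1) by flag. Absolute agreement is the right
  default for interobserver studies because systematic reader offsets
  should count against reliability.
* **No multiplicity correction** is applied by default (none is standard
  in this literature); all 18 p-values are reported so users can apply
  `p.adjust` if they wish.

## ROC analysis

`roc_curve()` places thresholds at midpoints between consecutive distinct
scores plus ∓∞ sentinels; the orientation is chosen so AUC ≥ 0.5 with the
CR group as the positive class, and a flipped direction is recorded. The
AUC is the trapezoid area, identical to the concordance (pair-counting,
ties = ½) statistic — the test suite verifies this equivalence by brute
force. Confidence intervals use the DeLong estimator by default
(Hanley–McNeil by flag). `youden_cutoff()` maximizes
J = sensitivity + specificity − 1 with ties broken toward higher
sensitivity, then the lower threshold; midpoint cutoffs match how
published optimal cutoffs (e.g. 1.050×10⁻³ mm²/s) are typically printed.
Predictive values report NA, never 0, on empty denominators.

## Validation problem sizes

The shipped checks use: noiseless self-inversion on the default 11-b
scheme (recovery ≈10⁻⁶–10⁻⁴ relative); 500 Rician replicates per model at
SNR 50 (bias < 5% for ADC, D_slow, DDC; α within 0.05; D_fast CV ≳ 2×
D_slow CV); 1000 simulated cohorts for the significance pattern; 8000 per
group for the binormal AUC check (closed form
$\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2}) \approx 0.875$ for the
ADC-T1 distributions); 5000 null simulations bounding both test routes'
type-I error within [0.03, 0.07]. These sizes give Monte-Carlo error
comfortably below every asserted tolerance while keeping the full suite
under a minute.

## Known limitations

* The segmented IVIM fit inherits the b > 200 decoupling assumption; very
  slow pseudo-diffusion biases $D_{slow}$ (see above).
* The cohort generator reproduces marginal distributions and serial
  correlation, not cross-parameter correlation or non-normal shapes; it
  cannot be used to study, e.g., multivariable marker combinations.
* No spatial regularization, registration between time-points, or
  automatic tumor segmentation — masks are inputs.
* Tri-exponential, kurtosis and Bayesian IVIM variants are out of scope.
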