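---
title: "Multi-echo denoising and effect-size analysis with echokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-echo denoising and effect-size analysis with echokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echokit)
```

## The signal model

A gradient-echo EPI voxel acquired at echo time $TE$ follows, to good
approximation, a mono-exponential decay

$$S(v, t, TE) = S_0(v, t)\, e^{-TE \cdot R_2^*(v, t)},$$

with $R_2^* = 1/T_2^*$. The two parameters respond to different physics.
Blood-oxygenation (BOLD) contrast acts on the decay rate: a fractional
change $\delta R_2^*$ produces a percent signal change
$\Delta S / S \approx -TE\,\delta R_2^*$ that grows linearly with $TE$.
Most artifacts — head motion, scanner drift, inflow and pulsatility —
act on the prefactor $S_0$, producing a percent signal change that is the
same at every echo. Acquiring several echoes per volume therefore turns
"is this fluctuation BOLD?" into a measurable regression question in the
TE domain. Everything in this package builds on that dichotomy.

`echokit` implements the full chain: voxelwise $T_2^*$ estimation and
matched-filter echo combination; spatial ICA of the combined data with
per-component TE-dependence ($\kappa$) and TE-independence ($\rho$)
statistics and removal of artifact components; block-design GLM analysis
with standardized group effect sizes; noncentral-$t$ power curves,
bootstrap confidence intervals and the effect-size "boost" comparison of
two pipelines; and seed connectivity from ICA coefficient maps. Because
no suitable public multi-echo dataset ships with the package, a seeded
synthetic-data module generates multi-echo acquisitions with known BOLD
and artifact ground truth, and every stage is validated against that
truth.

## Decay fitting and optimal combination

`fit_decay()` fits the temporal-mean signal of each echo to the decay
model by log-linear least squares; $T_2^* = -1/\text{slope}$ and
$S_0 = e^{\text{intercept}}$. The log-linear (rather than nonlinear) fit
on temporal means is deterministic, fast, and matches how the combination
weights are normally derived. $T_2^*$ is clipped to [2, 300] ms — bounds
bracketing gray matter, white matter and CSF at 3 T — so degenerate fits
(no measurable decay, or a non-positive mean) cannot produce unbounded
weights; non-positive-mean voxels are additionally dropped from the
decomposition mask.

`compute_weights()` evaluates

$$\omega(v, n) = \frac{TE_n\, e^{-TE_n / T_2^*(v)}}
  {\sum_m TE_m\, e^{-TE_m / T_2^*(v)}},$$

whose numerator peaks at $TE = T_2^*$, the echo time of optimal BOLD
contrast. `optimal_combination()` forms the weighted sum over echoes
("TSOC"), a per-voxel matched filter: for equal-variance white noise the
combined series has contrast-to-noise at least that of any single echo.
Weights are computed once from run means (a static-$T_2^*$ assumption),
not per volume.

## TE-dependence decomposition

The combined series is variance-normalized per voxel and reduced by PCA
(`me_pca()`). Rather than an eigenvalue-only cut, every principal
component's time course is refit to each echo's data, and two
one-parameter models are scored per voxel against the per-echo
coefficients $\beta_e(v)$:

* the $R_2^*$ model, $\beta_e(v) \propto -TE_e\,\bar S_e(v)$ — the
  signature of decay-rate (BOLD-like) scaling;
* the $S_0$ model, $\beta_e(v) \propto \bar S_e(v)$ — the signature of
  prefactor (artifact-like) scaling,

where $\bar S_e(v)$ is the voxel's temporal mean at echo $e$. Each model
yields a per-voxel pseudo-F; $\kappa$ and $\rho$ are the map-weighted
averages of the $R_2^*$-model and $S_0$-model F values, with weights equal
to the squared z-scored component map (so component-defining voxels
dominate smoothly, without a hard threshold). Per-voxel F values are
capped at 500 so perfect noiseless fits stay finite; voxels with zero
coefficients at all echoes get weight zero.

Components are retained when $\kappa$, $\rho$, or variance explained
exceeds its spectrum elbow — the point of maximum distance to the chord
joining the first and last sorted values, a deterministic, parameter-free
rule. Two guards make the rule behave at the extremes: the $\kappa$ and
$\rho$ thresholds are clamped from below at the 95% quantile of the null
$F(1, n_E - 1)$ distribution (an elbow below the null level would admit
components indistinguishable from noise), and with fewer than five
candidate components no reduction is attempted (there is no spectrum to
take an elbow of).

The retained subspace is decomposed by spatial FastICA with the tanh
contrast (`spatial_ica()`, backed by `ica::icafast`). ICA sign ambiguity
is fixed by flipping each map to positive skewness, and maps are z-scored
over the mask. Non-convergence triggers up to five restarts from random
rotations under counter-derived seeds (`derive_seed()`), then an error
naming the seeds tried; the convergence tolerance defaults to `1e-5`
with up to 1000 iterations, which converges on the first attempt across
the simulated regimes exercised in the tests.

`classify()` labels every component exactly once: *accepted* when
$\kappa$ clears its elbow and $\kappa / \rho \ge 1$; *rejected* when
$\rho$ clears its elbow and $\rho > \kappa$; *midk* when both statistics
are high, of comparable magnitude (neither dominating by more than a
factor of two) and the component carries high variance — the
mixed BOLD/non-BOLD case, excluded from the accepted set; the remaining
low-evidence components are *ignored* and left in the data. The `ignored`
category is an explicit extension beyond the three-way
BOLD/non-BOLD/midk narrative: removing ambiguous low-variance components
would risk deleting signal on weak evidence.

`denoise_timeseries()` refits the full mixing matrix (all components plus
an intercept) to the combined series by least squares and subtracts only
the fitted contribution of `rejected` and `midk` components. Because this
is a per-voxel linear projection, applying it twice equals applying it
once.

## GLM analysis and effect sizes

`hrf_canonical()` is the conventional double-gamma response (delays
6/16 s, unit dispersions, undershoot ratio 6, unit peak).
`build_design()` convolves condition boxcars with it on a 16-fold
oversampled grid (the convolution kernel is normalized so a sustained
block plateaus at 1), then appends a discrete-cosine high-pass basis with
$\lfloor 2\,T\,f_c \rfloor$ columns at the default cutoff
$f_c = 1/128$ Hz — high-pass filtering as part of the model keeps the
degrees of freedom exact — plus optional nuisance columns and an
intercept, and refuses rank-deficient results by naming the collinear
columns.

`first_level()` is voxelwise OLS; `second_level()` the one-sample
random-effects analysis (mean, unbiased variance, $t$ with $n-1$ df).
The standardized effect size of an ROI is the arithmetic mean over ROI
voxels of $\text{mean}(v)/\sqrt{\text{variance}(v)}$ — a per-voxel
Cohen's-d-like quantity averaged after standardization, not a ratio of
ROI averages. Zero-variance voxels are excluded with a warning. Voxelwise
$p$ values are two-sided (the choice is a documented default; sidedness
is otherwise underdetermined), and `fdr_threshold()` applies
Benjamini–Hochberg. ROI spheres (default radius 8 mm) include a voxel iff
its center lies within the radius; the bundled
`mentalizing_rois.csv` fixture carries the eleven meta-analytic peaks
used throughout, with the right-cerebellar $y$ stored as $-82$ (the
source prints $+82$ in one place and $-82$ in another; the negative sign
is the one consistent with the left-hemisphere homologue).

## Power, bootstrap, and the boost statistic

`power_one_sample_t()` is exact noncentral-$t$ power for the two-sided
one-sample test (noncentrality $d\sqrt n$, df $n-1$); `power_curve()`
evaluates it over $n = 5..100$ and reports the smallest $n$ reaching 80%
power, or absent when the grid never reaches it (absent minima exclude a
region from `cost_savings()`, which otherwise prices the sample-size
difference at a per-subject scanning cost, $500 by default).

`bootstrap_es()` resamples subjects with replacement, recomputes the
second level and ROI effect sizes per resample, and reports percentile
95% intervals — the simplest reproducible interval; BCa was deliberately
not used. The boost statistic
$(ES_A - ES_B)/|ES_B| \times 100$ compares two pipelines; its interval
comes from *paired* resamples (identical subject draws for both
pipelines, enforced by comparing the stored resample indices), because
the comparison is of two analyses of the same cohort and independent
resampling would inflate the interval. Interval coverage is validated
with subject-level draws (each subject's contrast value shared across
the ROI voxels, as the second-level random-effects model assumes);
simulating voxels as independent instead makes the ROI average
artificially precise and exposes the small-sample bias of any
standardized-mean statistic rather than a property of the bootstrap. A boost is called *robust* when
the 2.5% bound exceeds zero; the share of resamples with a positive boost
is reported alongside as a consistency percentage.

## Connectivity

`meicr_map()` correlates ICA coefficient vectors between a seed voxel and
every other voxel, with the component count as the effective degrees of
freedom; maps are sign-normalized before correlating, making the result
invariant to component order and sign. `conventional_map()` is the
baseline: nuisance regression, an ideal FFT bandpass to 0.01–0.1 Hz, and
seed correlation, with effective df approximated as time points times the
band's share of the Nyquist interval (documented as approximate; no
hypothesis tests are attached). `robust_map_correlation()` reports the
Huber M-estimator slope (tuning constant 1.345) on median/MAD
standardized maps — robust standardization matters, since a plain sd is
itself destroyed by the seed-adjacent outliers the method is meant to
resist. `compare_correlations()` is the Fisher-z difference
$(\text{atanh}\,r_1 - \text{atanh}\,r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$
for independent correlations; when applied to map-similarity values it is
an approximation (the maps share voxels), which is why no $p$ values are
attached to it.

## The synthetic-data module

`make_phantom()` builds smooth random $S_0$ and $T_2^*$ fields (defaults
800–1200 a.u. and 30–60 ms, bracketing cortical tissue at 3 T) inside an
ellipsoidal mask. `simulate_subject()` evaluates

$$S = S_0\,(1 + \textstyle\sum \delta S_0)\,
      e^{-TE\,R_2^*\,(1 - \sum \delta R_2^*)} + \varepsilon,$$

where `bold_r2star` sources enter the exponent (positive amplitude =
activation), `artifact_s0`, `drift` and `spike` sources enter the
prefactor, task-locked sources use the block design convolved with the
canonical HRF, and $\varepsilon$ is white Gaussian noise with sd a
fraction of the mean in-mask first-echo signal. Every injected source is
recorded in a truth table from which the noiseless signal reconstructs
exactly (`reconstruct_noiseless()`). `simulate_group()` draws per-subject
task amplitudes from
$\mathcal N(\text{true effect}, \text{between-subject sd}^2)$ and derives
per-subject seeds with a counter rule, so groups are reproducible and
parallelizable.

Default acquisition parameters mirror the targeted protocol: TE =
13/31/48 ms, TR = 2 s, alternating 16-s task and fixation blocks with
four blocks per condition. Amplitudes are the package's own calibration
(no published values exist for them): task $\delta R_2^*/R_2^* = 2\%$ at
block plateau (a robust block-design response; at $TE = T_2^*$ this is a
2% signal change), 30% between-subject coefficient of variation, 5%
$S_0$ artifacts, thermal noise 0.75% of the first-echo mean (large-voxel
acquisitions are physiological- rather than thermal-noise limited, and
physiological noise is modeled explicitly as the artifact sources).
Artifact geometry follows where real artifacts live: a brain-edge rim
(motion), a diffuse blob spanning the task region (pulsatile/
physiological), a global quadratic drift and a global single-volume
spike. The "motion parameters" supplied to the baseline pipeline are the
artifact time courses plus equal-variance independent noise — proxies
that capture roughly half the artifact variance, as real motion estimates
partially track the artifact they cause.

Grid sizes are desk-scale by design: unit tests run on 12×12×8 phantoms,
and the group comparison on 16×16×10 (about 1300 mask voxels), the
smallest grid at which spatial ICA unmixing is reliable — on smaller
grids the artifact components absorb task variance and the comparison
measures unmixing failure rather than denoising. A 12-subject group with
ten ICA pipelines per seed keeps the full validation suite within a few
minutes.

What the simulations do *not* contain tempers what passing tests show:
no rigid-body motion (only its rim-shaped intensity footprint), no
slice-timing or physiological waveforms, white rather than temporally
autocorrelated noise, and mono-exponential decay exactly — so the tests
demonstrate correctness of the algorithms under the stated model, not
performance on real scanner data.

## Numerical choices and limitations

* $T_2^*$ clipped to [2, 300] ms; per-voxel pseudo-F capped at 500;
  FastICA tolerance `1e-5`, 1000 iterations, 5 restarts.
* Eigenvalues below $10^{-9}$ of the largest are treated as rank
  deficiency in `me_pca()`.
* The $\kappa/\rho$ acceptance ratio defaults to 1 (accept when
  $\kappa \ge \rho$), the minimal assumption consistent with the
  dichotomy.
* First-level OLS has no AR(1) prewhitening; inference here is carried by
  the second level, as in standard random-effects practice.
* Runs are analyzed singly; multi-run sessions are averaged at the
  contrast level by the caller.
* The decay fit ignores noise-floor (Rician) bias, acceptable at the
  simulated SNR but a known limitation near signal dropout.

## A worked example

```{r example, eval = FALSE}
subj <- standard_mixture(seed = 7)          # 4 BOLD + 4 artifact sources
res <- run_meica(subj$series, seed = 7)
table(res$components$label)
head(data.frame(kappa = res$components$kappa,
                rho = res$components$rho,
                label = res$components$label))
```

The component table shows the high-$\kappa$ components (the injected
BOLD sources) accepted and the high-$\rho$ ones rejected;
`res$denoised` is the combined series with the rejected sub-model
removed. The README walks through the group-level effect-size comparison
that the acceptance script reproduces end to end.
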