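# echokit

Multi-echo fMRI combination, TE-dependence denoising, and statistical
power analysis in R.

## The problem

Task fMRI is chronically underpowered, and a large part of the problem is
not sample size but noise: motion, pulsatility, drift and other non-BOLD
artifacts inflate within-subject residuals and, downstream, the
between-subject variance that standardized group effect sizes are divided
by. Multi-echo EPI acquires each volume at several echo times (TE), which
makes BOLD and non-BOLD signals physically distinguishable: a BOLD
fluctuation perturbs the decay rate R2\* = 1/T2\*, so its percent signal
change grows linearly with TE, while artifacts perturb the baseline
signal S0 and are TE-independent. `echokit` implements the analysis chain
that exploits this:

* **Decay fitting and optimal combination** — voxelwise log-linear fit of
  S(TE) = S0 · e^(−TE/T2\*), then a matched-filter average of the echoes
  with weights ω(v,n) = TEn·e^(−TEn/T2\*v) / Σm TEm·e^(−TEm/T2\*v)
  (the "TSOC" series, with contrast optimized toward TE = T2\* per voxel).
* **TE-dependence ICA denoising** — PCA with model-based component
  selection, spatial FastICA (tanh contrast), per-echo refits of the
  mixing matrix, component-level pseudo-F statistics κ (TE-dependence,
  BOLD-like) and ρ (TE-independence, artifact-like), four-way
  classification (accepted / rejected / midk / ignored), and subtraction
  of the rejected sub-model from the combined series.
* **GLM effect sizes** — canonical double-gamma HRF, discrete-cosine
  high-pass design (1/128 Hz), voxelwise first-level OLS, one-sample
  second-level random effects, Benjamini–Hochberg FDR, and ROI effect
  sizes ES = mean/sd (Cohen's-d-like, averaged per voxel over 8-mm
  spheres).
* **Power and boost** — exact noncentral-t power for the one-sample
  design over n = 5..100, minimum n for 80% power, percentile bootstrap
  CIs, the effect-size boost (ES_A − ES_B)/|ES_B| · 100 with paired
  bootstrap robustness, and per-subject cost savings.
* **Connectivity** — seed connectivity from ICA coefficient maps (with
  component count as effective df), a conventional bandpass baseline,
  Huber-robust map similarity, and Fisher-z comparison of correlations.
* **Synthetic multi-echo data** — seeded phantoms, block designs, and
  BOLD/artifact sources with exact ground truth, used to validate every
  stage (no public multi-echo dataset ships with the package).

See `vignettes/multiecho-denoising.Rmd` for the model, the tunable
parameters, and the design decisions.

## Worked example

Simulate a subject carrying four BOLD-like (ΔR2\*) and four artifact-like
(ΔS0) sources at TE = 13/31/48 ms, run the full denoising pipeline, and
look at the component table:

```r
library(echokit)
subj <- standard_mixture(seed = 3)
res <- run_meica(subj$series, seed = 3)
table(res$components$label)
#> accepted  ignored rejected
#>        6       12        3
```

The top components by variance explained:

```r
#>   kappa   rho varex    label
#> 1  15.0 356.9 16.61 rejected
#> 2 218.6  31.3 11.84 accepted
#> 3 299.6  30.8 11.03 accepted
#> 4  12.0 339.5 10.12 rejected
#> 5   7.7 378.8  9.87 rejected
#> 6 274.7  50.9  8.90 accepted
#> 7 267.5  31.7  8.46 accepted
```

The four injected BOLD sources surface as the high-κ, low-ρ accepted
components; the injected S0 artifacts as the high-ρ rejected ones
(κ and ρ are pseudo-F statistics, so ~300 against ~30 is a decisive
margin). `res$denoised` is the combined time series with the rejected
sub-model regressed out; `write_component_table()` saves the table as
TSV.

Power planning from two effect sizes (say, 0.62 after denoising vs 0.45
without):

```r
min_n(power_curve(0.62))        # 23 subjects for 80% power
min_n(power_curve(0.45))        # 41 subjects
cost_savings(23, 41, 500)       # $9000 saved at $500/subject
boost(0.62, 0.45)               # +37.8% effect-size boost
```

A command-line wrapper ships in `exec/`:

```sh
echokit simulate --out-dir sim/ --seed 1
echokit denoise --echoes sim/sub-01_echo-1_bold.nii.gz,sim/sub-01_echo-2_bold.nii.gz,sim/sub-01_echo-3_bold.nii.gz \
        --te 13,31,48 --tr 2 --seed 1 --out-prefix sim/sub-01
```

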