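Package: echokit
Title: Multi-Echo fMRI Combination, TE-Dependence Denoising, and Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for multi-echo echo-planar fMRI: voxelwise mono-exponential
    T2* decay fitting, T2*-weighted optimal echo combination, spatial ICA with
    TE-dependence (kappa) and TE-independence (rho) component classification
    and removal of artifact components, block-design GLM analysis with
    standardized effect sizes, noncentral-t power curves with bootstrap
    effect-size-boost statistics, and seed-based connectivity from ICA
    coefficient maps. Includes a seeded synthetic multi-echo data generator
    with known BOLD and artifact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ica,
    MASS,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
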