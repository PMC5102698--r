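# Shared fixtures for the test suite, all generated in code.
#
# The group scenario mirrors the acquisition the package targets: three
# echoes at TE = 13/31/48 ms, TR = 2 s, alternating 16-s task and fixation
# blocks (4 blocks per condition), a distributed network-like task-locked
# BOLD source, and per-subject non-BOLD artifacts (a brain-edge motion rim,
# a diffuse physiological blob over the task region, a global quadratic
# drift, and a global spike) whose time courses are only partially captured
# by the six "motion parameter" proxy regressors.

# Small grid for cheap unit tests (phantom recovery, weights, GLM algebra).
test_shape <- c(12, 12, 8)
test_voxel_mm <- 4
test_affine <- grid_affine(test_shape, test_voxel_mm)

# Larger grid for the group denoising scenario: spatial ICA unmixing
# quality scales with the number of mask voxels.
grp_shape <- c(16, 16, 10)
grp_affine <- grid_affine(grp_shape, test_voxel_mm)
grp_scale <- grp_shape / c(12, 12, 8)
grp_task_center_vox <- c(4, 8, 4) * grp_scale
grp_task_roi <- roi_spec(
  "task", as.numeric(grp_affine %*% c(grp_task_center_vox - 1, 1))[1:3],
  radius_mm = 8)

# Distributed task activation: four blobs, like a task-positive network.
grp_network_map <- function(shape = grp_shape) {
  sc <- shape / c(12, 12, 8)
  m <- gaussian_blob(shape, c(4, 8, 4) * sc, fwhm_vox = 3.5 * sc[1]) +
    gaussian_blob(shape, c(8, 9, 5) * sc, fwhm_vox = 3.5 * sc[1]) +
    gaussian_blob(shape, c(6, 3, 4) * sc, fwhm_vox = 3.5 * sc[1]) +
    gaussian_blob(shape, c(3, 4, 5) * sc, fwhm_vox = 3.5 * sc[1])
  pmin(m, 1)
}

# Per-subject artifacts: spatially extensive non-BOLD sources whose time
# courses are random per subject. Amplitudes are fractions of S0.
make_artifact_fun <- function(amplitude = 0.05, mask) {
  force(amplitude)
  rim <- edge_rim_map(mask)
  function(seed, design, shape) {
    set.seed(derive_seed(seed, 500L))
    nt <- design$n_volumes
    sc <- shape / c(12, 12, 8)
    list(source_spec("artifact_s0", rim, smooth_time_course(nt, 2),
                     amplitude, name = "rim_motion"),
         source_spec("artifact_s0",
                     gaussian_blob(shape, c(5, 7, 4) * sc,
                                   fwhm_vox = 9 * sc[1]),
                     smooth_time_course(nt, 2), amplitude,
                     name = "diffuse_physio"),
         drift_source(array(1, shape), nt, order = 2,
                      amplitude = amplitude / 2),
         spike_source(array(1, shape), nt, at = sample.int(nt, 1),
                      amplitude = amplitude))
  }
}

make_test_template <- function(seed = 1L, artifact_amplitude = 0.05,
                               noise_sd = 0.0075, shape = grp_shape) {
  decay <- make_phantom(shape, seed = derive_seed(seed, 900L))
  design <- make_block_design(4, 16, 16, 2)
  group_template(decay, design,
                 te_ms = c(13, 31, 48), noise_sd = noise_sd,
                 task_map = grp_network_map(shape),
                 task_condition = "mentalizing",
                 artifact_fun = make_artifact_fun(artifact_amplitude,
                                                  decay$mask))
}

# Six-column motion-parameter proxy: the artifact time courses plus
# independent smooth noise (partial coupling, as real motion estimates
# are), padded to six columns.
motion_proxy <- function(subject, seed, coupling_noise = 1) {
  set.seed(derive_seed(seed, 600L))
  tcs <- lapply(subject$truth$sources, function(s)
    if (s$kind != "bold_r2star") s$time_course else NULL)
  tcs <- Filter(Negate(is.null), tcs)
  nt <- length(tcs[[1]])
  cols <- lapply(tcs, function(tc)
    tc + coupling_noise * smooth_time_course(nt, sigma_vol = 2))
  while (length(cols) < 6) {
    cols <- c(cols, list(smooth_time_course(nt, sigma_vol = 2)))
  }
  do.call(cbind, cols[1:6])
}

# Run the two first-level pipelines on one subject: ME-ICA denoised (no
# motion regressors) and TSOC + motion regression. Returns the two masked
# contrast maps and the shared mask.
run_subject_pipelines <- function(subject, design, seed) {
  res <- run_meica(subject$series, seed = seed)
  contrast <- c(mentalizing = 1, physical = -1)
  fl_a <- first_level(res$denoised, build_design(design), contrast)
  mot <- motion_proxy(subject, seed)
  fl_b <- first_level(res$tsoc, build_design(design, nuisance = mot),
                      contrast)
  list(con_meica = fl_a$contrast_map, con_tsoc = fl_b$contrast_map,
       mask = res$tsoc$mask, meica = res)
}

# Group-level contrast stacks and ROI effect sizes under both pipelines.
run_group_pipelines <- function(seed, n_subjects = 12, true_effect = 0.02,
                                between_subject_sd = 0.006,
                                artifact_amplitude = 0.05) {
  template <- make_test_template(seed,
                                 artifact_amplitude = artifact_amplitude)
  grp <- simulate_group(template, n_subjects, true_effect,
                        between_subject_sd, seed = seed)
  cons_a <- cons_b <- NULL
  mask <- NULL
  for (i in seq_len(n_subjects)) {
    pl <- run_subject_pipelines(grp$subjects[[i]], template$design,
                                seed = derive_seed(seed, 700L + i))
    if (is.null(mask)) mask <- pl$mask
    stopifnot(identical(mask, pl$mask))
    cons_a <- cbind(cons_a, pl$con_meica)
    cons_b <- cbind(cons_b, pl$con_tsoc)
  }
  gr_a <- second_level(cons_a, mask = mask, shape = grp_shape)
  gr_b <- second_level(cons_b, mask = mask, shape = grp_shape)
  list(es_meica = roi_effect_size(gr_a, grp_task_roi, grp_affine),
       es_tsoc = roi_effect_size(gr_b, grp_task_roi, grp_affine),
       cons_meica = cons_a, cons_tsoc = cons_b, mask = mask, group = grp)
}

vox_by_time_test <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, prod(d[1:3]), d[4])
}
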