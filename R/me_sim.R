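## Synthetic multi-echo data generation.
##
## The generator produces per-echo 4-d time series from a voxelwise
## mono-exponential decay model S(v, t, TE) = S0(v) * (1 + sum dS0 terms) *
## exp(-TE * R2*(v) * (1 - sum dR2* terms)) + thermal noise, so that
## BOLD-like sources (which perturb the decay rate R2*) show percent signal
## change growing linearly with TE while artifact-like sources (which
## perturb the prefactor S0) produce TE-independent percent signal change.
## Every injected source is recorded in a truth table so downstream stages
## (decay fitting, optimal combination, ICA classification, GLM effect
## sizes) can be validated against known ground truth.

#' Voxelwise decay model (S0 and T2* maps)
#'
#' @param s0 3-d array of baseline (TE = 0) signal, arbitrary units.
#' @param t2star 3-d array of transverse decay constants, ms.
#' @param mask logical 3-d array marking brain voxels.
#' @return an object of class `decay_model`.
#' @export
decay_model <- function(s0, t2star, mask) {
  if (!identical(dim(s0), dim(t2star)) || !identical(dim(s0), dim(mask)))
    stop_invalid("s0, t2star and mask must share one grid")
  if (any(t2star[mask] <= 0)) stop_invalid("t2star must be > 0 inside the mask")
  if (any(s0[mask] <= 0)) stop_invalid("s0 must be > 0 inside the mask")
  structure(list(s0 = s0, t2star = t2star, mask = mask, shape = dim(s0)),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("decay_model:", paste(x$shape, collapse = " x "),
      "grid,", sum(x$mask), "voxels in mask\n")
  cat("  T2* range in mask:",
      paste(signif(range(x$t2star[x$mask]), 4), collapse = " - "), "ms\n")
  invisible(x)
}

#' Generate a smooth random decay phantom
#'
#' Builds spatially smooth random S0 and T2* fields inside an ellipsoidal
#' "brain" mask, emulating tissue T2* heterogeneity (some voxels with
#' T2* above the echo times, others below).
#'
#' @param shape grid dimensions, three positive integers.
#' @param s0_range range (low, high) of baseline signal, arbitrary units.
#' @param t2star_range_ms range (low, high) of T2*, ms.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @param smooth_sigma Gaussian smoothing sigma in voxels for the random
#'   fields.
#' @return a [decay_model()].
#' @examples
#' ph <- make_phantom(c(12, 12, 8), seed = 1)
#' range(ph$t2star[ph$mask])
#' @export
make_phantom <- function(shape, s0_range = c(800, 1200),
                         t2star_range_ms = c(30, 60), seed = 1L,
                         smooth_sigma = 1.2) {
  shape <- check_shape3(shape)
  if (any(s0_range <= 0) || any(t2star_range_ms <= 0))
    stop_invalid("range bounds must be positive")
  if (s0_range[1] > s0_range[2] || t2star_range_ms[1] > t2star_range_ms[2])
    stop_invalid("range low must not exceed range high")
  set.seed(seed)
  s0 <- rescale_range(smooth3d(array(rnorm(prod(shape)), shape), smooth_sigma),
                      s0_range[1], s0_range[2])
  t2 <- rescale_range(smooth3d(array(rnorm(prod(shape)), shape), smooth_sigma),
                      t2star_range_ms[1], t2star_range_ms[2])
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  inside <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
    ((g$k - ctr[3]) / semi[3])^2 <= 1
  mask <- array(inside, shape)
  decay_model(s0, t2, mask)
}

#' Block task design
#'
#' @param conditions character vector of condition labels.
#' @param events data.frame with columns `onset` (s), `duration` (s),
#'   `trial_type`.
#' @param tr repetition time, s.
#' @param n_volumes number of volumes in the run.
#' @return an object of class `task_design`.
#' @export
task_design <- function(conditions, events, tr, n_volumes) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "trial_type") %in% names(events)))
  if (tr <= 0) stop_invalid("tr must be > 0")
  if (any(events$onset < 0)) stop_invalid("onsets must be >= 0")
  if (any(events$duration <= 0)) stop_invalid("durations must be > 0")
  if (any(events$onset + events$duration > n_volumes * tr))
    stop_invalid("events must end within the run")
  structure(list(conditions = conditions, events = events, tr = tr,
                 n_volumes = as.integer(n_volumes)),
            class = "task_design")
}

#' Build an alternating block design
#'
#' Condition blocks alternate between conditions and are separated from each
#' other (and preceded) by fixation periods, the usual layout of a two-run
#' block paradigm (e.g. 4 blocks per condition of 16 s separated by 16 s
#' fixation at TR = 2 s).
#'
#' @param n_blocks_per_condition number of blocks per condition.
#' @param block_s block duration, s.
#' @param fixation_s fixation duration between blocks (and before the first
#'   block), s.
#' @param tr repetition time, s.
#' @param conditions condition labels (blocks alternate in this order).
#' @return a [task_design()].
#' @examples
#' d <- make_block_design(4, 16, 16, 2)
#' nrow(d$events)  # 8 task blocks
#' @export
make_block_design <- function(n_blocks_per_condition, block_s = 16,
                              fixation_s = 16, tr = 2,
                              conditions = c("mentalizing", "physical")) {
  if (tr <= 0) stop_invalid("tr must be > 0")
  if (block_s <= 0 || fixation_s < 0) stop_invalid("durations must be positive")
  if (n_blocks_per_condition < 1) stop_invalid("need at least one block")
  nb <- n_blocks_per_condition * length(conditions)
  onsets <- fixation_s + (seq_len(nb) - 1) * (block_s + fixation_s)
  types <- rep(conditions, length.out = nb)
  total <- fixation_s + nb * (block_s + fixation_s)
  n_volumes <- ceiling(total / tr)
  task_design(conditions,
              data.frame(onset = onsets, duration = block_s,
                         trial_type = types, stringsAsFactors = FALSE),
              tr, n_volumes)
}

#' Signal source specification for the simulator
#'
#' A source is the outer product of a spatial weight map and a time course,
#' scaled by a fractional amplitude. `bold_r2star` sources modulate the
#' decay exponent (amplitude is a fractional change of R2*, so percent
#' signal change grows linearly with TE); `artifact_s0`, `drift` and
#' `spike` sources modulate the signal prefactor (fractional change of S0,
#' TE-independent percent signal change).
#'
#' @param kind one of `"bold_r2star"`, `"artifact_s0"`, `"drift"`,
#'   `"spike"`.
#' @param spatial_map 3-d array of unitless voxel weights.
#' @param time_course numeric vector, one value per volume; may be `NULL`
#'   for a `bold_r2star` source with a `condition`, in which case
#'   [simulate_subject()] uses the task design convolved with the canonical
#'   HRF.
#' @param amplitude fractional change (dR2*/R2* or dS0/S0) at
#'   map = time course = 1.
#' @param condition optional condition label driving a task-locked source.
#' @param name optional source label.
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(kind, spatial_map, time_course = NULL, amplitude,
                        condition = NULL, name = NULL) {
  kind <- match.arg(kind, c("bold_r2star", "artifact_s0", "drift", "spike"))
  if (!is.finite(amplitude)) stop_invalid("amplitude must be finite")
  if (is.null(time_course) && is.null(condition))
    stop_invalid("a source needs a time_course or a task condition")
  structure(list(kind = kind, spatial_map = spatial_map,
                 time_course = time_course, amplitude = amplitude,
                 condition = condition,
                 name = name %||% kind),
            class = "source_spec")
}

#' Gaussian blob spatial map
#'
#' @param shape grid dimensions.
#' @param center blob center in voxel coordinates (may be fractional).
#' @param fwhm_vox full width at half maximum in voxels.
#' @return 3-d array with maximum 1 at the center.
#' @export
gaussian_blob <- function(shape, center, fwhm_vox = 3) {
  shape <- check_shape3(shape)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(exp(-d2 / (2 * sigma^2)), shape)
}

#' Low-order polynomial drift source
#'
#' @param spatial_map voxel weights (typically broad).
#' @param n_volumes run length in volumes.
#' @param order polynomial order (1 = linear, 2 adds quadratic, ...).
#' @param amplitude fractional dS0/S0 at the run end.
#' @param coef polynomial coefficients (length `order`); defaults to equal
#'   weights.
#' @return a [source_spec()] of kind `"drift"`.
#' @export
drift_source <- function(spatial_map, n_volumes, order = 2, amplitude = 0.02,
                         coef = NULL) {
  x <- seq(-1, 1, length.out = n_volumes)
  coef <- coef %||% rep(1, order)
  tc <- rowSums(outer(x, seq_len(order), "^") %*% diag(coef, nrow = order))
  tc <- tc / max(abs(tc))
  source_spec("drift", spatial_map, tc, amplitude, name = "drift")
}

#' Single-volume spike source
#'
#' @param spatial_map voxel weights.
#' @param n_volumes run length in volumes.
#' @param at volume index of the spike.
#' @param amplitude fractional dS0/S0 at the spike.
#' @return a [source_spec()] of kind `"spike"`.
#' @export
spike_source <- function(spatial_map, n_volumes, at, amplitude = 0.05) {
  if (at < 1 || at > n_volumes) stop_invalid("spike volume outside the run")
  tc <- numeric(n_volumes)
  tc[at] <- 1
  source_spec("spike", spatial_map, tc, amplitude, name = "spike")
}

#' Task-locked BOLD time course
#'
#' Boxcar of one condition convolved with the canonical double-gamma HRF and
#' sampled at the TR; the convolution kernel is normalized so a sustained
#' block plateaus at 1, making source amplitudes interpretable as the
#' fractional change at plateau.
#'
#' @param design a [task_design()].
#' @param condition condition label.
#' @return numeric vector of length `design$n_volumes`.
#' @export
task_time_course <- function(design, condition) {
  if (!condition %in% design$conditions)
    stop_invalid("unknown condition: ", condition)
  ev <- design$events[design$events$trial_type == condition, , drop = FALSE]
  convolve_boxcar(ev, design$tr, design$n_volumes)
}

## Shared fine-grid boxcar * HRF convolution (also used by build_design).
convolve_boxcar <- function(events, tr, n_volumes, oversample = 16L) {
  dt <- tr / oversample
  nf <- n_volumes * oversample
  box <- numeric(nf)
  tgrid <- (seq_len(nf) - 1) * dt
  for (r in seq_len(nrow(events))) {
    box[tgrid >= events$onset[r] & tgrid < events$onset[r] + events$duration[r]] <- 1
  }
  h <- hrf_canonical(dt)
  h <- h / sum(h)  # sustained block plateaus at 1
  x <- stats::convolve(box, rev(h), type = "open")[seq_len(nf)]
  x[seq(1L, nf, by = oversample)]
}

#' Brain-edge rim map
#'
#' Spatial weight map concentrated at the mask boundary, the characteristic
#' footprint of rigid-body motion artifact (signal change is largest where
#' the intensity gradient is steepest, i.e. at brain edges).
#'
#' @param mask logical 3-d brain mask.
#' @param sigma_vox smoothing sigma (voxels) controlling rim thickness.
#' @return 3-d array with maximum 1 on the rim, 0 outside the mask.
#' @export
edge_rim_map <- function(mask, sigma_vox = 1.2) {
  sm <- smooth3d(mask * 1, sigma_vox)
  rim <- mask * (1 - pmin(sm / max(sm[mask]), 1))
  rim / max(rim)
}

#' Smooth random source time course
#'
#' Gaussian white noise smoothed with a Gaussian kernel and standardized to
#' mean 0, sd 1 — a generic slowly varying artifact or source time course.
#' Uses the current RNG state (seed outside for reproducibility).
#'
#' @param n_volumes length in volumes.
#' @param sigma_vol smoothing sigma in volumes.
#' @return numeric vector of length `n_volumes`.
#' @export
smooth_time_course <- function(n_volumes, sigma_vol = 2) {
  tc <- as.vector(conv_cols(matrix(stats::rnorm(n_volumes), ncol = 1),
                            gauss_kernel1d(sigma_vol)))
  (tc - mean(tc)) / stats::sd(tc)
}

#' Simulate one subject's multi-echo acquisition
#'
#' Evaluates the decay signal model with the injected sources and adds white
#' Gaussian thermal noise. The noise standard deviation is `noise_sd` times
#' the mean noiseless in-mask signal at the earliest TE, applied to every
#' echo. Returns the per-echo series plus a truth record containing the
#' realized map, time course and amplitude of every injected source, from
#' which the noiseless signal can be reconstructed exactly with
#' [reconstruct_noiseless()].
#'
#' @param decay a [decay_model()].
#' @param design a [task_design()].
#' @param sources list of [source_spec()] objects.
#' @param te_ms echo times, ms, strictly increasing, at least two.
#' @param noise_sd thermal noise sd as a fraction of mean in-mask signal at
#'   the earliest TE.
#' @param seed integer seed for the noise draw.
#' @return a list of class `me_subject` with elements `series` (an
#'   [me_series()]) and `truth`.
#' @export
simulate_subject <- function(decay, design, sources = list(),
                             te_ms = c(13, 31, 48), noise_sd = 0.02,
                             seed = 1L) {
  if (length(te_ms) < 2) stop_invalid("need at least two echo times")
  if (any(diff(te_ms) <= 0)) stop_invalid("te_ms must be strictly increasing")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  shape <- decay$shape
  nv <- prod(shape)
  nt <- design$n_volumes

  d_r2 <- matrix(0, nv, nt)   # summed fractional dR2*/R2* field
  d_s0 <- matrix(0, nv, nt)   # summed fractional dS0/S0 field
  truth_sources <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    tc <- src$time_course
    if (is.null(tc)) {
      if (src$kind != "bold_r2star")
        stop_invalid("only bold_r2star sources can be task-locked")
      tc <- task_time_course(design, src$condition)
    }
    if (length(tc) != nt) stop_invalid("time course length must match volumes")
    contrib <- src$amplitude * outer(as.vector(src$spatial_map), tc)
    if (src$kind == "bold_r2star") d_r2 <- d_r2 + contrib
    else d_s0 <- d_s0 + contrib
    truth_sources[[i]] <- list(name = src$name, kind = src$kind,
                               amplitude = src$amplitude,
                               spatial_map = src$spatial_map,
                               time_course = tc)
  }

  s0 <- as.vector(decay$s0)
  r2 <- 1 / as.vector(decay$t2star)
  pre <- (1 + d_s0) * s0           # rows scaled by S0(v)
  clean <- vector("list", length(te_ms))
  for (e in seq_along(te_ms)) {
    clean[[e]] <- pre * exp(-te_ms[e] * r2 * (1 - d_r2))
  }
  sd_abs <- noise_sd * mean(clean[[1]][as.vector(decay$mask), ])

  set.seed(seed)
  echoes <- vector("list", length(te_ms))
  for (e in seq_along(te_ms)) {
    eps <- if (sd_abs > 0) matrix(rnorm(nv * nt, sd = sd_abs), nv, nt) else 0
    echoes[[e]] <- array(clean[[e]] + eps, c(shape, nt))
  }

  series <- me_series(echoes, te_ms, design$tr, decay$mask)
  truth <- list(sources = truth_sources, noise_sd = noise_sd,
                noise_sd_abs = sd_abs, seed = seed, te_ms = te_ms,
                design = design)
  structure(list(series = series, truth = truth), class = "me_subject")
}

#' Reconstruct the noiseless multi-echo signal from a truth record
#'
#' @param decay the [decay_model()] used in the simulation.
#' @param truth the truth record returned by [simulate_subject()].
#' @return list of 4-d arrays, one per echo, equal to the emitted data minus
#'   the noise draw.
#' @export
reconstruct_noiseless <- function(decay, truth) {
  shape <- decay$shape
  nv <- prod(shape)
  nt <- truth$design$n_volumes
  d_r2 <- matrix(0, nv, nt)
  d_s0 <- matrix(0, nv, nt)
  for (src in truth$sources) {
    contrib <- src$amplitude * outer(as.vector(src$spatial_map),
                                     src$time_course)
    if (src$kind == "bold_r2star") d_r2 <- d_r2 + contrib
    else d_s0 <- d_s0 + contrib
  }
  s0 <- as.vector(decay$s0)
  r2 <- 1 / as.vector(decay$t2star)
  pre <- (1 + d_s0) * s0
  lapply(truth$te_ms, function(te) array(pre * exp(-te * r2 * (1 - d_r2)),
                                         c(shape, nt)))
}

#' Group simulation template
#'
#' Bundles the pieces shared by all subjects of a simulated group: the decay
#' phantom, the task design, the echo times, the task activation map, and a
#' generator of per-subject artifact sources.
#'
#' @param decay a [decay_model()].
#' @param design a [task_design()].
#' @param te_ms echo times, ms.
#' @param noise_sd thermal noise fraction.
#' @param task_map spatial map of the task-locked BOLD source.
#' @param task_condition condition driving the BOLD source.
#' @param artifact_fun `function(seed, design, shape)` returning a list of
#'   artifact [source_spec()]s for one subject (or `NULL` for none).
#' @return an object of class `group_template`.
#' @export
group_template <- function(decay, design, te_ms = c(13, 31, 48),
                           noise_sd = 0.02, task_map,
                           task_condition = "mentalizing",
                           artifact_fun = NULL) {
  structure(list(decay = decay, design = design, te_ms = te_ms,
                 noise_sd = noise_sd, task_map = task_map,
                 task_condition = task_condition,
                 artifact_fun = artifact_fun),
            class = "group_template")
}

#' Simulate a group of subjects with between-subject effect variability
#'
#' Each subject's task amplitude (fractional dR2*/R2* at block plateau) is
#' drawn from Normal(`true_effect`, `between_subject_sd`^2); subject data
#' are then simulated with [simulate_subject()] under per-subject seeds
#' derived from the master seed with [derive_seed()].
#'
#' @param template a [group_template()].
#' @param n_subjects number of subjects, at least 2.
#' @param true_effect mean task amplitude across subjects.
#' @param between_subject_sd sd of the per-subject amplitude.
#' @param seed master seed.
#' @return a list of class `group_sim` with `subjects` (list of
#'   `me_subject`), `amplitudes`, `template`, `seed`.
#' @export
simulate_group <- function(template, n_subjects, true_effect = 0.01,
                           between_subject_sd = 0.003, seed = 1L) {
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  if (between_subject_sd < 0) stop_invalid("between_subject_sd must be >= 0")
  set.seed(derive_seed(seed, 0L))
  amps <- rnorm(n_subjects, true_effect, between_subject_sd)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- derive_seed(seed, i)
    bold <- source_spec("bold_r2star", template$task_map,
                        time_course = NULL, amplitude = amps[i],
                        condition = template$task_condition, name = "task")
    art <- if (is.null(template$artifact_fun)) list()
           else template$artifact_fun(sseed, template$design,
                                      template$decay$shape)
    subjects[[i]] <- simulate_subject(template$decay, template$design,
                                      c(list(bold), art), template$te_ms,
                                      template$noise_sd, seed = sseed)
  }
  structure(list(subjects = subjects, amplitudes = amps, template = template,
                 true_effect = true_effect,
                 between_subject_sd = between_subject_sd, seed = seed),
            class = "group_sim")
}

#' Standard eight-source test mixture
#'
#' Simulates a single subject carrying four `bold_r2star` and four
#' `artifact_s0` sources with compact Gaussian-blob maps and independent
#' smooth random time courses — the canonical ground-truth mixture used to
#' validate TE-dependence component classification.
#'
#' @param seed integer seed.
#' @param shape grid dimensions.
#' @param amplitude fractional source amplitude (dR2*/R2* resp. dS0/S0).
#' @param noise_sd thermal noise fraction.
#' @param n_volumes run length in volumes.
#' @return an `me_subject` whose truth record labels each source kind.
#' @export
standard_mixture <- function(seed = 1L, shape = c(12, 12, 8),
                             amplitude = 0.05, noise_sd = 0.005,
                             n_volumes = 140L) {
  decay <- make_phantom(shape, seed = derive_seed(seed, 90L))
  design <- task_design("none",
                        data.frame(onset = 0, duration = 1,
                                   trial_type = "none"),
                        tr = 2, n_volumes = n_volumes)
  centers <- list(c(3.5, 5, 4), c(9, 4, 5), c(6, 9.5, 3), c(4, 9, 6),
                  c(8.5, 8.5, 4), c(3.5, 3.5, 5.5), c(6.5, 3, 3.5),
                  c(9, 6.5, 6))
  centers <- lapply(centers, function(cc) cc * shape / c(12, 12, 8))
  kinds <- rep(c("bold_r2star", "artifact_s0"), each = 4)
  set.seed(derive_seed(seed, 91L))
  sources <- vector("list", 8)
  for (i in 1:8) {
    tc <- smooth_time_course(n_volumes, sigma_vol = 1.5)
    sources[[i]] <- source_spec(kinds[i],
                                gaussian_blob(shape, centers[[i]],
                                              fwhm_vox = 3),
                                tc, amplitude,
                                name = sprintf("%s_%d", kinds[i], i))
  }
  simulate_subject(decay, design, sources, te_ms = c(13, 31, 48),
                   noise_sd = noise_sd, seed = derive_seed(seed, 92L))
}
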