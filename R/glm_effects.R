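## Block-design GLM analysis: canonical HRF, design matrix with
## discrete-cosine high-pass basis, voxelwise first-level OLS, one-sample
## second-level random-effects analysis, Benjamini-Hochberg FDR
## thresholding, and ROI-averaged standardized effect size (mean / sd,
## analogous to Cohen's d).

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional double-gamma impulse response (response peak around 5 s,
#' undershoot around 15 s; delays 6 / 16 s, unit dispersions,
#' peak:undershoot ratio 6), evaluated on a grid of spacing `dt` over
#' `duration_s` seconds and normalized to unit peak. The value at t = 0 is
#' exactly 0.
#'
#' @param dt sampling interval, s.
#' @param duration_s kernel length, s.
#' @param peak_delay,undershoot_delay gamma delays, s.
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio peak to undershoot amplitude ratio.
#' @return numeric kernel.
#' @export
hrf_canonical <- function(dt, duration_s = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 6) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  t <- seq(0, duration_s, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h / max(h)
}

#' Build a first-level design matrix
#'
#' Condition boxcars convolved with the canonical HRF (sampled at the TR),
#' a discrete-cosine high-pass basis up to the cutoff (the SPM convention:
#' floor(2 * run duration * cutoff) columns, so high-pass filtering is part
#' of the model and degrees of freedom stay exact), optional nuisance
#' columns (e.g. six motion parameters), and an intercept.
#'
#' @param design a [task_design()].
#' @param n_volumes run length (defaults to the design's).
#' @param highpass_hz high-pass cutoff, Hz.
#' @param nuisance optional volumes x k matrix of nuisance regressors.
#' @return an object of class `design_matrix`: `X` (volumes x columns),
#'   `names`, `highpass_hz`. Errors if the result is rank deficient, naming
#'   the offending columns.
#' @examples
#' d <- make_block_design(4, 16, 16, 2)
#' dm <- build_design(d)
#' colnames(dm$X)
#' @export
build_design <- function(design, n_volumes = design$n_volumes,
                         highpass_hz = 1 / 128, nuisance = NULL) {
  conds <- design$conditions
  xs <- vapply(conds, function(cc) {
    ev <- design$events[design$events$trial_type == cc, , drop = FALSE]
    if (nrow(ev) == 0) numeric(n_volumes)
    else convolve_boxcar(ev, design$tr, n_volumes)
  }, numeric(n_volumes))
  keep <- apply(xs, 2, function(v) any(v != 0))
  xs <- xs[, keep, drop = FALSE]

  ttot <- n_volumes * design$tr
  kdct <- floor(2 * ttot * highpass_hz)
  dct <- NULL
  if (kdct >= 1) {
    n <- n_volumes
    dct <- vapply(seq_len(kdct), function(k)
      sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)),
      numeric(n))
    colnames(dct) <- paste0("dct", seq_len(kdct))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop_invalid("nuisance rows must equal the number of volumes")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
  }
  x <- cbind(intercept = 1, xs, dct, nuisance)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    offending <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_invalid("design matrix is rank deficient; collinear column(s): ",
                 paste(offending, collapse = ", "))
  }
  structure(list(X = x, names = colnames(x), highpass_hz = highpass_hz),
            class = "design_matrix")
}

#' First-level voxelwise GLM
#'
#' Ordinary least squares per in-mask voxel; the contrast map is c' beta-hat
#' and the residual variance is RSS / dof with dof = volumes - design rank.
#'
#' @param data a [timeseries4d()].
#' @param dm a [build_design()] result.
#' @param contrast numeric contrast weights, one per design column (may be
#'   named a subset: missing columns get weight 0 when given as a named
#'   vector).
#' @return an object of class `first_level_result`: `betas` (masked voxel x
#'   column), `contrast_map`, `residual_variance` (masked vectors), `dof`,
#'   `mask`, `shape`.
#' @export
first_level <- function(data, dm, contrast) {
  x <- dm$X
  if (!is.null(names(contrast))) {
    cvec <- numeric(ncol(x))
    names(cvec) <- colnames(x)
    unknown <- setdiff(names(contrast), colnames(x))
    if (length(unknown) > 0)
      stop_invalid("unknown contrast column(s): ",
                   paste(unknown, collapse = ", "))
    cvec[names(contrast)] <- contrast
    contrast <- cvec
  }
  if (length(contrast) != ncol(x))
    stop_invalid("contrast length must equal design columns")
  if (data$n_volumes != nrow(x))
    stop_invalid("data volumes must equal design rows")
  dof <- nrow(x) - qr(x)$rank
  if (dof <= 0) stop_invalid("no residual degrees of freedom")
  maskv <- as.vector(data$mask)
  y <- t(vox_by_time(data$data)[maskv, , drop = FALSE])  # time x voxels
  qx <- qr(x)
  b <- qr.coef(qx, y)
  res <- y - x %*% b
  rss <- colSums(res^2)
  structure(list(betas = t(b), contrast_map = as.vector(t(contrast) %*% b),
                 residual_variance = rss / dof, dof = dof,
                 mask = data$mask, shape = data$shape),
            class = "first_level_result")
}

#' Second-level one-sample random-effects analysis
#'
#' Per-voxel sample mean, unbiased variance, and one-sample t statistic with
#' n - 1 degrees of freedom over a stack of subject contrast maps.
#'
#' @param contrast_maps masked-voxel x subject matrix (or a list of masked
#'   contrast vectors).
#' @param mask,shape grid bookkeeping carried through to ROI extraction.
#' @return an object of class `group_result`: `mean_map`, `variance_map`,
#'   `t_map` (NA where the variance is zero), `n`, `dof`, `mask`, `shape`.
#' @export
second_level <- function(contrast_maps, mask = NULL, shape = NULL) {
  if (is.list(contrast_maps)) contrast_maps <- do.call(cbind, contrast_maps)
  n <- ncol(contrast_maps)
  if (n < 2) stop_invalid("second level requires n >= 2 subjects")
  m <- rowMeans(contrast_maps)
  v <- rowSums((contrast_maps - m)^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), NA_real_)
  structure(list(mean_map = m, variance_map = v, t_map = t, n = n,
                 dof = n - 1, mask = mask, shape = shape),
            class = "group_result")
}

#' Two-sided p values for a group result
#'
#' @param group a [second_level()] result.
#' @return vector of two-sided p values from the t distribution with
#'   `group$dof` degrees of freedom (NA where t is undefined).
#' @export
group_p_values <- function(group) {
  2 * stats::pt(-abs(group$t_map), df = group$dof)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure over the supplied (in-mask) p values at rate `q`;
#' returns the p-value cutoff and the significance mask. The mask is
#' monotone in `q`.
#'
#' @param p_map vector of p values in (0, 1); NAs are not significant.
#' @param q false discovery rate.
#' @return list with `threshold` (0 if nothing survives) and `mask`
#'   (logical).
#' @export
fdr_threshold <- function(p_map, q = 0.05) {
  ok <- !is.na(p_map)
  if (!any(ok)) stop_invalid("no p values supplied")
  if (any(p_map[ok] < 0 | p_map[ok] > 1)) stop_invalid("p values outside [0, 1]")
  padj <- stats::p.adjust(p_map, method = "BH")
  sig <- !is.na(padj) & padj <= q
  list(threshold = if (any(sig)) max(p_map[sig]) else 0, mask = sig)
}

#' Region of interest specification
#'
#' @param name label.
#' @param center_mni (x, y, z) center in mm.
#' @param radius_mm sphere radius, mm.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(name, center_mni, radius_mm = 8) {
  if (radius_mm <= 0) stop_invalid("radius must be > 0")
  structure(list(name = name, center_mni = as.numeric(center_mni),
                 radius_mm = radius_mm),
            class = "roi_spec")
}

#' Grid-to-mm affine for a synthetic grid
#'
#' Diagonal affine with isotropic voxel size, placing the grid center at the
#' mm origin (or at `origin_mm`). Voxel (i, j, k), 1-based, maps to
#' `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param shape grid dimensions.
#' @param voxel_mm isotropic voxel size, mm.
#' @param origin_mm mm coordinate of the grid center.
#' @return 4 x 4 affine matrix.
#' @export
grid_affine <- function(shape, voxel_mm = 4, origin_mm = c(0, 0, 0)) {
  shape <- check_shape3(shape)
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- origin_mm - (shape - 1) / 2 * voxel_mm
  a
}

#' Voxel center coordinates in mm
#'
#' @param shape grid dimensions.
#' @param affine 4 x 4 voxel-to-mm affine.
#' @return (number of voxels) x 3 matrix of mm coordinates in grid order.
#' @export
voxel_coords <- function(shape, affine) {
  g <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                             j = seq_len(shape[2]) - 1,
                             k = seq_len(shape[3]) - 1))
  sweep(g %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

#' Voxels inside a spherical ROI
#'
#' A voxel belongs to the sphere iff its center lies within the radius of
#' the ROI center.
#'
#' @param roi a [roi_spec()].
#' @param shape grid dimensions.
#' @param affine voxel-to-mm affine.
#' @return integer vector of linear voxel indices.
#' @export
roi_voxels <- function(roi, shape, affine) {
  xyz <- voxel_coords(shape, affine)
  d2 <- (xyz[, 1] - roi$center_mni[1])^2 + (xyz[, 2] - roi$center_mni[2])^2 +
    (xyz[, 3] - roi$center_mni[3])^2
  which(d2 <= roi$radius_mm^2)
}

#' ROI-averaged standardized effect size
#'
#' Per-voxel effect size ES(v) = mean(v) / sqrt(variance(v)) from the
#' second-level result (a standardized distance from zero in sd units,
#' analogous to Cohen's d), averaged arithmetically over the in-mask ROI
#' voxels. Zero-variance voxels are excluded with a warning.
#'
#' @param group a [second_level()] result carrying `mask` and `shape`.
#' @param roi a [roi_spec()].
#' @param affine voxel-to-mm affine of the grid.
#' @return the ROI effect size (sd units).
#' @export
roi_effect_size <- function(group, roi, affine) {
  if (is.null(group$mask) || is.null(group$shape))
    stop_invalid("group result lacks mask/shape bookkeeping")
  sel <- roi_masked_index(roi, group$mask, group$shape, affine)
  if (length(sel) == 0) stop_invalid("ROI does not intersect the mask")
  m <- group$mean_map[sel]
  v <- group$variance_map[sel]
  bad <- v <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) excluded from ROI '",
            roi$name, "'", call. = FALSE)
    m <- m[!bad]
    v <- v[!bad]
  }
  if (length(m) == 0) stop_invalid("no usable voxels in ROI '", roi$name, "'")
  mean(m / sqrt(v))
}

## Indices of ROI voxels within the masked-vector representation.
roi_masked_index <- function(roi, mask, shape, affine) {
  idx <- roi_voxels(roi, shape, affine)
  maskidx <- which(as.vector(mask))
  match(intersect(idx, maskidx), maskidx)
}

#' Bundled mentalizing ROI table
#'
#' Eleven 8-mm spherical ROIs at meta-analytic peak coordinates for the
#' mentalizing network (eight canonical cortical regions plus three
#' cerebellar regions). The right-cerebellar y coordinate is stored as -82;
#' the source coordinates print it inconsistently (+82 in one place, -82 in
#' another) and the negative sign is the one consistent with its
#' left-hemisphere homologue.
#'
#' @param path optional alternative CSV (columns name, x, y, z, radius_mm).
#' @return data.frame with one row per ROI.
#' @export
load_roi_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mentalizing_rois.csv",
                                package = "echokit")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_roi_table
#' @param table a data.frame as returned by `load_roi_table`.
#' @return `roi_list` returns a list of [roi_spec()] objects.
#' @export
roi_list <- function(table) {
  lapply(seq_len(nrow(table)), function(i)
    roi_spec(table$name[i], c(table$x[i], table$y[i], table$z[i]),
             table$radius_mm[i]))
}
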