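## Seed-based connectivity: correlation of ICA coefficient vectors
## (component-count degrees of freedom), a conventional bandpass + nuisance
## regression baseline, robust map-similarity correlation, and the Fisher-z
## comparison of correlations.

#' Connectivity from ICA coefficient maps
#'
#' Connectivity between the seed voxel and every other in-mask voxel is the
#' Pearson correlation, across components, of their ICA coefficient
#' vectors; the number of components serves as the effective degrees of
#' freedom. Component maps are sign-normalized (positive skewness) before
#' correlating, so the result is invariant to component order and sign
#' flips.
#'
#' @param components a `component_set` (see [spatial_ica()]).
#' @param seed_mni seed coordinate, mm.
#' @param affine voxel-to-mm affine of the grid.
#' @return an object of class `connectivity_map`: `r` (3-d array, NA
#'   outside the mask), `seed_mni`, `dof` (component count), `method`.
#' @export
meicr_map <- function(components, seed_mni, affine) {
  maps <- components$maps
  flip <- col_skewness(maps) < 0
  maps[, flip] <- -maps[, flip]
  seed_row <- seed_masked_row(seed_mni, components$mask, components$shape,
                              affine)
  r <- row_correlations(maps, maps[seed_row, ])
  arr <- array(NA_real_, components$shape)
  arr[components$mask] <- r
  structure(list(r = arr, seed_mni = seed_mni, dof = ncol(maps),
                 method = "meicr"),
            class = "connectivity_map")
}

#' Conventional seed connectivity on combined data
#'
#' Orthogonalizes every voxel's time series with respect to the nuisance
#' matrix (plus an intercept), applies an FFT bandpass to the given band,
#' and correlates the seed time series with every in-mask voxel. The
#' effective degrees of freedom are reported as the retained time points
#' scaled by the band's share of the Nyquist interval (an approximation).
#'
#' @param tsoc a [timeseries4d()].
#' @param nuisance optional volumes x k nuisance matrix (e.g. motion
#'   parameters).
#' @param band passband (low, high), Hz; must lie inside (0, Nyquist).
#' @param seed_mni seed coordinate, mm.
#' @param affine voxel-to-mm affine.
#' @return a `connectivity_map` (zero-variance voxels are NA).
#' @export
conventional_map <- function(tsoc, nuisance = NULL, band = c(0.01, 0.1),
                             seed_mni, affine) {
  nyq <- 1 / (2 * tsoc$tr_s)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop_invalid("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  nt <- tsoc$n_volumes
  if (nt * tsoc$tr_s < 100)
    warning("run shorter than ~100 s: band poorly resolved", call. = FALSE)
  maskv <- as.vector(tsoc$mask)
  y <- t(vox_by_time(tsoc$data)[maskv, , drop = FALSE])  # time x voxels
  flat <- apply(y, 2, stats::sd) == 0
  x <- cbind(rep(1, nt), nuisance)
  y <- y - x %*% qr.coef(qr(x), y)
  y <- bandpass_fft(y, tsoc$tr_s, band)
  seed_col <- seed_masked_row(seed_mni, tsoc$mask, tsoc$shape, affine)
  r <- row_correlations(t(y), y[, seed_col])
  r[flat] <- NA_real_
  arr <- array(NA_real_, tsoc$shape)
  arr[tsoc$mask] <- r
  structure(list(r = arr, seed_mni = seed_mni,
                 dof = nt * (band[2] - band[1]) / nyq,
                 method = "conventional"),
            class = "connectivity_map")
}

## Ideal FFT bandpass of the columns of a time x series matrix.
bandpass_fft <- function(y, tr_s, band) {
  nt <- nrow(y)
  freq <- (seq_len(nt) - 1) / (nt * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)       # fold to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  yf <- stats::mvfft(y)
  yf[!keep, ] <- 0
  Re(stats::mvfft(yf, inverse = TRUE)) / nt
}

## Pearson correlation of each row of `m` with vector `v` (NA where a row
## has zero variance).
row_correlations <- function(m, v) {
  mc <- m - rowMeans(m)
  vc <- v - mean(v)
  denom <- sqrt(rowSums(mc^2) * sum(vc^2))
  r <- as.vector(mc %*% vc) / denom
  r[denom == 0 | rowSums(mc^2) == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

## Masked-vector row index of the in-mask voxel nearest a mm coordinate;
## errors if the coordinate's voxel is outside the mask.
seed_masked_row <- function(seed_mni, mask, shape, affine) {
  xyz <- voxel_coords(shape, affine)
  d2 <- rowSums(sweep(xyz, 2, seed_mni)^2)
  vox <- which.min(d2)
  if (!as.vector(mask)[vox])
    stop_invalid("seed coordinate falls outside the mask")
  match(vox, which(as.vector(mask)))
}

#' Robust correlation between two whole-brain maps
#'
#' Huber M-estimator regression (tuning constant 1.345, 95% Gaussian
#' efficiency) of map B on map A after robustly standardizing both over the
#' mask (median and MAD, so contaminated values cannot distort the scale);
#' the slope on standardized variables is reported as a robust correlation
#' clipped to [-1, 1]. Protects the similarity estimate against the gross
#' outliers that seed-adjacent voxels produce in connectivity maps.
#'
#' @param map_a,map_b 3-d arrays (or vectors) of voxel values.
#' @param mask logical array/vector selecting the voxels to compare (at
#'   least 10).
#' @return robust correlation in [-1, 1].
#' @export
robust_map_correlation <- function(map_a, map_b, mask) {
  a <- as.vector(map_a)[as.vector(mask)]
  b <- as.vector(map_b)[as.vector(mask)]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 10) stop_invalid("need at least 10 in-mask voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("zero-variance input map")
  rs <- function(x) {
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    (x - stats::median(x)) / s
  }
  za <- rs(a)
  zb <- rs(b)
  fit <- MASS::rlm(zb ~ za, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  unname(pmin(pmax(stats::coef(fit)[2], -1), 1))
}

#' Fisher-z comparison of two correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3)): the
#' difference of independent Fisher-transformed correlations in standard
#' error units. Antisymmetric in its arguments and zero at equality.
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 effective sample sizes, > 3.
#' @return the z statistic.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop_invalid("|r| must be < 1")
  if (any(c(n1, n2) <= 3)) stop_invalid("n must be > 3")
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}
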