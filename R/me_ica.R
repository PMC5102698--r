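## TE-dependence ICA: decomposition of optimally combined data, per-component
## kappa (TE-dependence) and rho (TE-independence) pseudo-F statistics,
## component classification, and removal of the rejected sub-model.
##
## The logic: the mixing matrix is refit to each echo's data separately,
## giving per-voxel, per-echo coefficients for every component. A BOLD-like
## component scales across echoes as a change in the decay rate
## (coefficients proportional to -TEn * mean(v, TEn)), an artifact-like
## component as a change in the signal prefactor (coefficients proportional
## to mean(v, TEn)). Per-voxel pseudo-F values of the two one-parameter
## models are averaged over voxels, weighted by the squared z-scored
## component map, to yield kappa and rho.

#' Elbow of a metric spectrum
#'
#' Sorts the values in decreasing order and returns the value at the point
#' of maximum distance to the chord joining the first and last points (both
#' axes normalized to the unit interval). A deterministic, parameter-free
#' rule for "the spectrum elbow".
#'
#' @param x numeric vector of nonnegative metric values.
#' @return the metric value at the elbow.
#' @export
elbow_threshold <- function(x) {
  s <- sort(x, decreasing = TRUE)
  n <- length(s)
  if (n < 3 || s[1] == s[n]) return(s[n])
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (s - s[n]) / (s[1] - s[n])
  d <- abs(xs + ys - 1) / sqrt(2)
  s[which.max(d)]
}

#' ME-PCA: model-based dimensionality reduction
#'
#' PCA of the variance-normalized optimally combined data, with every
#' principal-component time course scored for TE-dependence (kappa) and
#' TE-independence (rho) by refitting it to the separate echoes. Components
#' carrying MR contrast — kappa, rho, or variance explained above the
#' respective spectrum elbows — are retained; the remaining (thermal-noise)
#' bulk is discarded. With fewer than five candidate components there is no
#' spectrum to take an elbow of and all components are retained.
#'
#' @param tsoc a [timeseries4d()] (optimally combined data).
#' @param series the [me_series()] the TSOC was built from (used for the
#'   per-echo refits; with fewer than three echoes, selection falls back to
#'   the variance elbow alone with a warning).
#' @param f_cap cap applied to per-voxel pseudo-F values.
#' @return an object of class `me_pca`: `tc` (time x PC, unit norm),
#'   `scores` (masked voxel x PC spatial maps), `varex` (% variance),
#'   `kappa`, `rho`, `retained` (logical), `elbows`, `mask`, `shape`.
#' @export
me_pca <- function(tsoc, series, f_cap = 500) {
  maskv <- as.vector(tsoc$mask)
  y <- vox_by_time(tsoc$data)[maskv, , drop = FALSE]
  y <- y - rowMeans(y)
  sdv <- sqrt(rowMeans(y^2))
  sdv[sdv == 0] <- 1
  yn <- y / sdv
  ev <- eigen(crossprod(yn), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-9
  tc <- ev$vectors[, keep, drop = FALSE]
  lambda <- ev$values[keep]
  varex <- lambda / sum(pmax(ev$values, 0)) * 100
  scores <- yn %*% tc

  if (length(series$te_ms) >= 3) {
    fit <- echo_fit(tc, series, mask = tsoc$mask)
    kr <- kappa_rho(fit, series$te_ms, scores, f_cap = f_cap)
    kappa <- kr$kappa
    rho <- kr$rho
    # kappa and rho are pseudo-F values: an elbow below the null F
    # quantile would admit components indistinguishable from noise, so the
    # selection thresholds are clamped at the 95% point of F(1, nE - 1)
    f_null <- stats::qf(0.95, 1, length(series$te_ms) - 1)
    elbows <- selection_thresholds(max(elbow_threshold(kappa), f_null),
                                   max(elbow_threshold(rho), f_null),
                                   elbow_threshold(varex))
    retained <- kappa >= elbows$kappa_elbow | rho >= elbows$rho_elbow |
      varex >= elbows$variance_elbow
    if (length(retained) < 5) retained[] <- TRUE
  } else {
    warning("fewer than 3 echoes: kappa/rho unavailable, ",
            "selecting by variance elbow only", call. = FALSE)
    kappa <- rho <- rep(NA_real_, ncol(tc))
    elbows <- selection_thresholds(NA_real_, NA_real_,
                                   elbow_threshold(varex))
    retained <- varex >= elbows$variance_elbow
  }
  structure(list(tc = tc, scores = scores, varex = varex, kappa = kappa,
                 rho = rho, retained = retained, elbows = elbows,
                 mask = tsoc$mask, shape = tsoc$shape,
                 n_volumes = tsoc$n_volumes, tr_s = tsoc$tr_s),
            class = "me_pca")
}

#' @export
print.me_pca <- function(x, ...) {
  cat("me_pca:", ncol(x$tc), "components,", sum(x$retained),
      "retained above elbows\n")
  invisible(x)
}

#' Spatial FastICA of the retained principal subspace
#'
#' Runs FastICA with the tanh (logcosh) contrast on the retained spatial
#' basis, treating voxels as samples, to obtain statistically independent
#' spatial maps and the complementary mixing matrix of component time
#' courses. Maps are z-scored over the mask and sign-fixed so each map's
#' skewness is positive. Deterministic given the seed; on non-convergence
#' the decomposition is restarted (up to `max_restarts` times) from random
#' rotations under seeds derived with [derive_seed()].
#'
#' @param reduced an [me_pca()] result.
#' @param n_components number of components; defaults to the retained
#'   dimension and may not exceed it.
#' @param seed integer seed.
#' @param max_restarts restarts before giving up.
#' @param maxit,tol FastICA iteration controls.
#' @return an object of class `component_set`: `mixing` (time x component),
#'   `maps` (masked voxel x component, z-scored), `varex`, `kappa`, `rho`,
#'   `label` (unset), `mask`, `shape`.
#' @export
spatial_ica <- function(reduced, n_components = NULL, seed = 1L,
                        max_restarts = 5L, maxit = 1000L, tol = 1e-5) {
  ret <- which(reduced$retained)
  k <- n_components %||% length(ret)
  if (k > length(ret))
    stop_invalid("n_components exceeds the retained dimension (", length(ret), ")")
  if (k < 1) stop_invalid("need at least one component")
  basis <- reduced$scores[, ret[seq_len(k)], drop = FALSE]

  res <- NULL
  seeds_tried <- integer(0)
  for (attempt in seq_len(max_restarts)) {
    s <- derive_seed(seed, attempt - 1L)
    seeds_tried <- c(seeds_tried, s)
    set.seed(s)
    rmat <- if (attempt == 1) diag(k) else qr.Q(qr(matrix(rnorm(k * k), k)))
    fit <- ica::icafast(basis, nc = k, center = TRUE, maxit = maxit,
                        tol = tol, Rmat = rmat, alg = "par", fun = "logcosh")
    if (isTRUE(fit$converged)) { res <- fit; break }
  }
  if (is.null(res))
    stop_invalid("FastICA failed to converge after ", max_restarts,
                 " restarts (seeds tried: ",
                 paste(seeds_tried, collapse = ", "), ")")

  s_maps <- res$S                      # masked voxel x k
  mixing <- reduced$tc[, ret[seq_len(k)], drop = FALSE] %*% res$M
  flip <- col_skewness(s_maps) < 0
  s_maps[, flip] <- -s_maps[, flip]
  mixing[, flip] <- -mixing[, flip]
  maps <- zscore_cols(s_maps)
  varex <- res$vafs * sum(reduced$varex[ret[seq_len(k)]])

  structure(list(mixing = mixing, maps = maps, varex = varex,
                 kappa = NULL, rho = NULL, label = NULL,
                 mask = reduced$mask, shape = reduced$shape,
                 tr_s = reduced$tr_s, seed = seed,
                 ica_seed = s),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set:", ncol(x$mixing), "components\n")
  if (!is.null(x$label)) print(table(x$label))
  invisible(x)
}

#' Refit the mixing matrix to each echo's time series
#'
#' Per-echo multiple linear least squares of every in-mask voxel's time
#' series on all component time courses (plus an intercept), producing the
#' per-component coefficient maps at each TE that drive the kappa/rho
#' TE-dependence statistics.
#'
#' @param mixing time x component matrix of component time courses.
#' @param series an [me_series()].
#' @param mask optional logical mask (defaults to the series mask).
#' @return an object of class `echo_fit`: `coeffs` (masked voxel x
#'   component x echo), `echo_means` (masked voxel x echo), `te_ms`.
#' @export
echo_fit <- function(mixing, series, mask = NULL) {
  mask <- mask %||% series$mask
  maskv <- as.vector(mask)
  nt <- series$n_volumes
  if (nrow(mixing) != nt)
    stop_invalid("mixing rows must equal the number of volumes")
  x <- cbind(intercept = 1, mixing)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    offending <- qx$pivot[(qx$rank + 1):ncol(x)] - 1L
    stop_invalid("rank-deficient mixing matrix; collinear component(s): ",
                 paste(offending, collapse = ", "))
  }
  k <- ncol(mixing)
  nvm <- sum(maskv)
  coeffs <- array(NA_real_, c(nvm, k, length(series$te_ms)))
  echo_means <- matrix(NA_real_, nvm, length(series$te_ms))
  for (e in seq_along(series$te_ms)) {
    ye <- vox_by_time(series$echoes[[e]])[maskv, , drop = FALSE]
    echo_means[, e] <- rowMeans(ye)
    b <- qr.coef(qx, t(ye))           # (k+1) x voxels
    coeffs[, , e] <- t(b[-1, , drop = FALSE])
  }
  structure(list(coeffs = coeffs, echo_means = echo_means,
                 te_ms = series$te_ms),
            class = "echo_fit")
}

#' Component-level TE-dependence (kappa) and TE-independence (rho)
#'
#' For every voxel and component, the per-echo coefficients are fit to two
#' one-parameter models: the R2* (TE-dependence) model predicting
#' coefficients proportional to -TEn * mean(v, TEn), and the S0
#' (TE-independence) model predicting coefficients proportional to
#' mean(v, TEn). The per-voxel pseudo-F of each model (capped at `f_cap`)
#' is averaged over voxels, weighted by the squared z-scored component map,
#' yielding the component-level kappa and rho.
#'
#' @param fit an [echo_fit()] result.
#' @param te_ms echo times, ms (at least three).
#' @param maps masked voxel x component spatial maps (z-scored internally
#'   for the weights). Voxels with zero coefficients at all echoes get
#'   weight zero.
#' @param f_cap per-voxel pseudo-F cap (guards the perfect-fit limit).
#' @return list with numeric vectors `kappa` and `rho`.
#' @export
kappa_rho <- function(fit, te_ms, maps, f_cap = 500) {
  if (length(te_ms) < 3)
    stop_invalid("kappa/rho require at least three echoes")
  ne <- length(te_ms)
  k <- dim(fit$coeffs)[2]
  mu <- fit$echo_means                       # voxels x echoes
  x_r2 <- -rep(te_ms, each = nrow(mu)) * mu  # voxels x echoes
  dim(x_r2) <- dim(mu)
  x_s0 <- mu
  ssx_r2 <- rowSums(x_r2^2)
  ssx_s0 <- rowSums(x_s0^2)
  wmaps <- zscore_cols(maps)^2
  kappa <- rho <- numeric(k)
  for (c in seq_len(k)) {
    y <- fit$coeffs[, c, ]                   # voxels x echoes
    sst <- rowSums(y^2)
    a_r2 <- rowSums(x_r2 * y) / ssx_r2
    a_s0 <- rowSums(x_s0 * y) / ssx_s0
    sse_r2 <- rowSums((y - a_r2 * x_r2)^2)
    sse_s0 <- rowSums((y - a_s0 * x_s0)^2)
    f_r2 <- pmin((sst - sse_r2) * (ne - 1) / pmax(sse_r2, 0), f_cap)
    f_s0 <- pmin((sst - sse_s0) * (ne - 1) / pmax(sse_s0, 0), f_cap)
    f_r2[!is.finite(f_r2)] <- f_cap
    f_s0[!is.finite(f_s0)] <- f_cap
    w <- wmaps[, c]
    w[sst == 0] <- 0
    f_r2[sst == 0] <- 0
    f_s0[sst == 0] <- 0
    kappa[c] <- sum(w * pmax(f_r2, 0)) / sum(w)
    rho[c] <- sum(w * pmax(f_s0, 0)) / sum(w)
  }
  list(kappa = kappa, rho = rho)
}

#' Selection thresholds for component classification
#'
#' @param kappa_elbow,rho_elbow,variance_elbow nonnegative thresholds
#'   (pseudo-F, pseudo-F, percent variance).
#' @return an object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(kappa_elbow, rho_elbow, variance_elbow) {
  vals <- c(kappa_elbow, rho_elbow, variance_elbow)
  if (any(vals < 0, na.rm = TRUE)) stop_invalid("thresholds must be >= 0")
  structure(list(kappa_elbow = kappa_elbow, rho_elbow = rho_elbow,
                 variance_elbow = variance_elbow),
            class = "selection_thresholds")
}

#' Classify components by their TE behavior
#'
#' Labels every component exactly once:
#' \itemize{
#'   \item `midk` — kappa and rho both above their elbows, of comparable
#'     magnitude (neither dominating by more than a factor of two), with
#'     high variance explained: mixed BOLD/non-BOLD (e.g. draining-vein
#'     physiology), removed from the accepted set;
#'   \item `accepted` — kappa at or above its elbow and kappa/rho at or
#'     above `ratio` (TE-dependent scaling, BOLD-like);
#'   \item `rejected` — rho at or above its elbow and rho > kappa
#'     (TE-independent scaling, artifact);
#'   \item `ignored` — remaining low-variance ambiguous components, left in
#'     the data.
#' }
#'
#' @param components a `component_set` with `kappa` and `rho` filled in.
#' @param thresholds a [selection_thresholds()]; if `NULL`, elbows are
#'   computed from the component spectra with [elbow_threshold()].
#' @param ratio kappa/rho ratio required for acceptance.
#' @return the `component_set` with `label` set and the thresholds attached.
#' @export
classify <- function(components, thresholds = NULL, ratio = 1) {
  kappa <- components$kappa
  rho <- components$rho
  if (is.null(kappa) || is.null(rho))
    stop_invalid("kappa/rho must be computed before classification")
  thresholds <- thresholds %||%
    selection_thresholds(elbow_threshold(kappa), elbow_threshold(rho),
                         elbow_threshold(components$varex))
  ke <- thresholds$kappa_elbow
  re <- thresholds$rho_elbow
  ve <- thresholds$variance_elbow
  label <- character(length(kappa))
  for (i in seq_along(kappa)) {
    if (kappa[i] >= ke && rho[i] >= re && components$varex[i] >= ve &&
        kappa[i] / max(rho[i], .Machine$double.eps) < 2 * ratio &&
        rho[i] / max(kappa[i], .Machine$double.eps) < 2) {
      label[i] <- "midk"
    } else if (kappa[i] >= ke &&
               kappa[i] >= ratio * rho[i]) {
      label[i] <- "accepted"
    } else if (rho[i] >= re && rho[i] > kappa[i]) {
      label[i] <- "rejected"
    } else {
      label[i] <- "ignored"
    }
  }
  components$label <- label
  components$thresholds <- thresholds
  components
}

#' Remove the rejected sub-model from the combined time series
#'
#' Fits the full mixing matrix (all component time courses plus an
#' intercept) to every in-mask voxel of the optimally combined series by
#' multiple linear least squares, then subtracts the fitted contribution of
#' the components labeled `rejected` or `midk`. Accepted and ignored
#' contributions and the residual remain, so the operation is a per-voxel
#' linear projection (idempotent for fixed labels).
#'
#' @param tsoc a [timeseries4d()].
#' @param components a labeled `component_set`.
#' @return a [timeseries4d()] of the denoised data.
#' @export
denoise_timeseries <- function(tsoc, components) {
  if (is.null(components$label))
    stop_invalid("components must be classified before denoising")
  maskv <- as.vector(tsoc$mask)
  y <- vox_by_time(tsoc$data)
  x <- cbind(intercept = 1, components$mixing)
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop_invalid("rank-deficient mixing matrix")
  rej <- which(components$label %in% c("rejected", "midk")) + 1L
  if (length(rej) > 0) {
    b <- qr.coef(qx, t(y[maskv, , drop = FALSE]))
    fitted_rej <- x[, rej, drop = FALSE] %*% b[rej, , drop = FALSE]
    y[maskv, ] <- y[maskv, , drop = FALSE] - t(fitted_rej)
  }
  timeseries4d(array(y, c(tsoc$shape, tsoc$n_volumes)), tsoc$tr_s, tsoc$mask)
}

#' Full multi-echo denoising pipeline
#'
#' Convenience orchestrator: decay fit, combination weights, optimal
#' combination, ME-PCA, spatial ICA, per-echo refits, kappa/rho,
#' classification, and removal of the rejected sub-model.
#'
#' @param series an [me_series()].
#' @param seed integer seed for the ICA step.
#' @param n_components number of ICA components (default: ME-PCA retained
#'   dimension).
#' @param ratio kappa/rho acceptance ratio, see [classify()].
#' @return list with `decay`, `weights`, `tsoc`, `pca`, `components`
#'   (classified), `denoised`.
#' @examples
#' \donttest{
#' subj <- standard_mixture(seed = 7)
#' res <- run_meica(subj$series, seed = 7)
#' table(res$components$label)
#' }
#' @export
run_meica <- function(series, seed = 1L, n_components = NULL, ratio = 1) {
  decay <- fit_decay(series)
  weights <- compute_weights(decay, series$te_ms)
  series$mask <- decay$mask
  tsoc <- optimal_combination(series, weights)
  pca <- me_pca(tsoc, series)
  comps <- spatial_ica(pca, n_components = n_components, seed = seed)
  fit <- echo_fit(comps$mixing, series, mask = tsoc$mask)
  kr <- kappa_rho(fit, series$te_ms, comps$maps)
  comps$kappa <- kr$kappa
  comps$rho <- kr$rho
  comps <- classify(comps, ratio = ratio)
  denoised <- denoise_timeseries(tsoc, comps)
  list(decay = decay, weights = weights, tsoc = tsoc, pca = pca,
       components = comps, denoised = denoised)
}

#' Write / read a component table
#'
#' Tab-separated table with one row per component: `component`, `kappa`,
#' `rho`, `variance_explained`, `label`.
#'
#' @param components a labeled `component_set`.
#' @param path file path.
#' @return `write_component_table` returns the path invisibly;
#'   `read_component_table` returns a data.frame.
#' @export
write_component_table <- function(components, path) {
  df <- data.frame(component = seq_along(components$kappa),
                   kappa = components$kappa, rho = components$rho,
                   variance_explained = components$varex,
                   label = components$label %||%
                     rep(NA_character_, length(components$kappa)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
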