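## T2* decay fitting and T2*-weighted optimal combination of echoes.

#' Multi-echo time series container
#'
#' @param echoes list of 4-d arrays (x, y, z, t), one per echo time.
#' @param te_ms echo times, ms, strictly increasing.
#' @param tr_s repetition time, s.
#' @param mask logical 3-d array of brain voxels.
#' @return an object of class `me_series`.
#' @export
me_series <- function(echoes, te_ms, tr_s, mask) {
  if (length(echoes) != length(te_ms))
    stop_invalid("one 4-d array per echo time required")
  if (length(te_ms) < 2) stop_invalid("need at least two echo times")
  if (any(diff(te_ms) <= 0)) stop_invalid("te_ms must be strictly increasing")
  d1 <- dim(echoes[[1]])
  if (length(d1) != 4) stop_invalid("echo arrays must be 4-d")
  for (e in echoes) if (!identical(dim(e), d1))
    stop_invalid("all echoes must share dimensions")
  if (!identical(dim(mask), d1[1:3]))
    stop_invalid("mask grid must match the echo grid")
  structure(list(echoes = echoes, te_ms = te_ms, tr_s = tr_s,
                 mask = mask, shape = d1[1:3], n_volumes = d1[4]),
            class = "me_series")
}

#' @export
print.me_series <- function(x, ...) {
  cat("me_series:", paste(x$shape, collapse = " x "), "grid,",
      x$n_volumes, "volumes,", length(x$te_ms), "echoes (TE =",
      paste(x$te_ms, collapse = ", "), "ms), TR =", x$tr_s, "s\n")
  invisible(x)
}

#' 4-d single time series container
#'
#' @param data 4-d array.
#' @param tr_s repetition time, s.
#' @param mask logical 3-d array.
#' @return an object of class `timeseries4d`.
#' @export
timeseries4d <- function(data, tr_s, mask) {
  d <- dim(data)
  if (length(d) != 4) stop_invalid("data must be 4-d")
  if (!identical(dim(mask), d[1:3])) stop_invalid("mask grid mismatch")
  structure(list(data = data, tr_s = tr_s, mask = mask, shape = d[1:3],
                 n_volumes = d[4]),
            class = "timeseries4d")
}

#' Fit the voxelwise mono-exponential decay model
#'
#' The temporal mean of each echo is fit to S(TE) = S0 * exp(-TE / T2*) by
#' log-linear least squares over echoes: T2* = -1 / slope and
#' S0 = exp(intercept). Voxels where the fit is degenerate (non-negative
#' slope, i.e. no measurable decay) are clipped to the T2* limits; voxels
#' with a non-positive echo mean inside the mask are flagged, assigned the
#' upper cap, and removed from the returned mask (they keep cap-valued
#' weights for combination but are excluded from decomposition).
#'
#' @param series an [me_series()].
#' @param t2star_limits clipping bounds for T2*, ms. The defaults (2, 300)
#'   bracket physiological gray/white/CSF values at 3 T and keep the
#'   combination weights bounded.
#' @return a [decay_model()]; attribute `flagged` marks in-mask voxels with
#'   non-positive echo means.
#' @export
fit_decay <- function(series, t2star_limits = c(2, 300)) {
  nv <- prod(series$shape)
  ne <- length(series$te_ms)
  ybar <- vapply(series$echoes, function(a) rowMeans(vox_by_time(a)),
                 numeric(nv))
  maskv <- as.vector(series$mask)
  bad <- rowSums(ybar <= 0) > 0
  if (any(bad & maskv))
    warning(sum(bad & maskv),
            " in-mask voxel(s) with non-positive echo mean; assigned cap T2*",
            call. = FALSE)
  ly <- log(pmax(ybar, .Machine$double.xmin))
  te <- series$te_ms
  tec <- te - mean(te)
  slope <- as.vector(ly %*% tec) / sum(tec^2)
  intercept <- rowMeans(ly) - slope * mean(te)
  t2 <- ifelse(slope < 0, -1 / slope, Inf)
  t2 <- pmin(pmax(t2, t2star_limits[1]), t2star_limits[2])
  t2[bad] <- t2star_limits[2]
  s0 <- exp(intercept)
  s0[bad] <- pmax(ybar[bad, 1], 1)
  out <- decay_model(array(s0, series$shape), array(t2, series$shape),
                     series$mask & !array(bad, series$shape))
  attr(out, "flagged") <- array(bad & maskv, series$shape)
  out
}

#' Per-echo combination weights from a decay model
#'
#' Evaluates the matched-filter weight
#' w(v, n) = TEn * exp(-TEn / T2*(v)) / sum_n TEn * exp(-TEn / T2*(v)),
#' which peaks at the echo time closest (in contrast terms) to TE = T2*,
#' the acquisition of optimal BOLD contrast.
#'
#' @param decay a [decay_model()].
#' @param te_ms echo times, ms.
#' @return an object of class `weight_map` with `weights` (voxel x echo
#'   matrix, rows summing to 1), `shape`, `mask`, `te_ms`.
#' @export
compute_weights <- function(decay, te_ms) {
  t2v <- as.vector(decay$t2star)
  if (any(t2v <= 0)) stop_invalid("T2* must be positive")
  w <- vapply(te_ms, function(te) te * exp(-te / t2v), numeric(length(t2v)))
  w <- w / rowSums(w)
  structure(list(weights = w, shape = decay$shape, mask = decay$mask,
                 te_ms = te_ms),
            class = "weight_map")
}

#' T2*-weighted optimal combination of echoes
#'
#' TSOC(v, t) = sum_n w(v, n) * S(v, t, TEn): a convex per-voxel average of
#' the echoes implementing a matched filter, so under white noise of equal
#' variance the combined series has contrast-to-noise at least that of any
#' single echo.
#'
#' @param series an [me_series()].
#' @param weights a [compute_weights()] result on the same grid.
#' @return a [timeseries4d()] (the TSOC series).
#' @export
optimal_combination <- function(series, weights) {
  if (!identical(weights$shape, series$shape))
    stop_invalid("weight grid does not match the series grid")
  if (ncol(weights$weights) != length(series$te_ms))
    stop_invalid("one weight column per echo required")
  nv <- prod(series$shape)
  acc <- matrix(0, nv, series$n_volumes)
  for (e in seq_along(series$te_ms)) {
    acc <- acc + weights$weights[, e] * vox_by_time(series$echoes[[e]])
  }
  timeseries4d(array(acc, c(series$shape, series$n_volumes)),
               series$tr_s, series$mask)
}
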