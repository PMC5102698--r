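#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Derive a child seed from a master seed and a counter
#'
#' Counter-based seed splitting: child seeds are a deterministic function of
#' the master seed and an integer counter, so subjects (or ICA restarts) can
#' be generated independently and reproducibly regardless of evaluation
#' order. The result stays inside the 32-bit integer range R requires.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer counter (subject index, restart
#'   number, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 104729 * as.double(counter)) %% 2147483647)
}

## 1-d convolution of the columns of `mat` with kernel `k` (odd length),
## edges handled by replication.
conv_cols <- function(mat, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(mat)
  idx <- outer(seq_len(n), seq(-r, r), "+")
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(k)) {
    out <- out + k[j] * mat[idx[, j], , drop = FALSE]
  }
  out
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian smoothing of a 3-d array (sigma in voxels).
smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gauss_kernel1d(sigma)
  d <- dim(arr)
  x <- arr
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- conv_cols(matrix(xp, nrow = dp[1]), k)
    x <- aperm(array(m, dp), order(perm))
  }
  x
}

## Rescale an array linearly so its range maps onto [lo, hi].
rescale_range <- function(arr, lo, hi) {
  if (lo == hi) return(array(lo, dim(arr)))
  rng <- range(arr)
  if (rng[1] == rng[2]) return(array((lo + hi) / 2, dim(arr)))
  (arr - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

## Column z-scoring that tolerates zero-variance columns (left at 0).
zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2, mu)^2))
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

col_skewness <- function(m) {
  mu <- colMeans(m)
  d <- sweep(m, 2, mu)
  s2 <- colMeans(d^2)
  s2[s2 == 0] <- 1
  colMeans(d^3) / s2^1.5
}

## Flatten one echo's 4-d array to a voxel x time matrix.
vox_by_time <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
}

check_shape3 <- function(shape) {
  if (length(shape) != 3 || any(shape < 1) || any(shape != round(shape)))
    stop_invalid("'shape' must be three positive integers")
  as.integer(shape)
}
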