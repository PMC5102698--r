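## Statistical power for the one-sample second-level design, minimum sample
## size, bootstrap effect-size confidence intervals, the effect-size boost
## statistic, and the cost-savings computation.

#' Exact power of the two-sided one-sample t test
#'
#' Noncentral-t power with noncentrality d * sqrt(n) and n - 1 degrees of
#' freedom. At d = 0 the power equals the type-I rate.
#'
#' @param d standardized effect size (sd units).
#' @param n sample size, at least 2.
#' @param alpha two-sided type-I error rate.
#' @return power in [0, 1] (vectorized over `d` and `n`).
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05) {
  if (any(n < 2)) stop_invalid("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
}

#' Power curve over a sample-size grid
#'
#' @param d standardized effect size.
#' @param alpha type-I rate.
#' @param n_range integer grid of sample sizes (default 5..100).
#' @param target power target for the minimum sample size.
#' @return an object of class `power_curve`: `n_grid`, `power`, `d`,
#'   `alpha`, `min_n` (smallest grid n reaching `target`, or `NA` if never
#'   reached).
#' @examples
#' pc <- power_curve(0.7)
#' pc$min_n
#' @export
power_curve <- function(d, alpha = 0.05, n_range = 5:100, target = 0.80) {
  if (length(n_range) == 0 || any(diff(n_range) <= 0))
    stop_invalid("n_range must be nonempty and ascending")
  pw <- power_one_sample_t(d, n_range, alpha)
  structure(list(n_grid = n_range, power = pw, d = d, alpha = alpha,
                 target = target, min_n = min_n_from(n_range, pw, target)),
            class = "power_curve")
}

min_n_from <- function(n_grid, power, target) {
  hit <- which(power >= target)
  if (length(hit) == 0) NA_integer_ else n_grid[hit[1]]
}

#' Minimum sample size reaching a power target
#'
#' @param curve a [power_curve()].
#' @param target power target (defaults to the curve's).
#' @return smallest grid n with power at or above the target, or `NA` if
#'   the target is never reached on the grid.
#' @export
min_n <- function(curve, target = curve$target) {
  min_n_from(curve$n_grid, curve$power, target)
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("power_curve: d = %.3g, alpha = %.3g, n = %d..%d, min n (%.0f%%) = %s\n",
              x$d, x$alpha, min(x$n_grid), max(x$n_grid), 100 * x$target,
              ifelse(is.na(x$min_n), "not reached", x$min_n)))
  invisible(x)
}

#' Bootstrap distribution of ROI effect sizes
#'
#' Resamples subjects with replacement, recomputes the second-level
#' analysis and the ROI effect sizes for every resample, and returns the
#' percentile 95% confidence intervals. Degenerate resamples (a single
#' subject drawn n times, leaving zero variance everywhere) are redrawn and
#' counted.
#'
#' @param contrast_maps masked-voxel x subject matrix of first-level
#'   contrast maps.
#' @param rois list of [roi_spec()] objects.
#' @param mask,shape,affine grid bookkeeping.
#' @param B number of resamples.
#' @param seed integer seed.
#' @return an object of class `bootstrap_es`: `es` (B x ROI matrix), `ci`
#'   (2 x ROI, 2.5 and 97.5 percentiles), `point` (full-sample effect
#'   sizes), `indices` (B x n resample indices, enabling paired reuse),
#'   `redraws`.
#' @export
bootstrap_es <- function(contrast_maps, rois, mask, shape, affine,
                         B = 1000L, seed = 1L) {
  n <- ncol(contrast_maps)
  if (n < 2) stop_invalid("need n >= 2 subjects")
  if (B < 1) stop_invalid("B must be >= 1")
  sel <- lapply(rois, roi_masked_index, mask = mask, shape = shape,
                affine = affine)
  if (any(lengths(sel) == 0)) stop_invalid("an ROI does not intersect the mask")
  rows <- sort(unique(unlist(sel)))
  sub <- contrast_maps[rows, , drop = FALSE]
  selr <- lapply(sel, match, table = rows)

  roi_es <- function(m, v) {
    vapply(selr, function(s) {
      ok <- v[s] > 0
      mean(m[s][ok] / sqrt(v[s][ok]))
    }, numeric(1))
  }
  gm <- rowMeans(sub)
  gv <- rowSums((sub - gm)^2) / (n - 1)
  if (all(gv == 0)) stop_invalid("all subject maps identical: effect size undefined")
  point <- roi_es(gm, gv)

  set.seed(seed)
  es <- matrix(NA_real_, B, length(rois))
  indices <- matrix(NA_integer_, B, n)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- rowMeans(sub[, idx, drop = FALSE])
      vb <- rowSums((sub[, idx, drop = FALSE] - mb)^2) / (n - 1)
      if (any(vb > 0)) break
      redraws <- redraws + 1L
      if (redraws > 100L) stop_invalid("too many degenerate resamples")
    }
    indices[b, ] <- idx
    es[b, ] <- roi_es(mb, vb)
  }
  ci <- apply(es, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(es = es, ci = ci, point = point, indices = indices,
                 redraws = redraws,
                 roi_names = vapply(rois, `[[`, "", "name")),
            class = "bootstrap_es")
}

#' Effect-size boost percentage
#'
#' boost = (es_a - es_b) / |es_b| * 100: the percentage change of pipeline
#' A's effect size relative to pipeline B's, with an absolute-value
#' denominator so the sign of the boost follows the numerator.
#'
#' @param es_a,es_b effect sizes of the two pipelines (`es_b` nonzero).
#' @return boost in percent.
#' @export
boost <- function(es_a, es_b) {
  if (any(es_b == 0)) stop_invalid("es_b must be nonzero")
  (es_a - es_b) / abs(es_b) * 100
}

#' Paired-bootstrap boost report
#'
#' Combines two [bootstrap_es()] runs obtained from the same subject draws
#' (pass the same seed, or reuse `indices`) into per-ROI boost statistics:
#' the point boost, the percentile 95% CI of the bootstrap boost
#' distribution, the robustness flag (CI lower bound above 0), and the
#' consistency percentage (share of resamples with a positive boost).
#'
#' @param boot_a,boot_b [bootstrap_es()] results for pipelines A and B with
#'   identical resample indices.
#' @return a data.frame of class `boost_report` with one row per ROI:
#'   `roi`, `es_a`, `es_b`, `boost_pct`, `ci_low`, `ci_high`, `robust`,
#'   `consistency_pct`.
#' @export
boost_ci <- function(boot_a, boot_b) {
  if (!identical(dim(boot_a$es), dim(boot_b$es)))
    stop_invalid("bootstrap runs must match in size")
  if (!identical(boot_a$indices, boot_b$indices))
    stop_invalid("boost CIs require paired resamples (same subject draws)")
  bmat <- boost(boot_a$es, boot_b$es)
  ci <- apply(bmat, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(roi = boot_a$roi_names,
                    es_a = boot_a$point, es_b = boot_b$point,
                    boost_pct = boost(boot_a$point, boot_b$point),
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    robust = ci[1, ] > 0,
                    consistency_pct = colMeans(bmat > 0, na.rm = TRUE) * 100,
                    stringsAsFactors = FALSE)
  class(out) <- c("boost_report", "data.frame")
  out
}

#' Scanning cost saved by the smaller required sample
#'
#' (min_n_b - min_n_a) * cost_per_subject. If either pipeline never reaches
#' the power target (absent minimum), the region is excluded and `NA` is
#' returned.
#'
#' @param min_n_a,min_n_b minimum sample sizes of the two pipelines (NA if
#'   the target was not attained).
#' @param cost_per_subject scanning cost per subject (currency units).
#' @return saved cost, or `NA` when excluded.
#' @export
cost_savings <- function(min_n_a, min_n_b, cost_per_subject = 500) {
  ifelse(is.na(min_n_a) | is.na(min_n_b), NA_real_,
         (min_n_b - min_n_a) * cost_per_subject)
}
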