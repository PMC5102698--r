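# GLM analysis: canonical HRF shape, design-matrix construction with the
# discrete-cosine high-pass basis, first- and second-level estimation, FDR
# thresholding, and ROI effect sizes.

test_that("canonical HRF has the conventional double-gamma shape", {
  h <- hrf_canonical(dt = 0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_gte(t[which.max(h)], 4)
  expect_lte(t[which.max(h)], 6)
  expect_gt(sum(h), 0)
  expect_equal(max(h), 1)
  # undershoot present
  expect_lt(min(h), 0)
  expect_error(hrf_canonical(0), "dt")
})

test_that("design matrices carry convolved boxcars, DCT columns, and an intercept", {
  d <- make_block_design(4, 16, 16, 2)
  ev <- d$events
  # 261-volume run at TR 2 with 1/128 Hz cutoff: floor(2*522/128) = 8 DCTs
  d261 <- task_design(d$conditions, ev, 2, 261)
  dm <- build_design(d261, n_volumes = 261)
  expect_equal(sum(grepl("^dct", colnames(dm$X))), 8)
  expect_true("intercept" %in% colnames(dm$X))
  expect_equal(qr(dm$X)$rank, ncol(dm$X))

  # no in-condition events: intercept + DCT only
  dempty <- task_design("a", data.frame(onset = 10, duration = 4,
                                        trial_type = "other"),
                        2, 100)
  dm0 <- build_design(dempty)
  expect_equal(sum(!grepl("^dct|^intercept", colnames(dm0$X))), 0)

  # constant nuisance column collides with the intercept
  expect_error(build_design(d261, nuisance = matrix(1, 261, 1)),
               "collinear")
})

test_that("first-level OLS recovers constructed effects exactly", {
  d <- make_block_design(2, 16, 16, 2)
  dm <- build_design(d)
  nvol <- nrow(dm$X)
  shape <- c(4, 4, 2)
  nv <- prod(shape)
  mask <- array(TRUE, shape)
  set.seed(1)
  beta_true <- matrix(rnorm(nv * ncol(dm$X)), nv)
  y <- beta_true %*% t(dm$X)
  ts <- timeseries4d(array(y, c(shape, nvol)), 2, mask)
  cvec <- c(mentalizing = 1, physical = -1)
  fl <- first_level(ts, dm, cvec)
  cidx <- match(c("mentalizing", "physical"), colnames(dm$X))
  expect_equal(fl$contrast_map,
               beta_true[, cidx[1]] - beta_true[, cidx[2]],
               tolerance = 1e-8)
  expect_equal(fl$dof, nvol - ncol(dm$X))

  # residuals orthogonal to every design column
  noisy <- timeseries4d(array(y + rnorm(length(y)), c(shape, nvol)), 2, mask)
  fln <- first_level(noisy, dm, cvec)
  res <- t(vox_by_time_test(noisy$data)) - dm$X %*% t(fln$betas)
  expect_lt(max(abs(crossprod(dm$X, res))), 1e-7)

  # symmetry: data equal to the sum of both condition regressors gives a
  # zero difference contrast
  ysum <- matrix(rep(dm$X[, cidx[1]] + dm$X[, cidx[2]], nv),
                 nv, nvol, byrow = TRUE)
  fls <- first_level(timeseries4d(array(ysum, c(shape, nvol)), 2, mask),
                     dm, cvec)
  expect_equal(fls$contrast_map, rep(0, nv), tolerance = 1e-8)

  # pure noise: contrast map centered at zero
  set.seed(2)
  fl0 <- first_level(timeseries4d(array(rnorm(nv * nvol), c(shape, nvol)),
                                  2, mask), dm, cvec)
  se <- sd(fl0$contrast_map) / sqrt(nv)
  expect_lt(abs(mean(fl0$contrast_map)), 4 * se)
})

test_that("second level computes one-sample statistics and is exchangeable", {
  set.seed(3)
  maps <- matrix(rnorm(50 * 20, mean = 0.5), 50, 20)
  g <- second_level(maps)
  expect_equal(g$mean_map, rowMeans(maps))
  expect_equal(g$t_map, g$mean_map / sqrt(g$variance_map / 20))
  expect_equal(g$dof, 19)
  # subject permutation leaves the result unchanged
  g2 <- second_level(maps[, sample(20)])
  expect_equal(g2$t_map, g$t_map)

  # concentration near the true standardized effect
  expect_equal(mean(g$mean_map / sqrt(g$variance_map)), 0.5,
               tolerance = 3 / sqrt(20 * 50) * 5)

  # degenerate constant maps: zero variance flagged as NA t
  cm <- matrix(2, 10, 5)
  gc <- second_level(cm)
  expect_equal(gc$mean_map, rep(2, 10))
  expect_equal(gc$variance_map, rep(0, 10))
  expect_true(all(is.na(gc$t_map)))
  expect_error(second_level(matrix(1, 5, 1)), "n >= 2")
})

test_that("Benjamini-Hochberg thresholding controls and is monotone in q", {
  expect_true(fdr_threshold(0.04, 0.05)$mask)
  expect_false(any(fdr_threshold(rep(1, 100), 0.05)$mask))

  set.seed(4)
  p <- runif(2000)
  p[1:30] <- p[1:30] / 5000  # strong signals
  m1 <- fdr_threshold(p, 0.01)$mask
  m2 <- fdr_threshold(p, 0.05)$mask
  m3 <- fdr_threshold(p, 0.2)$mask
  expect_true(all(m1 <= m2) && all(m2 <= m3))
  expect_error(fdr_threshold(c(NA_real_, NA_real_)), "no p values")
  expect_error(fdr_threshold(c(0.5, 1.2)), "outside")
})

test_that("ROI effect sizes average voxelwise mean/sd and respect geometry", {
  shape <- c(7, 7, 7)
  affine <- grid_affine(shape, 4)
  nv <- prod(shape)
  mask <- array(TRUE, shape)
  g <- structure(list(mean_map = rep(1.2, nv), variance_map = rep(4, nv),
                      t_map = rep(NA_real_, nv), n = 10, dof = 9,
                      mask = mask, shape = shape),
                 class = "group_result")
  roi <- roi_spec("center", c(0, 0, 0), 8)
  expect_equal(roi_effect_size(g, roi, affine), 1.2 / 2)

  # two-voxel ROI averaging 0.2 and 0.4
  g2 <- g
  idx <- roi_voxels(roi_spec("pair", c(0, 0, 0), 4.1), shape, affine)
  expect_gt(length(idx), 2)
  g2$mean_map[] <- 0
  g2$variance_map[] <- 1
  two <- roi_voxels(roi_spec("two", c(0, 0, 2), 2.1), shape, affine)
  expect_equal(length(two), 2)
  g2$mean_map[two] <- c(0.2, 0.4)
  expect_equal(roi_effect_size(g2, roi_spec("two", c(0, 0, 2), 2.1),
                               affine), 0.3)

  # scale invariance of the standardized effect
  g3 <- g
  g3$mean_map <- g$mean_map * 7
  g3$variance_map <- g$variance_map * 49
  expect_equal(roi_effect_size(g3, roi, affine),
               roi_effect_size(g, roi, affine))

  # zero-variance voxels excluded with a warning
  g4 <- g
  ctr <- roi_voxels(roi, shape, affine)
  g4$variance_map[ctr[1]] <- 0
  expect_warning(es <- roi_effect_size(g4, roi, affine), "zero-variance")
  expect_equal(es, 0.6)

  # mirror symmetry of sphere voxelization under x sign flip
  roi_l <- roi_spec("l", c(-6, 2, 2), 8)
  roi_r <- roi_spec("r", c(6, 2, 2), 8)
  vl <- arrayInd(roi_voxels(roi_l, shape, affine), shape)
  vr <- arrayInd(roi_voxels(roi_r, shape, affine), shape)
  vl_flip <- cbind(shape[1] + 1L - vl[, 1], vl[, 2], vl[, 3])
  mode(vl_flip) <- "integer"
  expect_equal(nrow(vl), nrow(vr))
  ord <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  expect_equal(ord(vl_flip), ord(vr), ignore_attr = TRUE)

  # ROI outside the mask errors
  expect_error(roi_effect_size(g, roi_spec("out", c(500, 0, 0), 8), affine),
               "intersect")
})

test_that("the bundled ROI fixture loads and matches the published layout", {
  tab <- load_roi_table()
  expect_equal(nrow(tab), 11)
  expect_true(all(tab$radius_mm == 8))
  rois <- roi_list(tab)
  expect_s3_class(rois[[1]], "roi_spec")
  expect_true("rCereb" %in% tab$name)
  expect_equal(tab$y[tab$name == "rCereb"], -82)
})
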