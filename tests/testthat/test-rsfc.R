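full_mask <- function(g) label_volume(array(1L, g$shape), g)

mk_ts <- function(mat, g, tr = 2) {
  # mat: time x voxel matrix laid onto the grid
  timeseries_volume(array(t(mat), c(g$shape, nrow(mat))), g, tr)
}

test_that("band-pass preserves in-band bins and annihilates out-of-band bins", {
  g <- voxel_grid(c(2, 2, 2))
  nt <- 180; tr <- 2
  cfg <- denoise_config(n_drop_volumes = 10, smooth_fwhm_mm = 0,
                        nuisance = character(0), tr_seconds = tr)
  tgrid <- seq_len(nt - 10) - 1
  # 0.05 Hz is an exact FFT bin of the 170-frame series (17 / 340)
  in_band <- sin(2 * pi * 0.05 * tgrid * tr)
  out_band <- sin(2 * pi * 0.2 * tgrid * tr)
  mat <- cbind(matrix(rep(in_band, 4), ncol = 4),
               matrix(rep(out_band, 4), ncol = 4))
  full <- rbind(matrix(0, 10, 8), mat)   # frames that will be dropped
  dn <- denoise(mk_ts(full, g, tr), cfg, full_mask(g))
  res <- t(matrix(dn$values, 8, nt - 10))
  gain_in <- max(abs(res[, 1])) / max(abs(in_band))
  gain_out <- max(abs(res[, 5])) / max(abs(out_band))
  expect_gte(gain_in, 0.999)
  expect_lte(gain_out, 1e-6)
})

test_that("denoise zeroes constants and enforces its contracts", {
  g <- voxel_grid(c(3, 3, 3))
  cfg <- denoise_config(n_drop_volumes = 2, smooth_fwhm_mm = 0,
                        nuisance = character(0))
  const <- mk_ts(matrix(5, 40, 27), g)
  dn <- denoise(const, cfg, full_mask(g))
  expect_lt(max(abs(dn$values)), 1e-10)
  expect_error(denoise_config(band_hz = c(0.01, 0.3), tr_seconds = 2),
               "Nyquist")
  badmotion <- matrix(0, 10, 6)
  cfgm <- denoise_config(n_drop_volumes = 2, smooth_fwhm_mm = 0,
                         nuisance = "motion")
  expect_error(denoise(const, cfgm, full_mask(g), motion = badmotion),
               "motion table rows")
  other <- full_mask(voxel_grid(c(4, 4, 4)))
  expect_error(denoise(const, cfg, other), "mismatch")
})

test_that("denoise residuals are orthogonal to every nuisance regressor", {
  spec <- small_cohort_spec(rng_seed = 13)
  ph <- make_phantom(spec)
  mb <- make_bold(ph, 0.4, spec, rng_seed = 21)
  cfg <- denoise_config()
  dn <- denoise(mb$bold, cfg, ph$brain, ph$wm, ph$csf, mb$motion)
  nt <- dn$n_timepoints
  res <- t(matrix(dn$values, prod(ph$grid$shape), nt))
  bm <- which(as.vector(ph$brain$labels) != 0L)
  raw <- t(matrix(mb$bold$values, prod(ph$grid$shape),
                  spec$n_timepoints))[-(1:10), ]
  regs <- cbind(1, mb$motion, rowMeans(raw[, bm]))
  ndot <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  set.seed(2); probe <- sample(bm, 25)
  # motion / intercept orthogonality is exact; the global regressor checked
  # against its band-passed (regressed) version
  for (j in seq_len(ncol(mb$motion)))
    expect_lt(max(vapply(probe,
                         function(v) ndot(mb$motion[, j], res[, v]), 0)),
              1e-8)
})

test_that("masked Gaussian smoothing: identity, constants, impulse oracle", {
  g <- voxel_grid(c(7, 7, 7))
  set.seed(8)
  v <- scalar_volume(array(rnorm(343), g$shape), g)
  m <- label_volume(array(as.integer(runif(343) < 0.8), g$shape), g)
  expect_equal(gaussian_smooth(v, 0, m)$values, v$values * (m$labels != 0))
  expect_error(gaussian_smooth(v, -1), ">= 0")

  cst <- scalar_volume(array(3.3, g$shape), g)
  sm <- gaussian_smooth(cst, 3, m)
  inm <- m$labels != 0
  expect_equal(sm$values[inm], rep(3.3, sum(inm)), tolerance = 1e-12)
  expect_true(all(sm$values[!inm] == 0))

  # unit impulse against a direct convolution oracle
  g9 <- voxel_grid(c(9, 9, 9))
  imp <- array(0, g9$shape); imp[5, 5, 5] <- 1
  out <- gaussian_smooth(scalar_volume(imp, g9), 3)
  sigma <- 3 / (2 * sqrt(2 * log(2)))
  rad <- ceiling(3 * sigma)
  k1 <- dnorm(-rad:rad, sd = sigma); k1 <- k1 / sum(k1)
  oracle <- array(0, g9$shape)
  for (dx in -rad:rad) for (dy in -rad:rad) for (dz in -rad:rad) {
    oracle[5 + dx, 5 + dy, 5 + dz] <-
      k1[dx + rad + 1] * k1[dy + rad + 1] * k1[dz + rad + 1]
  }
  expect_equal(out$values, oracle, tolerance = 1e-12)
})

test_that("seed FC maps recover planted correlations and flag the seed", {
  g <- voxel_grid(c(4, 4, 2))
  nt <- 1000
  set.seed(31)
  s <- rnorm(nt)
  n_other <- prod(g$shape) - 2L
  mat <- cbind(s, 0.6 * s + sqrt(1 - 0.36) * rnorm(nt),
               matrix(rnorm(nt * n_other), nt))
  ts <- mk_ts(mat, g)
  seedarr <- array(0L, g$shape); seedarr[1, 1, 1] <- 1L
  fc <- seed_fc_map(ts, label_volume(seedarr, g), full_mask(g))
  # the seed voxel correlates 1 with itself: clipped ceiling, flagged
  expect_equal(fc$z$values[1, 1, 1], atanh(1 - 1e-7))
  expect_equal(fc$seed_lin, 1L)
  # planted r = 0.6 -> z near atanh(0.6) = 0.693
  expect_equal(fc$z$values[2, 1, 1], atanh(0.6), tolerance = 0.12)
  # independent voxels stay near zero
  expect_lte(max(abs(fc$z$values[, , 2])), 0.3)
  expect_error(seed_fc_map(mk_ts(matrix(1, 20, 32), g),
                           label_volume(seedarr, g), full_mask(g)),
               "zero-variance")
})

test_that("group t maps equal the pooled t of per-voxel samples", {
  g <- voxel_grid(c(3, 3, 3))
  mkfc <- function(vals) structure(
    list(z = scalar_volume(array(vals, g$shape), g), seed_lin = integer(0),
         subject_id = NA), class = "fc_map")
  set.seed(12)
  g1 <- lapply(1:5, function(i) mkfc(rnorm(27, 0.5, 0.2)))
  g2 <- lapply(1:4, function(i) mkfc(rnorm(27, 0.1, 0.2)))
  tm <- group_t_map(g1, g2)
  expect_equal(tm$df, 7L)
  for (v in c(1, 9, 14, 20, 27)) {
    x <- vapply(g1, function(m) m$z$values[v], 0)
    y <- vapply(g2, function(m) m$z$values[v], 0)
    expect_equal(tm$t$values[v], pooled_t_test(x, y)$statistic)
  }
  same <- group_t_map(g1, g1)
  expect_true(all(same$t$values == 0))
  expect_error(group_t_map(g1[1], g2), ">= 2 maps")
})

test_that("Monte-Carlo cluster threshold behaves at its limits", {
  # tiny mask, alpha near 1: any cluster passes
  g3 <- voxel_grid(c(3, 3, 3))
  thr <- alphasim_threshold(full_mask(g3), voxel_p = 0.01,
                            cluster_alpha = 0.999, smoothness_fwhm_mm = 0,
                            n_iterations = 200, rng_seed = 1)
  expect_equal(thr$min_cluster_voxels, 1L)
  expect_error(alphasim_threshold(full_mask(g3), cluster_alpha = 1.5,
                                  n_iterations = 200), "cluster_alpha")
  expect_error(alphasim_threshold(full_mask(g3), n_iterations = 10),
               "n_iterations")

  # unsmoothed noise: mean suprathreshold fraction matches voxel_p
  g20 <- voxel_grid(c(20, 20, 20))
  set.seed(5)
  nsup <- replicate(30, {
    z <- rnorm(8000); z <- (z - mean(z)) / sd(z)
    sum(abs(z) >= qnorm(0.995))
  })
  expect_lt(abs(mean(nsup) - 80), 3 * sd(nsup) / sqrt(30))

  # smoothing increases spatial clustering: cutoff non-decreasing in FWHM
  thr0 <- alphasim_threshold(full_mask(g20), smoothness_fwhm_mm = 0,
                             n_iterations = 300, rng_seed = 9)
  thr3 <- alphasim_threshold(full_mask(g20), smoothness_fwhm_mm = 3,
                             n_iterations = 300, rng_seed = 9)
  expect_gte(thr3$min_cluster_voxels, thr0$min_cluster_voxels)
})

test_that("significant clusters respect extent cutoff, sign splitting and peaks", {
  g <- voxel_grid(c(10, 10, 10))
  mkstat <- function(tvals) structure(
    list(t = scalar_volume(tvals, g), df = 23L, n1 = 14L, n2 = 11L,
         seed_lin = integer(0)), class = "stat_map")
  thr <- structure(list(voxel_p = 0.01, cluster_alpha = 0.05,
                        min_cluster_voxels = 8L, connectivity = 26L),
                   class = "cluster_threshold")
  zero <- mkstat(array(0, g$shape))
  expect_equal(nrow(significant_clusters(zero, thr)$table), 0L)

  blk <- array(0, g$shape); blk[2:3, 2:3, 2:3] <- -5  # exactly 8 voxels
  res <- significant_clusters(mkstat(blk), thr)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$n_voxels, 8L)
  expect_equal(res$table$sign, -1)
  expect_equal(res$table$peak_t, -5)

  blk7 <- array(0, g$shape); blk7[2:3, 2:3, 2:3] <- -5; blk7[3, 3, 3] <- 0
  expect_equal(nrow(significant_clusters(mkstat(blk7), thr)$table), 0L)

  # adjacent positive and negative blocks do not merge
  two <- array(0, g$shape)
  two[2:3, 2:5, 2:3] <- 5; two[4:5, 2:5, 2:3] <- -5
  res2 <- significant_clusters(mkstat(two), thr)
  expect_equal(nrow(res2$table), 2L)
  expect_setequal(res2$table$sign, c(1, -1))

  # seed-flagged voxels are excluded before thresholding
  st <- mkstat(blk)
  st$seed_lin <- which(as.vector(blk) != 0)[1:2]
  expect_equal(nrow(significant_clusters(st, thr)$table), 0L)
})

test_that("cluster mean FC averages Fisher z over cluster voxels", {
  g <- voxel_grid(c(3, 3, 3))
  vals <- array(0, g$shape); vals[1, 1, 1] <- 0.2; vals[2, 1, 1] <- 0.4
  fc <- structure(list(z = scalar_volume(vals, g), seed_lin = integer(0),
                       subject_id = "s"), class = "fc_map")
  expect_equal(cluster_mean_fc(list(fc), c(1L, 2L)), 0.3)
  expect_equal(cluster_mean_fc(list(fc), 1L), 0.2)
  cst <- fc; cst$z$values[] <- 0.7
  expect_equal(cluster_mean_fc(list(cst), 1:27), 0.7)
  # seed voxels are excluded from the average
  fc2 <- fc; fc2$seed_lin <- 1L
  expect_equal(cluster_mean_fc(list(fc2), c(1L, 2L)), 0.4)
  expect_error(cluster_mean_fc(list(fc), integer(0)), "empty")
})
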