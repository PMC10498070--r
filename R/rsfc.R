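#' @title Seed-based resting-state functional connectivity
#' @description BOLD denoising (volume dropping, masked Gaussian smoothing,
#'   nuisance regression, ideal FFT band-pass), seed-based correlation maps
#'   with Fisher's z, voxel-wise pooled-t group comparison, and Monte-Carlo
#'   (AlphaSim-style) cluster-extent correction.
#' @name rsfc
NULL

#' Denoising configuration
#'
#' @param n_drop_volumes leading volumes to discard (default 10).
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm (default 3).
#' @param band_hz numeric pair `(low, high)` in Hz, `0 <= low < high <
#'   Nyquist` (default `c(0.01, 0.1)`).
#' @param nuisance subset of `c("motion", "wm", "csf", "global")`.
#' @param tr_seconds repetition time (default 2).
#' @return a `denoise_config` list.
#' @export
denoise_config <- function(n_drop_volumes = 10L, smooth_fwhm_mm = 3,
                           band_hz = c(0.01, 0.1),
                           nuisance = c("motion", "wm", "csf", "global"),
                           tr_seconds = 2) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(band_hz[1] >= 0 && band_hz[1] < band_hz[2] && band_hz[2] < nyq))
    stop("band must satisfy 0 <= low < high < Nyquist = ", nyq, " Hz")
  if (length(nuisance))
    nuisance <- match.arg(nuisance, c("motion", "wm", "csf", "global"),
                          several.ok = TRUE)
  else nuisance <- character(0)
  structure(list(n_drop_volumes = as.integer(n_drop_volumes),
                 smooth_fwhm_mm = smooth_fwhm_mm, band_hz = band_hz,
                 nuisance = nuisance, tr_seconds = tr_seconds),
            class = "denoise_config")
}

gauss_band_matrix <- function(n, s) {
  rad <- max(1L, ceiling(3 * s))
  kk <- stats::dnorm(-rad:rad, sd = s)
  kk <- kk / sum(kk)
  km <- matrix(0, n, n)
  for (o in -rad:rad) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    km[cbind(i[ok], j[ok])] <- km[cbind(i[ok], j[ok])] + kk[o + rad + 1L]
  }
  km
}

# Separable Gaussian convolution (zero-padded boundaries) of a 3-D array,
# or of a 4-D array frame-by-frame (the 4th dimension is untouched),
# implemented as one small dense band matrix product per spatial axis.
smooth_core <- function(arr, sigma_vox) {
  d <- dim(arr)
  nd <- length(d)
  rest <- function(ax) prod(d[-ax]) # product of the remaining dims
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    km <- gauss_band_matrix(d[ax], s)
    if (ax == 1L) {
      arr <- array(km %*% matrix(arr, d[1], rest(1L)), d)
    } else {
      perm <- seq_len(nd)
      perm[c(1L, ax)] <- c(ax, 1L)
      a <- aperm(arr, perm)
      a <- array(km %*% matrix(a, d[ax], rest(ax)), d[perm])
      arr <- aperm(a, perm)
    }
  }
  arr
}

#' Masked Gaussian smoothing
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis (converted from mm to voxels). Within a mask the kernel is
#' renormalized by the smoothed mask, so smoothing a constant inside the
#' mask returns that constant; voxels outside the mask are zero.
#' `fwhm_mm = 0` is the identity (within the mask).
#'
#' @param v a `scalar_volume` or a bare 3-D array (with `grid` supplied).
#' @param fwhm_mm FWHM in mm (>= 0).
#' @param mask optional `label_volume`; `NULL` smooths the full grid.
#' @param grid required when `v` is a bare array.
#' @return same type as `v`.
#' @export
gaussian_smooth <- function(v, fwhm_mm, mask = NULL, grid = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  is_vol <- inherits(v, "scalar_volume")
  arr <- if (is_vol) v$values else v
  g <- if (is_vol) v$grid else grid
  if (is.null(g)) stop("grid required for bare arrays")
  m <- if (is.null(mask)) NULL else (mask$labels != 0L)
  if (fwhm_mm == 0) {
    out <- if (is.null(m)) arr else arr * m
    return(if (is_vol) scalar_volume(out, g) else out)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / g$voxel_size_mm
  if (is.null(m)) {
    out <- smooth_core(arr, sigma)
  } else {
    num <- smooth_core(arr * m, sigma)
    den <- smooth_core(m + 0, sigma)
    out <- array(0, dim(arr))
    out[m] <- num[m] / den[m]
  }
  if (is_vol) scalar_volume(out, g) else out
}

# Ideal band-pass by zeroing FFT bins outside [low, high] Hz (two-sided,
# inclusive with a small numeric tolerance). Y: T x nvoxel matrix.
bandpass_mat <- function(y, tr_seconds, band_hz) {
  nt <- nrow(y)
  f <- (seq_len(nt) - 1) / (nt * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)   # two-sided frequency magnitude
  keep <- f >= band_hz[1] - 1e-12 & f <= band_hz[2] + 1e-12
  yf <- stats::mvfft(y)
  yf[!keep, ] <- 0
  Re(stats::mvfft(yf, inverse = TRUE)) / nt
}

#' Denoise a BOLD time series
#'
#' Applies, in order: (1) dropping of the first `n_drop_volumes` frames,
#' (2) masked Gaussian smoothing of every frame, (3) an ideal FFT
#' band-pass restricted to `band_hz`, and (4) ordinary least-squares
#' removal of the band-passed nuisance signals (intercept, motion columns,
#' white-matter mean, CSF mean, global mean — per the config). Filtering
#' before the regression keeps the residuals exactly orthogonal to the
#' nuisance regressors (see the methods vignette).
#'
#' @param ts a `timeseries_volume`.
#' @param cfg a [denoise_config()].
#' @param brain_mask,wm_mask,csf_mask `label_volume`s on the same grid.
#' @param motion numeric matrix of motion parameters whose rows must equal
#'   the number of timepoints remaining after dropping.
#' @return a denoised `timeseries_volume` (zeros outside the brain mask).
#' @export
denoise <- function(ts, cfg, brain_mask, wm_mask = NULL, csf_mask = NULL,
                    motion = NULL) {
  if (!grids_compatible(ts$grid, brain_mask$grid))
    stop("mask/grid mismatch")
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(cfg$band_hz[1] >= 0 && cfg$band_hz[1] < cfg$band_hz[2] &&
        cfg$band_hz[2] < nyq))
    stop("band outside Nyquist range")
  arr <- ts$values
  nt0 <- dim(arr)[4]
  keep <- seq.int(cfg$n_drop_volumes + 1L, nt0)
  arr <- arr[, , , keep, drop = FALSE]
  nt <- length(keep)
  if ("motion" %in% cfg$nuisance) {
    if (is.null(motion)) stop("motion table required by config")
    motion <- as.matrix(motion)
    if (nrow(motion) != nt)
      stop("motion table rows must equal timepoints after dropping")
  }
  if (cfg$smooth_fwhm_mm > 0) {
    sigma <- cfg$smooth_fwhm_mm / (2 * sqrt(2 * log(2))) / ts$grid$voxel_size_mm
    mk <- (brain_mask$labels != 0L) + 0
    den <- smooth_core(mk, sigma)           # mask renormalization, once
    den[mk == 0] <- 1
    arr <- smooth_core(arr * as.vector(mk), sigma) / as.vector(den)
    arr <- arr * as.vector(mk)
  }
  bm <- as.vector(brain_mask$labels != 0L)
  y <- matrix(arr, prod(ts$grid$shape), nt)  # voxels x time
  y <- t(y[bm, , drop = FALSE])              # time x in-mask voxels
  # band-pass first, then regress band-passed nuisance signals: residuals
  # are exactly orthogonal to the raw regressors (the in-band part by OLS,
  # the out-of-band part because the residuals live in the band subspace)
  y <- bandpass_mat(y, ts$tr_seconds, cfg$band_hz)
  x <- matrix(1, nt, 1)
  if ("motion" %in% cfg$nuisance)
    x <- cbind(x, bandpass_mat(motion, ts$tr_seconds, cfg$band_hz))
  if ("wm" %in% cfg$nuisance) {
    if (is.null(wm_mask)) stop("wm mask required by config")
    wmv <- as.vector(wm_mask$labels != 0L)[bm]
    x <- cbind(x, rowMeans(y[, wmv, drop = FALSE]))
  }
  if ("csf" %in% cfg$nuisance) {
    if (is.null(csf_mask)) stop("csf mask required by config")
    csv <- as.vector(csf_mask$labels != 0L)[bm]
    x <- cbind(x, rowMeans(y[, csv, drop = FALSE]))
  }
  if ("global" %in% cfg$nuisance) x <- cbind(x, rowMeans(y))
  fit <- stats::lm.fit(x, y)
  y <- as.matrix(fit$residuals)
  out <- matrix(0, prod(ts$grid$shape), nt)
  out[bm, ] <- t(y)
  timeseries_volume(array(out, c(ts$grid$shape, nt)), ts$grid,
                    ts$tr_seconds)
}

#' Seed-based functional connectivity map
#'
#' The seed series is the mean over seed-mask voxels; every in-brain voxel
#' gets the Pearson correlation of its series with the seed series,
#' Fisher-z transformed (clipped near |r| = 1). Seed voxels are recorded
#' so they can be excluded from downstream cluster statistics.
#'
#' @param ts a (denoised) `timeseries_volume`.
#' @param seed_mask non-empty `label_volume` of seed voxels.
#' @param brain_mask `label_volume` of in-brain voxels.
#' @param subject_id optional identifier carried in the result.
#' @return object of class `fc_map`: `z` (a `scalar_volume`), `seed_lin`
#'   (linear indices flagged as seed), `subject_id`.
#' @export
seed_fc_map <- function(ts, seed_mask, brain_mask, subject_id = NA) {
  if (!grids_compatible(ts$grid, seed_mask$grid) ||
      !grids_compatible(ts$grid, brain_mask$grid))
    stop("mask/grid mismatch")
  bm <- as.vector(brain_mask$labels != 0L)
  sm <- which(as.vector(seed_mask$labels != 0L))
  if (!length(sm)) stop("empty seed mask")
  nt <- ts$n_timepoints
  y <- t(matrix(ts$values, prod(ts$grid$shape), nt))  # time x voxels
  seed <- rowMeans(y[, sm, drop = FALSE])
  if (stats::sd(seed) == 0) stop("zero-variance seed series")
  yc <- sweep(y[, bm, drop = FALSE], 2L, colMeans(y[, bm, drop = FALSE]))
  sc <- seed - mean(seed)
  sds <- sqrt(colSums(yc^2))
  r <- as.vector(crossprod(yc, sc)) / (sds * sqrt(sum(sc^2)))
  r[sds == 0] <- 0
  z <- fisher_z(r)
  zz <- numeric(prod(ts$grid$shape))
  zz[bm] <- z
  structure(list(z = scalar_volume(array(zz, ts$grid$shape), ts$grid),
                 seed_lin = sm, subject_id = subject_id),
            class = "fc_map")
}

#' Voxel-wise two-sample pooled-t map between groups of FC maps
#'
#' @param maps_g1,maps_g2 lists of `fc_map`s (>= 2 per group) on one grid.
#' @return object of class `stat_map`: `t` (a `scalar_volume`), `df`,
#'   `n1`, `n2`, and the union of seed-flagged voxels.
#' @export
group_t_map <- function(maps_g1, maps_g2) {
  n1 <- length(maps_g1); n2 <- length(maps_g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 maps per group")
  g <- maps_g1[[1]]$z$grid
  ok <- vapply(c(maps_g1, maps_g2),
               function(m) grids_compatible(m$z$grid, g), logical(1))
  if (!all(ok)) stop("FC map grid mismatch")
  a1 <- vapply(maps_g1, function(m) as.vector(m$z$values),
               numeric(prod(g$shape)))
  a2 <- vapply(maps_g2, function(m) as.vector(m$z$values),
               numeric(prod(g$shape)))
  m1 <- rowMeans(a1); m2 <- rowMeans(a2)
  v1 <- rowSums((a1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((a2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tval[!is.finite(tval)] <- 0
  seed_lin <- sort(unique(unlist(lapply(c(maps_g1, maps_g2),
                                        function(m) m$seed_lin))))
  structure(list(t = scalar_volume(array(tval, g$shape), g),
                 df = n1 + n2 - 2L, n1 = n1, n2 = n2, seed_lin = seed_lin),
            class = "stat_map")
}

#' Monte-Carlo (AlphaSim-style) cluster-extent threshold
#'
#' Estimates the minimum cluster size controlling the family-wise rate of
#' suprathreshold clusters under smooth Gaussian noise: each iteration
#' draws white noise in the mask, smooths it at `smoothness_fwhm_mm`,
#' standardizes it within the mask, applies the two-sided voxel threshold,
#' and records the maximum connected-component size (positive and negative
#' tails clustered separately). The returned cutoff is the smallest `s`
#' with empirical `P(max cluster >= s) <= cluster_alpha`.
#'
#' @param brain_mask `label_volume` defining the noise support.
#' @param voxel_p two-sided cluster-forming voxel p (default .01).
#' @param cluster_alpha cluster-level alpha in (0, 1) (default .05).
#' @param smoothness_fwhm_mm assumed spatial smoothness (default 3 mm,
#'   i.e. the applied smoothing kernel).
#' @param connectivity cluster connectivity (default 26).
#' @param n_iterations Monte-Carlo iterations (>= 100).
#' @param rng_seed integer seed (deterministic result).
#' @param group_sizes optional integer pair `(n1, n2)`. When supplied, each
#'   iteration simulates the full group design — `n1 + n2` smooth noise
#'   fields combined into a pooled-t map thresholded at
#'   `qt(1 - voxel_p/2, df)` — so the null matches the statistic that will
#'   be thresholded. A single-field standardized Gaussian null (the
#'   classic construction) underestimates the cluster extent of group t
#'   maps at small df; see the methods vignette.
#' @return object of class `cluster_threshold` with fields `voxel_p`,
#'   `cluster_alpha`, `min_cluster_voxels`, `n_iterations`,
#'   `smoothness_fwhm_mm`, `connectivity`, `group_sizes`, and the
#'   empirical `max_sizes`.
#' @export
alphasim_threshold <- function(brain_mask, voxel_p = 0.01,
                               cluster_alpha = 0.05,
                               smoothness_fwhm_mm = 3, connectivity = 26,
                               n_iterations = 1000L, rng_seed = 1L,
                               group_sizes = NULL) {
  if (cluster_alpha <= 0 || cluster_alpha >= 1)
    stop("cluster_alpha must be in (0, 1)")
  if (n_iterations < 100L) stop("need n_iterations >= 100")
  g <- brain_mask$grid
  m <- brain_mask$labels != 0L
  nin <- sum(m)
  sigma <- smoothness_fwhm_mm / (2 * sqrt(2 * log(2))) / g$voxel_size_mm
  den <- if (smoothness_fwhm_mm > 0) smooth_core(m + 0, sigma)
  maxs <- integer(n_iterations)
  max_cluster <- function(z, thr_val) {
    mx <- 0L
    for (sgn in c(1, -1)) {
      sup <- label_volume(array(as.integer(sgn * z >= thr_val & m),
                                g$shape), g)
      cc <- connected_components(sup, 1L, connectivity)
      if (length(cc$sizes_voxels)) mx <- max(mx, max(cc$sizes_voxels))
    }
    mx
  }
  with_seed(rng_seed, {
    if (is.null(group_sizes)) {
      zthr <- stats::qnorm(1 - voxel_p / 2)
      for (it in seq_len(n_iterations)) {
        noise <- array(0, g$shape)
        noise[m] <- stats::rnorm(nin)
        if (smoothness_fwhm_mm > 0) {
          num <- smooth_core(noise * m, sigma)
          noise[m] <- num[m] / den[m]
        }
        v <- noise[m]
        z <- array(0, g$shape)
        z[m] <- (v - mean(v)) / stats::sd(v)
        maxs[it] <- max_cluster(z, zthr)
      }
    } else {
      n1 <- group_sizes[1]; n2 <- group_sizes[2]
      ns <- n1 + n2
      df <- n1 + n2 - 2
      tthr <- stats::qt(1 - voxel_p / 2, df)
      nvox <- prod(g$shape)
      for (it in seq_len(n_iterations)) {
        noise <- array(stats::rnorm(nvox * ns), c(g$shape, ns)) *
          as.vector(m)
        if (smoothness_fwhm_mm > 0)
          noise <- smooth_core(noise, sigma) / as.vector(den)
        y <- matrix(noise, nvox, ns)
        m1 <- rowMeans(y[, seq_len(n1), drop = FALSE])
        m2 <- rowMeans(y[, n1 + seq_len(n2), drop = FALSE])
        v1 <- rowSums((y[, seq_len(n1)] - m1)^2) / (n1 - 1)
        v2 <- rowSums((y[, n1 + seq_len(n2)] - m2)^2) / (n2 - 1)
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
        tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        tv[!is.finite(tv)] <- 0
        maxs[it] <- max_cluster(array(tv, g$shape), tthr)
      }
    }
  })
  # smallest s with P(max >= s) <= alpha
  s <- 1L
  while (mean(maxs >= s) > cluster_alpha) s <- s + 1L
  structure(list(voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 min_cluster_voxels = s, n_iterations = n_iterations,
                 smoothness_fwhm_mm = smoothness_fwhm_mm,
                 connectivity = connectivity, group_sizes = group_sizes,
                 max_sizes = maxs),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "<cluster_threshold: voxel p < %g, alpha %g -> >= %d voxels (%d iters)>\n",
    x$voxel_p, x$cluster_alpha, x$min_cluster_voxels, x$n_iterations))
  invisible(x)
}

#' Significant clusters of a group t map
#'
#' Applies the two-sided voxel threshold `|t| >= qt(1 - voxel_p/2, df)`,
#' labels connected components separately within positive and negative
#' tails (clusters never mix signs), and keeps those with at least
#' `min_cluster_voxels` voxels. Seed-flagged voxels are excluded before
#' thresholding.
#'
#' @param stat a `stat_map`.
#' @param thr a `cluster_threshold`.
#' @param connectivity override of the threshold's connectivity.
#' @return list with `labels` (a `label_volume`, cluster ids by decreasing
#'   size) and `table` (data.frame: cluster, sign, n_voxels, mm3, peak_t,
#'   peak_x/y/z).
#' @export
significant_clusters <- function(stat, thr,
                                 connectivity = thr$connectivity) {
  g <- stat$t$grid
  tcrit <- stats::qt(1 - thr$voxel_p / 2, stat$df)
  tv <- stat$t$values
  excl <- array(FALSE, g$shape)
  if (length(stat$seed_lin)) excl[stat$seed_lin] <- TRUE
  out <- integer(prod(g$shape))
  rows <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    sup <- (sgn * tv >= tcrit) & !excl
    cc <- connected_components(
      label_volume(array(as.integer(sup), g$shape), g), 1L, connectivity)
    if (!length(cc$sizes_voxels)) next
    keep <- which(cc$sizes_voxels >= thr$min_cluster_voxels)
    for (comp in keep) {
      cid <- cid + 1L
      idx <- which(as.vector(cc$labels$labels) == comp)
      out[idx] <- cid
      pk <- idx[which.max(sgn * tv[idx])]
      tri <- lin_to_triple(pk, g$shape)
      rows[[cid]] <- data.frame(
        cluster = cid, sign = sgn, n_voxels = length(idx),
        mm3 = length(idx) * voxel_volume_mm3(g),
        peak_t = tv[pk], peak_x = tri[1], peak_y = tri[2], peak_z = tri[3])
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), sign = numeric(0),
               n_voxels = integer(0), mm3 = numeric(0), peak_t = numeric(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0))
  if (nrow(tab) > 1L) { # renumber by decreasing size
    ord <- order(-tab$n_voxels)
    remap <- integer(nrow(tab)); remap[tab$cluster[ord]] <- seq_len(nrow(tab))
    out[out > 0L] <- remap[out[out > 0L]]
    tab <- tab[ord, , drop = FALSE]
    tab$cluster <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  list(labels = label_volume(array(out, g$shape), g), table = tab)
}

#' Per-subject mean Fisher-z connectivity within a cluster
#'
#' @param maps list of `fc_map`s.
#' @param cluster a `label_volume` (non-zero = cluster) or a vector of
#'   linear voxel indices; must be non-empty.
#' @return numeric vector of per-subject means (seed-flagged voxels are
#'   excluded per subject).
#' @export
cluster_mean_fc <- function(maps, cluster) {
  idx <- if (inherits(cluster, "label_volume"))
    which(as.vector(cluster$labels) != 0L) else as.integer(cluster)
  if (!length(idx)) stop("empty cluster")
  vapply(maps, function(m) {
    use <- setdiff(idx, m$seed_lin)
    if (!length(use)) stop("cluster entirely within seed")
    mean(m$z$values[use])
  }, numeric(1))
}
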