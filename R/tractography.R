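#' @title Monte-Carlo streamline tractography
#' @description Probabilistic fiber tracking over supplied per-voxel fiber
#'   orientation distributions (up to two per voxel, each a mean axis with
#'   an angular concentration and a volume fraction). At every step one
#'   sample is drawn from each available distribution and the sample
#'   closest in angle to the previous direction is taken; a streamline
#'   terminates on leaving the brain mask, exceeding the step budget, or
#'   turning more than the curvature limit. Arrival counts over a
#'   down-sampled target grid form each seed voxel's whole-brain anatomical
#'   connectivity profile.
#' @name tractography
NULL

#' Construct a fiber orientation field
#'
#' @param grid a `voxel_grid` (isotropic voxels required for tracking).
#' @param brain_mask a `label_volume` (non-zero = inside brain).
#' @param mu1 `n_voxel x 3` matrix of first mean directions (unit rows
#'   where `f1 > 0`); voxels in column-major (linear-index) order.
#' @param kappa1 positive angular concentrations, length `n_voxel`.
#' @param f1 volume fractions in `[0, 1]`.
#' @param mu2,kappa2,f2 optional second fiber population (default absent:
#'   `f2 = 0`).
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(grid, brain_mask, mu1, kappa1, f1,
                              mu2 = NULL, kappa2 = NULL, f2 = NULL) {
  nvox <- prod(grid$shape)
  if (!grids_compatible(grid, brain_mask$grid))
    stop("brain_mask grid mismatch")
  if (nrow(mu1) != nvox) stop("mu1 must have one row per voxel")
  if (is.null(f2)) f2 <- rep(0, nvox)
  if (is.null(mu2)) mu2 <- mu1
  if (is.null(kappa2)) kappa2 <- kappa1
  if (any(f1 + f2 > 1 + 1e-9)) stop("volume fractions must sum to <= 1")
  nrm <- sqrt(rowSums(mu1^2))
  act <- f1 > 0
  if (any(abs(nrm[act] - 1) > 1e-6))
    stop("mean directions must be unit-norm where the fraction is positive")
  structure(list(grid = grid, brain_mask = brain_mask,
                 mu1 = mu1, kappa1 = as.numeric(kappa1), f1 = as.numeric(f1),
                 mu2 = mu2, kappa2 = as.numeric(kappa2), f2 = as.numeric(f2)),
            class = "orientation_field")
}

row_normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Draw one direction sample per row: mean axis mu plus isotropic Gaussian
# perturbation of scale 1/sqrt(kappa), renormalized (axial von Mises-Fisher
# stand-in). Rows are unit vectors.
sample_orientations <- function(mu, kappa) {
  n <- nrow(mu)
  sd <- 1 / sqrt(kappa)
  row_normalize(mu + matrix(stats::rnorm(3 * n), n, 3) * sd)
}

# Core lockstep tracking engine. start_vox: n_stream x 3 voxel triples.
# Returns a 2-column matrix of distinct (stream id, visited linear voxel)
# pairs, including the starting voxel.
track_bundle <- function(field, start_vox, step_mm, max_steps,
                         curvature_limit_deg, rng_seed) {
  g <- field$grid
  vs <- g$voxel_size_mm
  if (max(abs(vs - vs[1])) > 1e-9)
    stop("tracking requires isotropic voxels")
  if (step_mm <= 0) stop("step_mm must be positive")
  d <- g$shape
  nxy <- d[1] * d[2]
  mask <- as.vector(field$brain_mask$labels) != 0L
  nstream <- nrow(start_vox)
  start_lin <- lin_index(start_vox[, 1], start_vox[, 2], start_vox[, 3], d)
  if (any(!mask[start_lin])) stop("seed outside brain mask")
  step_vox <- step_mm / vs[1]
  cos_lim <- cos(curvature_limit_deg * pi / 180)

  with_seed(rng_seed, {
    pos <- start_vox - 0.5            # continuous voxel coords, 0-based
    # initial direction: pick component by volume fraction, random axial sign
    f1 <- field$f1[start_lin]; f2 <- field$f2[start_lin]
    pick2 <- stats::runif(nstream) * (f1 + f2) > f1
    mu <- field$mu1[start_lin, , drop = FALSE]
    kap <- field$kappa1[start_lin]
    if (any(pick2)) {
      mu[pick2, ] <- field$mu2[start_lin[pick2], , drop = FALSE]
      kap[pick2] <- field$kappa2[start_lin[pick2]]
    }
    # the initial sample lies in the hemisphere of the stored mean axis
    # (directions are axes; propagation is sign-invariant afterwards)
    prev <- sample_orientations(mu, kap)

    visits_s <- vector("list", 64L); visits_v <- vector("list", 64L)
    nv <- 1L
    visits_s[[1L]] <- seq_len(nstream); visits_v[[1L]] <- start_lin
    active <- seq_len(nstream)
    cur_lin <- start_lin
    stepi <- 0L
    while (length(active) && stepi < max_steps) {
      stepi <- stepi + 1L
      lin <- cur_lin
      na <- length(active)
      s1 <- sample_orientations(field$mu1[lin, , drop = FALSE],
                                field$kappa1[lin])
      # axial: flip each sample into the hemisphere of the previous direction
      pa <- prev[active, , drop = FALSE]
      sg <- sign(rowSums(s1 * pa)); sg[sg == 0] <- 1
      s1 <- s1 * sg
      dot1 <- rowSums(s1 * pa)
      has2 <- field$f2[lin] > 0
      if (any(has2)) {
        s2 <- sample_orientations(field$mu2[lin, , drop = FALSE],
                                  field$kappa2[lin])
        sg2 <- sign(rowSums(s2 * pa)); sg2[sg2 == 0] <- 1
        s2 <- s2 * sg2
        dot2 <- rowSums(s2 * pa)
        use2 <- has2 & dot2 > dot1
        s1[use2, ] <- s2[use2, , drop = FALSE]
        dot1[use2] <- dot2[use2]
      }
      ok <- dot1 >= cos_lim              # curvature termination
      active <- active[ok]
      if (!length(active)) break
      dirs <- s1[ok, , drop = FALSE]
      newpos <- pos[active, , drop = FALSE] + step_vox * dirs
      iv <- floor(newpos) + 1
      inb <- iv[, 1] >= 1 & iv[, 1] <= d[1] &
             iv[, 2] >= 1 & iv[, 2] <= d[2] &
             iv[, 3] >= 1 & iv[, 3] <= d[3]
      lin_new <- rep(NA_integer_, nrow(iv))
      lin_new[inb] <- lin_index(iv[inb, 1], iv[inb, 2], iv[inb, 3], d)
      inb[inb] <- mask[lin_new[inb]]
      pos[active[inb], ] <- newpos[inb, , drop = FALSE]
      prev[active[inb], ] <- dirs[inb, , drop = FALSE]
      nv <- nv + 1L
      if (nv > length(visits_s)) {       # grow accumulators
        visits_s <- c(visits_s, vector("list", length(visits_s)))
        visits_v <- c(visits_v, vector("list", length(visits_v)))
      }
      visits_s[[nv]] <- active[inb]
      visits_v[[nv]] <- lin_new[inb]
      active <- active[inb]
      cur_lin <- lin_new[inb]
    }
    sid <- unlist(visits_s[seq_len(nv)], use.names = FALSE)
    vid <- unlist(visits_v[seq_len(nv)], use.names = FALSE)
    key <- (as.numeric(sid) - 1) * prod(d) + vid
    keep <- !duplicated(key)
    cbind(stream = sid[keep], voxel = vid[keep])
  })
}

#' Track streamlines from a single seed voxel
#'
#' Launches `n_samples` streamlines from the center of `seed` and returns
#' per-voxel arrival counts (each streamline increments a voxel at most
#' once, i.e. "number of traces arriving").
#'
#' @param field an `orientation_field`.
#' @param seed 1-based voxel index triple inside the brain mask.
#' @param n_samples number of streamlines (>= 1).
#' @param step_mm step length in mm (default 0.5).
#' @param max_steps step budget per streamline (default 2000).
#' @param curvature_limit_deg maximum turning angle per step (default 80).
#' @param rng_seed integer seed; identical seeds give identical counts.
#' @return a `scalar_volume` of arrival counts on the field grid.
#' @export
track_from_voxel <- function(field, seed, n_samples, step_mm = 0.5,
                             max_steps = 2000, curvature_limit_deg = 80,
                             rng_seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  starts <- matrix(as.integer(seed), n_samples, 3, byrow = TRUE)
  pairs <- track_bundle(field, starts, step_mm, max_steps,
                        curvature_limit_deg, rng_seed)
  counts <- numeric(prod(field$grid$shape))
  tab <- rowsum(rep(1, nrow(pairs)), group = pairs[, "voxel"])
  counts[as.integer(rownames(tab))] <- tab[, 1]
  scalar_volume(array(counts, field$grid$shape), field$grid)
}

#' Whole-brain connectivity profiles for every voxel of a seed region
#'
#' Tracks `n_samples` streamlines from each voxel of `seed_mask` and bins
#' the distinct-voxel arrival counts onto a coarser target grid by block
#' summation ([downsample_counts()]), yielding the seed-voxel x target
#' profile matrix used for connectivity-based parcellation.
#'
#' @param field an `orientation_field`.
#' @param seed_mask a `label_volume`; non-zero voxels are seeds (must be
#'   non-empty and inside the brain mask).
#' @param n_samples streamlines per seed voxel.
#' @param step_mm,max_steps,curvature_limit_deg tracking parameters, see
#'   [track_from_voxel()].
#' @param rng_seed integer seed; results are bit-identical for equal seeds.
#' @param target_factor integer down-sampling factor from the working grid
#'   to the profile target grid (default 3, i.e. 3 mm targets at a 1 mm
#'   working resolution).
#' @return object of class `connectivity_profiles`: `seed_voxels` (ordered
#'   index triples), `counts` (n_seed x n_target integer matrix),
#'   `target_grid`, `n_samples`.
#' @export
seed_region_profiles <- function(field, seed_mask, n_samples = 5000,
                                 step_mm = 0.5, max_steps = 2000,
                                 curvature_limit_deg = 80, rng_seed = 1L,
                                 target_factor = 3L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!grids_compatible(field$grid, seed_mask$grid))
    stop("seed mask grid mismatch")
  seed_lin <- which(as.vector(seed_mask$labels) != 0L)
  if (!length(seed_lin)) stop("empty seed mask")
  d <- field$grid$shape
  seeds <- lin_to_triple(seed_lin, d)
  nseed <- length(seed_lin)
  starts <- seeds[rep(seq_len(nseed), each = n_samples), , drop = FALSE]
  pairs <- track_bundle(field, starts, step_mm, max_steps,
                        curvature_limit_deg, rng_seed)
  # map fine voxels to coarse target blocks
  f <- as.integer(target_factor)
  od <- as.integer(ceiling(d / f))
  tri <- lin_to_triple(pairs[, "voxel"], d)
  tb <- 1L + (tri[, 1] - 1L) %/% f + ((tri[, 2] - 1L) %/% f) * od[1] +
    ((tri[, 3] - 1L) %/% f) * od[1] * od[2]
  srow <- (pairs[, "stream"] - 1L) %/% n_samples + 1L
  ntar <- prod(od)
  key <- (as.numeric(srow) - 1) * ntar + tb
  tab <- rowsum(rep(1L, length(key)), group = key)
  counts <- matrix(0L, nseed, ntar)
  kidx <- as.numeric(rownames(tab))
  counts[cbind(((kidx - 1) %/% ntar) + 1, ((kidx - 1) %% ntar) + 1)] <-
    as.integer(tab[, 1])
  structure(list(seed_voxels = seeds, seed_lin = seed_lin,
                 counts = counts,
                 target_grid = voxel_grid(
                   od, voxel_size_mm = field$grid$voxel_size_mm * f,
                   origin_mm = field$grid$origin_mm),
                 source_grid = field$grid,
                 n_samples = as.integer(n_samples)),
            class = "connectivity_profiles")
}

#' @export
print.connectivity_profiles <- function(x, ...) {
  cat(sprintf(
    "<connectivity_profiles: %d seed voxels x %d targets, %d samples/voxel>\n",
    nrow(x$counts), ncol(x$counts), x$n_samples))
  invisible(x)
}
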