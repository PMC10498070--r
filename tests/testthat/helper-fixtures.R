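# Fixtures built in code: small orientation fields and cohorts.

# A straight corridor field: nx voxels long, 3x3 cross-section, oriented +x
# with very high concentration (effectively deterministic tracking). The
# brain mask is the corridor only.
corridor_field <- function(nx = 12L, kappa = 1e8) {
  g <- voxel_grid(c(nx, 3L, 3L))
  brain <- label_volume(array(1L, g$shape), g)
  nvox <- prod(g$shape)
  mu <- matrix(rep(c(1, 0, 0), each = nvox), nvox, 3)
  orientation_field(g, brain, mu1 = mu, kappa1 = rep(kappa, nvox),
                    f1 = rep(1, nvox))
}

# Y-junction: seed voxel at (2,2,2) carries two fiber populations with
# volume fractions f_x (+x) and f_y (+y); two corridors lead to far ends.
junction_field <- function(f_x = 0.7, kappa = 1e6, n = 10L) {
  g <- voxel_grid(c(n, n, 3L))
  brainarr <- array(0L, g$shape)
  brainarr[, 2, 2] <- 1L       # +x corridor
  brainarr[2, , 2] <- 1L       # +y corridor
  brain <- label_volume(brainarr, g)
  nvox <- prod(g$shape)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  mu1 <- matrix(rep(ex, each = nvox), nvox, 3)
  mu2 <- matrix(rep(ey, each = nvox), nvox, 3)
  f1 <- rep(1, nvox); f2 <- rep(0, nvox)
  ycorr <- which(as.vector(brainarr) != 0L)
  tri <- amygparc:::lin_to_triple(ycorr, g$shape)
  on_y <- ycorr[tri[, 1] == 2L & tri[, 2] > 2L]
  for (v in on_y) { mu1[v, ] <- ey }           # +y corridor points +y
  seedlin <- amygparc:::lin_index(2L, 2L, 2L, g$shape)
  f1[seedlin] <- f_x; f2[seedlin] <- 1 - f_x   # junction voxel: two fibers
  orientation_field(g, brain, mu1 = mu1, kappa1 = rep(kappa, nvox),
                    f1 = f1, mu2 = mu2, kappa2 = rep(kappa, nvox), f2 = f2)
}

# A small, fast cohort for pipeline tests.
small_cohort_spec <- function(rng_seed = 1L, ...) {
  cohort_spec(n_md = 3L, n_mr = 3L, n_timepoints = 60L, rng_seed = rng_seed,
              ...)
}

small_run_config <- function(rng_seed = 1L, ...) {
  run_config(n_samples = 60L, max_steps = 120L, n_iterations = 200L,
             k_range = 2:3, rng_seed = rng_seed, ...)
}

# Brute-force Mann-Whitney U null distribution by enumeration of all
# C(n1+n2, n1) rank arrangements (independent oracle for the DP recursion).
enumerate_u_counts <- function(n1, n2) {
  n <- n1 + n2
  counts <- rep(0, n1 * n2 + 1L)
  combs <- utils::combn(n, n1)
  for (j in seq_len(ncol(combs))) {
    u <- sum(combs[, j]) - n1 * (n1 + 1) / 2
    counts[u + 1L] <- counts[u + 1L] + 1
  }
  counts
}

# Phantom Dice of an MPM labeling against ground truth, maximizing over the
# two label orientations.
mpm_truth_dice <- function(mpm, phantom) {
  seedlin <- which(as.vector(phantom$seed$labels) != 0L)
  truth <- as.vector(phantom$truth$labels)[seedlin]
  lab <- as.vector(mpm$labels$labels)[seedlin]
  sc <- function(map) mean(c(dice(which(lab == map[1]), which(truth == 1)),
                             dice(which(lab == map[2]), which(truth == 2))))
  max(sc(c(1, 2)), sc(c(2, 1)))
}
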