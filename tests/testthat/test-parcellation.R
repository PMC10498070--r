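fake_profiles <- function(counts) {
  n <- nrow(counts)
  structure(list(seed_voxels = cbind(seq_len(n), 1L, 1L),
                 seed_lin = seq_len(n), counts = counts,
                 target_grid = voxel_grid(c(ncol(counts), 1, 1)),
                 n_samples = max(counts)),
            class = "connectivity_profiles")
}

test_that("cross-correlation matches hand-computed Pearson values", {
  p <- fake_profiles(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 4), c(1, 2, 3)))
  r <- cross_correlation(p)
  expect_equal(r[1, 2], -1)
  expect_equal(r[1, 4], 1)
  expect_equal(r[1, 3], 0.982, tolerance = 1e-3)
  expect_equal(diag(r), rep(1, 4))
  expect_true(isSymmetric(r, tol = 1e-10))
  # constant profile rows are excluded with a warning
  pc <- fake_profiles(rbind(c(1, 2, 3), c(5, 5, 5), c(3, 2, 1)))
  expect_warning(rc <- cross_correlation(pc), "constant profile")
  expect_equal(dim(rc), c(2L, 2L))
  expect_equal(attr(rc, "excluded"), 2L)
})

block_sim <- function(n_per_block, noise_sd = 0, seed = 1) {
  n <- 2 * n_per_block
  s <- matrix(-1, n, n)
  s[seq_len(n_per_block), seq_len(n_per_block)] <- 1
  s[(n_per_block + 1):n, (n_per_block + 1):n] <- 1
  if (noise_sd > 0) {
    set.seed(seed)
    e <- matrix(rnorm(n * n, 0, noise_sd), n)
    s <- s + (e + t(e)) / 2
    s <- pmin(pmax(s, -1), 1)
  }
  diag(s) <- 1
  s
}

test_that("spectral clustering recovers block structure", {
  s <- block_sim(5)
  lab <- spectral_cluster(s, 2, rng_seed = 3)
  truth <- rep(1:2, each = 5)
  expect_true(all(lab == truth) || all(lab == 3 - truth))
  expect_equal(spectral_cluster(s, 1), rep(1L, 10))
  expect_error(spectral_cluster(s, 0), "k out of range")
  expect_error(spectral_cluster(s, 11), "k out of range")

  # planted two-block with additive noise: high agreement with truth
  sn <- block_sim(30, noise_sd = 0.2, seed = 7)
  labn <- spectral_cluster(sn, 2, rng_seed = 5)
  truthn <- rep(1:2, each = 30)
  agree <- max(mean(labn == truthn), mean(labn == 3 - truthn))
  expect_gte(agree, 0.9)
})

test_that("spectral clustering is invariant to seed-voxel ordering", {
  sn <- block_sim(12, noise_sd = 0.15, seed = 2)
  lab <- spectral_cluster(sn, 2, rng_seed = 9)
  set.seed(4)
  perm <- sample(24)
  labp <- spectral_cluster(sn[perm, perm], 2, rng_seed = 9)
  # the permuted labels induce the same partition (up to label swap)
  expect_true(all(labp == lab[perm]) || all(labp == 3 - lab[perm]))
})

test_that("silhouette matches a brute-force oracle on a 4-point instance", {
  # hand-tabulated distances via similarity: d = 1 - sim
  sim <- matrix(c(1.0, 0.8, 0.1, 0.0,
                  0.8, 1.0, 0.2, 0.1,
                  0.1, 0.2, 1.0, 0.7,
                  0.0, 0.1, 0.7, 1.0), 4, 4)
  labels <- c(1, 1, 2, 2)
  d <- 1 - sim
  oracle <- mean(vapply(1:4, function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    oth <- which(labels != labels[i])
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, 0))
  expect_equal(silhouette_value(sim, labels), oracle)

  # two tight, far-separated clusters approach 1
  tight <- block_sim(6)
  expect_gte(silhouette_value(tight, rep(1:2, each = 6)), 0.95)

  # random labels on structureless distances stay near 0
  set.seed(10)
  vals <- replicate(20, {
    e <- matrix(rnorm(100, 0, 0.3), 10)
    s <- pmin(pmax((e + t(e)) / 2, -1), 1); diag(s) <- 1
    silhouette_value(s, sample(rep(1:2, 5)))
  })
  expect_lte(max(abs(vals)), 0.25)
  expect_lte(abs(mean(vals)), 0.1)

  expect_error(silhouette_value(sim, rep(1, 4)), "at least 2")
  expect_error(silhouette_value(sim[1:2, 1:2], c(1, 2)), "singleton")
})

test_that("dice obeys its closed form and symmetry", {
  expect_equal(dice(1:5, 1:5), 1)
  expect_equal(dice(1:3, 4:6), 0)
  expect_equal(dice(1:4, c(3, 4, 2, 10, 11, 12)), 0.6)
  expect_equal(dice(1:4, 2:8), dice(2:8, 1:4))
  expect_error(dice(integer(0), integer(0)), "empty")
  # dice == 1 iff the sets are identical
  expect_lt(dice(1:4, 1:5), 1)
})

test_that("label matching aligns permuted parcellations", {
  ref <- rep(1:3, times = c(5, 3, 4))
  shuffled <- c(3, 1, 2)[ref]   # relabeled version of the same partition
  expect_equal(match_labels(ref, shuffled, 3), ref)
  # matching is robust to a few disagreements
  noisy <- shuffled; noisy[1] <- shuffled[6]
  matched <- match_labels(ref, noisy, 3)
  expect_equal(mean(matched == ref), 11 / 12)
})

test_that("select_k honors its contracts and flags unstable cohorts", {
  s <- block_sim(6)
  k <- select_k(list(s, s), k_range = 2, rng_seed = 1)
  expect_equal(as.integer(k), 2L)
  expect_error(select_k(list(s), 2), "at least 2 subjects")
  expect_error(select_k(list(s, s), integer(0)), "empty k_range")
  expect_error(select_k(list(s, s), 1:2), "within")

  # structureless profiles: reproducibility near chance, flagged unstable
  set.seed(4)
  sims <- lapply(1:3, function(i) {
    p <- matrix(rnorm(30 * 80), 30)
    r <- cor(t(p)); (r + t(r)) / 2
  })
  kn <- select_k(sims, 2:4, rng_seed = 5)
  expect_false(attr(kn, "stable"))
})

test_that("select_k recovers the planted two-subregion structure", {
  spec <- cohort_spec(rng_seed = 77)
  ph <- make_phantom(spec)
  sims <- lapply(1:3, function(i) {
    f <- make_orientation_field(ph, spec, rng_seed = derive_seed(77, i, 2))
    pr <- seed_region_profiles(f, ph$seed, n_samples = 80, max_steps = 120,
                               rng_seed = derive_seed(77, i, 10))
    cross_correlation(pr)
  })
  k <- select_k(sims, 2:5, rng_seed = 6)
  expect_equal(as.integer(k), 2L)
  expect_true(attr(k, "stable"))
  tab <- attr(k, "table")
  expect_equal(tab$mean_dice[tab$k == 2], 1, tolerance = 0.02)
})

test_that("group MPM majority vote, probabilities and tie-breaks", {
  g <- voxel_grid(c(4, 4, 4))
  seed_voxels <- cbind(1:4, 1L, 1L)
  labs <- list(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  m <- group_mpm(labs, seed_voxels, g, k = 2)
  expect_equal(as.vector(m$labels$labels[1:4, 1, 1]), c(1L, 1L, 2L, 2L))
  expect_equal(m$winning_prob, rep(1, 4))

  # 2-1 vote -> majority with probability 2/3
  labs2 <- list(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L), c(2L, 1L, 2L, 2L))
  m2 <- group_mpm(labs2, seed_voxels, g, k = 2)
  expect_equal(m2$labels$labels[1, 1, 1], 1L)
  expect_equal(m2$winning_prob[1], 2 / 3)

  # constructed 2-subject tie at voxel 2 whose neighbors are solidly
  # label 2 -> the neighbor rule assigns label 2
  labs3 <- list(c(2L, 1L, 2L, 2L), c(2L, 2L, 2L, 2L))
  m3 <- group_mpm(labs3, seed_voxels, g, k = 2)
  expect_equal(m3$labels$labels[2, 1, 1], 2L)

  # an isolated tied voxel with no in-mask neighbors falls back to the
  # lowest label index
  m4 <- group_mpm(list(c(1L), c(2L)), cbind(2L, 2L, 2L), g, k = 2)
  expect_equal(m4$labels$labels[2, 2, 2], 1L)

  expect_error(group_mpm(list(c(1L, 2L), c(1L)), seed_voxels[1:2, ], g, 2),
               "same seed voxels")
})
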