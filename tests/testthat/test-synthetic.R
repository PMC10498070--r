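test_that("phantom geometry: disjoint contiguous subregions, corridors, masks", {
  spec <- cohort_spec(rng_seed = 1)
  ph <- make_phantom(spec)
  expect_gte(sum(ph$sub_a$labels), 27)
  expect_gte(sum(ph$sub_b$labels), 27)
  expect_equal(sum(ph$sub_a$labels & ph$sub_b$labels), 0L)
  expect_equal(sum(ph$t1$labels & ph$t2$labels), 0L)
  # corridors are disjoint and inside the brain
  expect_true(all(ph$wm$labels[ph$brain$labels == 0L] == 0L))
  # seed, targets, wm all on the brain grid; seed inside brain
  for (nm in c("seed", "t1", "t2", "wm", "csf"))
    expect_true(grids_compatible(ph[[nm]]$grid, ph$grid))
  expect_true(all(ph$brain$labels[ph$seed$labels != 0L] == 1L))
  # each subregion is one connected component
  expect_length(connected_components(ph$sub_a, 1L, 6)$sizes_voxels, 1L)
  expect_length(connected_components(ph$sub_b, 1L, 6)$sizes_voxels, 1L)
  # ground truth labels match the subregions
  expect_equal(ph$truth$labels == 1L, ph$sub_a$labels == 1L)
  # deterministic (pure geometry)
  expect_identical(make_phantom(spec), ph)
  expect_error(cohort_spec(grid_shape = c(16, 16, 16)), "at least 24")
})

test_that("noise-free corridors carry nearly all samples from A to T1", {
  # zero planted angular noise and an effectively deterministic sampling
  # concentration make the corridor fully deterministic
  spec <- cohort_spec(angular_noise = 0, corridor_kappa = 1e8, rng_seed = 2)
  ph <- make_phantom(spec)
  f1 <- make_orientation_field(ph, spec, rng_seed = 5)
  cnt <- track_from_voxel(f1, c(4, 11, 11), n_samples = 200,
                          max_steps = 200, rng_seed = 3)
  entry <- cnt$values[18, 11, 11]   # first T1 voxel on the corridor line
  expect_gte(entry / 200, 0.99)
  # determinism of the field generator
  f2 <- make_orientation_field(ph, spec, rng_seed = 5)
  expect_identical(f1$mu1, f2$mu1)
  f3 <- make_orientation_field(ph, spec, rng_seed = 6)
  expect_false(identical(f3$mu1, f1$mu1))
})

test_that("planted BOLD coupling is recovered up to white-noise attenuation", {
  spec <- cohort_spec(bold_white_sd = 0.1, rng_seed = 3)
  ph <- make_phantom(spec)
  ia <- which(as.vector(ph$sub_a$labels) != 0L)
  i1 <- which(as.vector(ph$t1$labels) != 0L)
  measure_r <- function(coupling, seed) {
    mb <- make_bold(ph, coupling, spec, rng_seed = seed)
    y <- t(matrix(mb$bold$values, prod(ph$grid$shape), spec$n_timepoints))
    seedser <- rowMeans(y[, ia])
    mean(cor(seedser, y[, i1]))
  }
  r0 <- vapply(1:6, function(s) measure_r(0, 100 + s), 0)
  expect_lte(abs(mean(r0)), 3 * sd(r0) / sqrt(length(r0)))
  r5 <- vapply(1:10, function(s) measure_r(0.5, 200 + s), 0)
  expect_gte(mean(r5), 0.35)
  expect_lte(mean(r5), 0.6)
  # determinism and contract
  b1 <- make_bold(ph, 0.3, spec, rng_seed = 7)
  b2 <- make_bold(ph, 0.3, spec, rng_seed = 7)
  expect_identical(b1$bold$values, b2$bold$values)
  expect_identical(b1$motion, b2$motion)
  expect_equal(nrow(b1$motion), spec$n_timepoints - spec$n_drop_volumes)
  expect_error(make_bold(ph, 1, spec), "< 1")
})

test_that("behavior generator: linear rates, exact episode bookkeeping", {
  spec0 <- cohort_spec(behavior_noise_sd = 0, behavior_intercept = 10,
                       behavior_slope = -10, rng_seed = 4)
  subj <- data.frame(subject_id = c("a", "b", "c"), group = "MD", sex = "F",
                     coupling = c(0.1, 0.5, 2))
  beh <- make_behavior(subj[1:2, ], spec0, rng_seed = 1)
  expect_equal(beh$true_rates$true_rate, 10 - 10 * c(0.1, 0.5))
  # the emitted episodes reproduce the target rate exactly
  rates <- stereotypy_rates(beh$episodes, spec0$total_recorded_min)
  expect_equal(sort(rates$rate_s_per_min),
               sort(beh$true_rates$true_rate), tolerance = 1e-9)
  # negative coupling with a steep slope exceeds the feasible 60 s/min
  spec_hi <- cohort_spec(behavior_noise_sd = 0, behavior_intercept = 59,
                         behavior_slope = -10, rng_seed = 4)
  expect_error(make_behavior(data.frame(subject_id = "z", group = "MD",
                                        sex = "F", coupling = -0.5),
                             spec_hi, 1), "impossible rate")
  # rates are floored at zero
  splo <- cohort_spec(behavior_noise_sd = 0, behavior_intercept = 1,
                      behavior_slope = -10, rng_seed = 4)
  b0 <- make_behavior(subj[2, ], splo, rng_seed = 1)
  expect_equal(b0$true_rates$true_rate, 0)
  expect_true(is.na(b0$episodes$start_s[1]))
  # determinism
  expect_identical(make_behavior(subj[1:2, ], spec0, rng_seed = 9),
                   make_behavior(subj[1:2, ], spec0, rng_seed = 9))
})

test_that("stereotypy rates correlate negatively with true coupling", {
  spec <- cohort_spec(rng_seed = 1)
  neg <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    coupling <- rnorm(25, rep(c(spec$coupling_md, spec$coupling_mr),
                              c(14, 11)), spec$coupling_sd)
    subj <- data.frame(subject_id = sprintf("s%02d", 1:25),
                       group = rep(c("MD", "MR"), c(14, 11)), sex = "F",
                       coupling = coupling)
    beh <- make_behavior(subj, spec, rng_seed = 1000 + i)
    cor(beh$true_rates$true_rate, coupling) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("cohort simulation is deterministic and correctly structured", {
  spec <- small_cohort_spec(rng_seed = 11)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_equal(length(co1$subjects), 6L)
  expect_identical(co1$subjects[[1]]$bold$values,
                   co2$subjects[[1]]$bold$values)
  expect_identical(co1$episodes, co2$episodes)
  expect_identical(co1$ground_truth$coupling, co2$ground_truth$coupling)
  groups <- vapply(co1$subjects, `[[`, "", "group")
  expect_equal(sum(groups == "MD"), 3L)
  expect_equal(sum(groups == "MR"), 3L)
  # MD couplings are centred lower than MR couplings by construction
  expect_lt(mean(co1$ground_truth$coupling[groups == "MD"]),
            mean(co1$ground_truth$coupling[groups == "MR"]))
  co3 <- simulate_cohort(small_cohort_spec(rng_seed = 12))
  expect_false(identical(co1$subjects[[1]]$bold$values,
                         co3$subjects[[1]]$bold$values))
})
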