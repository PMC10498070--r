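#' @title Synthetic cohort with planted ground truth
#' @description Generates a complete in-silico cohort on a shared 1 mm
#'   grid: a phantom with a two-subregion seed ("amygdala" with an A/lateral
#'   and a B/medial part), white-matter corridors wiring A to a frontal
#'   target T1 ("IFG-like") and B to T2, per-subject fiber orientation
#'   fields, BOLD series in which the A-T1 coupling is weaker in the
#'   deprived (MD) group than in the control (MR) group, and behavioral
#'   episode logs whose stereotypy rates decrease with the true coupling.
#'   Ground truth (subregion labels, per-subject couplings and rates) is
#'   recorded before noise is applied downstream.
#' @name synthetic_data
NULL

#' Cohort specification
#'
#' Defaults mirror the study design this generator emulates: 14 deprived
#' (MD) and 11 mother-reared (MR) subjects, 180 BOLD volumes at TR = 2 s,
#' group couplings 0.2 (MD) vs 0.5 (MR), and stereotypy rates that are
#' linear in the true coupling with a negative slope.
#'
#' @param n_md,n_mr group sizes (>= 2).
#' @param grid_shape integer triple (default 24 x 24 x 24 at 1 mm).
#' @param coupling_md,coupling_mr group-level seed-to-T1 couplings in
#'   (-1, 1).
#' @param coupling_sd between-subject coupling SD (default 0.05).
#' @param behavior_intercept,behavior_slope,behavior_noise_sd linear model
#'   of the stereotypy rate (s/min) on true coupling; the slope must be
#'   negative and the noise SD positive.
#' @param total_recorded_min,n_sessions recorded minutes (default 120 =
#'   eight 15-minute sessions).
#' @param tr_seconds,n_timepoints BOLD timing (defaults 2 s, 180 volumes).
#' @param n_drop_volumes leading volumes the analysis will drop; motion
#'   tables are emitted for the remaining frames (default 10).
#' @param bold_white_sd white (thermal) noise SD on top of unit-variance
#'   band-limited signals (default 0.3).
#' @param t2_coupling B-to-T2 coupling, identical in both groups (0.35).
#' @param corridor_kappa,background_kappa angular concentrations of the
#'   corridor and background orientation distributions.
#' @param angular_noise SD (radians) of the perturbation applied to
#'   corridor axes per subject (default 0.1).
#' @param rng_seed cohort-level seed; all subject/stage seeds derive from
#'   it via [derive_seed()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_md = 14L, n_mr = 11L, grid_shape = c(24L, 24L, 24L),
                        coupling_md = 0.2, coupling_mr = 0.5,
                        coupling_sd = 0.05,
                        behavior_intercept = 12, behavior_slope = -20,
                        behavior_noise_sd = 2,
                        total_recorded_min = 120, n_sessions = 8L,
                        tr_seconds = 2, n_timepoints = 180L,
                        n_drop_volumes = 10L,
                        bold_white_sd = 0.3, t2_coupling = 0.35,
                        corridor_kappa = 50, background_kappa = 0.5,
                        angular_noise = 0.1, rng_seed = 1L) {
  if (n_md < 2L || n_mr < 2L) stop("need >= 2 subjects per group")
  if (abs(coupling_md) >= 1 || abs(coupling_mr) >= 1)
    stop("couplings must lie in (-1, 1)")
  if (behavior_slope >= 0) stop("behavior_slope must be negative")
  if (behavior_noise_sd < 0) stop("behavior_noise_sd must be non-negative")
  if (any(grid_shape < 24L))
    stop("phantom geometry needs a grid of at least 24 voxels per axis")
  structure(as.list(environment()), class = "cohort_spec")
}

region_box <- function(arr, x, y, z, val = 1L) { arr[x, y, z] <- val; arr }

#' Build the phantom anatomy
#'
#' Lays out, on the cohort grid: a two-part seed (A at the "amygdala"
#' location wired to frontal target T1, B wired to T2) with disjoint
#' contiguous subregions of 27 voxels each, 5^3-voxel targets, disjoint
#' white-matter corridors A->T1 and B->T2, a CSF block, and a whole-grid
#' brain mask. Deterministic (pure geometry).
#'
#' @param spec a [cohort_spec()].
#' @return list of `label_volume`s: `brain`, `seed`, `sub_a`, `sub_b`,
#'   `t1`, `t2`, `wm`, `csf`, and `truth` (1 = A, 2 = B), plus `grid`.
#' @export
make_phantom <- function(spec) {
  g <- voxel_grid(spec$grid_shape, voxel_size_mm = c(1, 1, 1))
  z0 <- array(0L, g$shape)
  a   <- region_box(z0, 4:6,   10:12, 10:12)
  b   <- region_box(z0, 4:6,   16:18, 10:12)
  t1  <- region_box(z0, 18:22,  9:13,  9:13)
  t2  <- region_box(z0, 18:22, 15:19,  9:13)
  wm  <- region_box(region_box(z0, 7:17, 10:12, 10:12), 7:17, 16:18, 10:12)
  csf <- region_box(z0, 2:4, 2:4, 2:4)
  if (any(a & b) || any(t1 & t2) || any((a | b) & (t1 | t2)))
    stop("phantom regions overlap")
  # the target "gyri" are bordered by sulcal CSF: a 2-voxel non-brain rim
  # around T1/T2 (sparing the white-matter corridors), as at a cortical
  # surface, so BOLD smoothing cannot blur gyral signal into a shell of
  # neighboring brain voxels
  clip <- function(v, n) pmax(1L, pmin(n, v))
  exp1 <- region_box(z0, clip(16:24, g$shape[1]), clip(7:15, g$shape[2]),
                     clip(7:15, g$shape[3]))
  exp2 <- region_box(z0, clip(16:24, g$shape[1]), clip(13:21, g$shape[2]),
                     clip(7:15, g$shape[3]))
  sulcus <- (exp1 | exp2) & !t1 & !t2 & !wm
  brain <- array(1L, g$shape)
  brain[sulcus] <- 0L
  list(grid = g,
       brain = label_volume(brain, g),
       seed = label_volume(a + b, g),
       sub_a = label_volume(a, g), sub_b = label_volume(b, g),
       t1 = label_volume(t1, g), t2 = label_volume(t2, g),
       wm = label_volume(wm, g), csf = label_volume(csf, g),
       truth = label_volume(a + 2L * b, g))
}

#' Per-subject fiber orientation field for the phantom
#'
#' Voxels on the A-T1 and B-T2 paths (seed, corridor and target voxels)
#' carry a high-concentration distribution along the corridor axis (+x),
#' each axis perturbed by `angular_noise` radians; all other brain voxels
#' carry a low-concentration distribution with a random axis, so off-path
#' streamlines wander and terminate.
#'
#' @param phantom output of [make_phantom()].
#' @param spec the [cohort_spec()] (concentrations, angular noise).
#' @param rng_seed integer seed (identical seeds give identical fields).
#' @return an `orientation_field`.
#' @export
make_orientation_field <- function(phantom, spec, rng_seed = 1L) {
  g <- phantom$grid
  nvox <- prod(g$shape)
  onpath <- as.vector(phantom$seed$labels | phantom$wm$labels |
                        phantom$t1$labels | phantom$t2$labels)
  with_seed(rng_seed, {
    mu <- matrix(stats::rnorm(3 * nvox), nvox, 3)
    mu <- row_normalize(mu)
    ax <- cbind(1, stats::rnorm(sum(onpath), 0, spec$angular_noise),
                stats::rnorm(sum(onpath), 0, spec$angular_noise))
    mu[onpath, ] <- row_normalize(ax)
    kap <- rep(spec$background_kappa, nvox)
    kap[onpath] <- spec$corridor_kappa
    orientation_field(g, phantom$brain, mu1 = mu, kappa1 = kap,
                      f1 = rep(1, nvox))
  })
}

# White noise restricted to the analysis band, columns scaled to unit SD.
# Synthesized directly in the frequency domain (complex Gaussian weights on
# the in-band FFT bins with conjugate symmetry), which is distributionally
# identical to band-pass-filtered white noise.
bandlimited_noise <- function(nt, ncol, tr, band) {
  f <- (seq_len(nt) - 1) / (nt * tr)
  pos <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12 &
                 seq_len(nt) <= floor(nt / 2) + 1L & seq_len(nt) > 1L)
  yf <- matrix(0i, nt, ncol)
  z <- matrix(stats::rnorm(length(pos) * ncol) +
                1i * stats::rnorm(length(pos) * ncol), length(pos), ncol)
  yf[pos, ] <- z
  yf[nt + 2L - pos, ] <- Conj(z)
  y <- Re(stats::mvfft(yf, inverse = TRUE)) / nt
  sds <- sqrt(colMeans(y^2) - colMeans(y)^2)
  sweep(y, 2L, sds, `/`)
}

#' Simulate a subject's BOLD run on the phantom
#'
#' A latent band-limited (0.01-0.1 Hz) signal `s1` drives the A subregion
#' (`A = s1 + white`); T1 voxels carry `c * s1 + sqrt(1 - c^2) *
#' independent band-limited noise + white`, so the expected seed-T1
#' correlation is `c` up to white-noise attenuation (factor
#' `1 / sqrt(1 + bold_white_sd^2)` at the voxel level). The B subregion and
#' T2 are driven the same way by an independent latent signal with the
#' group-independent coupling `t2_coupling`. All remaining voxels carry
#' independent band-limited noise plus white noise. Small synthetic motion
#' regressors (six columns of scaled random-walk drift) are returned for
#' the frames remaining after volume dropping.
#'
#' @param phantom output of [make_phantom()].
#' @param coupling subject's true A-T1 coupling, `|c| < 1`.
#' @param spec the [cohort_spec()].
#' @param rng_seed integer seed.
#' @return list with `bold` (a `timeseries_volume`) and `motion` (matrix
#'   with `n_timepoints - n_drop_volumes` rows, 6 columns).
#' @export
make_bold <- function(phantom, coupling, spec, rng_seed = 1L) {
  if (abs(coupling) >= 1) stop("|coupling| must be < 1")
  g <- phantom$grid
  nvox <- prod(g$shape)
  nt <- spec$n_timepoints
  band <- c(0.01, 0.1)
  with_seed(rng_seed, {
    lat <- bandlimited_noise(nt, 2L, spec$tr_seconds, band)  # s1, s2
    eps <- bandlimited_noise(nt, nvox, spec$tr_seconds, band)
    y <- eps
    ia <- which(as.vector(phantom$sub_a$labels) != 0L)
    ib <- which(as.vector(phantom$sub_b$labels) != 0L)
    i1 <- which(as.vector(phantom$t1$labels) != 0L)
    i2 <- which(as.vector(phantom$t2$labels) != 0L)
    y[, ia] <- lat[, 1]
    y[, ib] <- lat[, 2]
    c1 <- coupling; c2 <- spec$t2_coupling
    y[, i1] <- c1 * lat[, 1] + sqrt(1 - c1^2) * eps[, i1]
    y[, i2] <- c2 * lat[, 2] + sqrt(1 - c2^2) * eps[, i2]
    y <- y + matrix(stats::rnorm(nt * nvox, 0, spec$bold_white_sd), nt, nvox)
    nkeep <- nt - spec$n_drop_volumes
    motion <- apply(matrix(stats::rnorm(nkeep * 6, 0, 0.02), nkeep, 6),
                    2L, cumsum)
    list(bold = timeseries_volume(array(t(y), c(g$shape, nt)), g,
                                  spec$tr_seconds),
         motion = motion)
  })
}

#' Simulate behavioral episode logs from true couplings
#'
#' Each subject's target stereotypy rate is `intercept + slope * coupling
#' + Gaussian noise`, floored at 0 (rates above 60 s/min are impossible
#' and raise an error). Episode durations are drawn from a log-normal with
#' mean ~20 s and appended until they sum to the target total; episodes
#' are laid into consecutive 15-minute sessions with 1-second gaps.
#'
#' @param subjects data.frame with columns `subject_id, group, sex,
#'   coupling`.
#' @param spec the [cohort_spec()].
#' @param rng_seed integer seed.
#' @return list with `episodes` (a data.frame in episode-log format) and
#'   `true_rates` (data.frame of the realized target rates).
#' @export
make_behavior <- function(subjects, spec, rng_seed = 1L) {
  if (spec$behavior_slope >= 0) stop("behavior slope must be negative")
  session_s <- spec$total_recorded_min * 60 / spec$n_sessions
  with_seed(rng_seed, {
    rows <- list(); rates <- numeric(nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      target <- spec$behavior_intercept +
        spec$behavior_slope * subjects$coupling[i] +
        stats::rnorm(1, 0, spec$behavior_noise_sd)
      target <- max(0, target)
      if (target > 60) stop("impossible rate requested (> 60 s/min)")
      rates[i] <- target
      total_s <- target * spec$total_recorded_min
      durs <- c()
      while (sum(durs) < total_s - 1e-9) {
        d <- stats::rlnorm(1, meanlog = log(20) - 0.125, sdlog = 0.5)
        if (sum(durs) + d >= total_s) d <- total_s - sum(durs)
        if (d < 1e-3) break
        durs <- c(durs, d)
      }
      if (!length(durs)) {
        rows[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                                group = subjects$group[i],
                                sex = subjects$sex[i],
                                session_id = NA_character_,
                                start_s = NA_real_, stop_s = NA_real_)
        next
      }
      ses <- 1L; pos <- 0
      st <- sp <- numeric(length(durs)); sid <- character(length(durs))
      for (k in seq_along(durs)) {
        if (pos + durs[k] > session_s) { ses <- ses + 1L; pos <- 0 }
        if (ses > spec$n_sessions)
          stop("episodes exceed recorded time: rate too high")
        st[k] <- pos; sp[k] <- pos + durs[k]; sid[k] <- paste0("S", ses)
        pos <- sp[k] + 1
      }
      rows[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                              group = subjects$group[i],
                              sex = subjects$sex[i],
                              session_id = sid, start_s = st, stop_s = sp)
    }
    list(episodes = do.call(rbind, rows),
         true_rates = data.frame(subject_id = subjects$subject_id,
                                 true_rate = rates))
  })
}

#' Simulate a complete cohort
#'
#' Draws per-subject couplings around the group means, builds each
#' subject's orientation field and BOLD run, and generates the behavioral
#' logs. Fully deterministic given `spec$rng_seed`: subject and stage
#' seeds derive from it via [derive_seed()].
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: `spec`, `phantom`, `subjects` (per
#'   subject: id, group, sex, true coupling, `field`, `bold`, `motion`),
#'   `episodes`, and `ground_truth` (truth labels, couplings, true rates).
#' @export
simulate_cohort <- function(spec) {
  phantom <- make_phantom(spec)
  n <- spec$n_md + spec$n_mr
  group <- c(rep("MD", spec$n_md), rep("MR", spec$n_mr))
  # sex layout mirrors the emulated design: MD 7F/7M-like, MR 4F/7M-like
  sex <- c(rep(c("F", "M"), length.out = spec$n_md),
           rep(c("F", "M", "M"), length.out = spec$n_mr))
  ids <- sprintf("sub%02d", seq_len(n))
  cmean <- ifelse(group == "MD", spec$coupling_md, spec$coupling_mr)
  coupling <- with_seed(derive_seed(spec$rng_seed, 0, 1), {
    pmin(pmax(stats::rnorm(n, cmean, spec$coupling_sd), -0.95), 0.95)
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    fld <- make_orientation_field(phantom, spec,
                                  rng_seed = derive_seed(spec$rng_seed, i, 2))
    bl <- make_bold(phantom, coupling[i], spec,
                    rng_seed = derive_seed(spec$rng_seed, i, 3))
    subjects[[i]] <- list(subject_id = ids[i], group = group[i],
                          sex = sex[i], coupling = coupling[i],
                          field = fld, bold = bl$bold, motion = bl$motion)
  }
  beh <- make_behavior(
    data.frame(subject_id = ids, group = group, sex = sex,
               coupling = coupling, stringsAsFactors = FALSE),
    spec, rng_seed = derive_seed(spec$rng_seed, 0, 4))
  structure(list(spec = spec, phantom = phantom, subjects = subjects,
                 episodes = beh$episodes,
                 ground_truth = list(truth = phantom$truth,
                                     coupling = stats::setNames(coupling, ids),
                                     true_rates = beh$true_rates)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d MD + %d MR subjects on a %s grid, seed %d>\n",
              x$spec$n_md, x$spec$n_mr,
              paste(x$spec$grid_shape, collapse = "x"), x$spec$rng_seed))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Writes per-subject BOLD and orientation-field NIfTI volumes (direction
#' components, concentration and fraction, named in a JSON sidecar),
#' motion TSVs, the phantom masks, the episode log TSV, and a
#' ground-truth JSON.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phantom
  for (nm in c("brain", "seed", "sub_a", "sub_b", "t1", "t2", "wm", "csf",
               "truth"))
    write_volume(ph[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")))
  utils::write.table(cohort$episodes, file.path(dir, "episodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  g <- ph$grid
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_volume(s$bold, file.path(sd, "bold.nii.gz"))
    utils::write.table(s$motion, file.path(sd, "motion.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    f <- s$field
    for (j in 1:3)
      write_volume(scalar_volume(array(f$mu1[, j], g$shape), g),
                   file.path(sd, sprintf("fib1_dir%d.nii.gz", j)))
    write_volume(scalar_volume(array(f$kappa1, g$shape), g),
                 file.path(sd, "fib1_kappa.nii.gz"))
    write_volume(scalar_volume(array(f$f1, g$shape), g),
                 file.path(sd, "fib1_frac.nii.gz"))
    jsonlite::write_json(
      list(subject_id = s$subject_id, group = s$group, sex = s$sex,
           n_fibers = 1L,
           files = list(dir = sprintf("fib1_dir%d.nii.gz", 1:3),
                        kappa = "fib1_kappa.nii.gz",
                        frac = "fib1_frac.nii.gz")),
      file.path(sd, "field.json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(
    list(spec = cohort$spec[setdiff(names(cohort$spec), "grid_shape")],
         grid_shape = cohort$spec$grid_shape,
         subjects = data.frame(
           subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
           group = vapply(cohort$subjects, `[[`, "", "group"),
           sex = vapply(cohort$subjects, `[[`, "", "sex"),
           coupling = vapply(cohort$subjects, `[[`, 0, "coupling")),
         true_rates = cohort$ground_truth$true_rates),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `cohort` object.
#' @export
read_cohort <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  spec <- do.call(cohort_spec, c(gt$spec[intersect(names(gt$spec),
                                                   names(formals(cohort_spec)))],
                                 list(grid_shape = gt$grid_shape)))
  ph <- list(grid = voxel_grid(gt$grid_shape))
  for (nm in c("brain", "seed", "sub_a", "sub_b", "t1", "t2", "wm", "csf",
               "truth"))
    ph[[nm]] <- read_volume(file.path(dir, paste0("mask_", nm, ".nii.gz")),
                            as_labels = TRUE)
  subjects <- vector("list", nrow(gt$subjects))
  for (i in seq_len(nrow(gt$subjects))) {
    sid <- gt$subjects$subject_id[i]
    sd <- file.path(dir, sid)
    if (!dir.exists(sd)) stop("missing subject directory: ", sid)
    mu <- vapply(1:3, function(j) as.vector(read_volume(
      file.path(sd, sprintf("fib1_dir%d.nii.gz", j)))$values),
      numeric(prod(ph$grid$shape)))
    kap <- as.vector(read_volume(file.path(sd, "fib1_kappa.nii.gz"))$values)
    fr <- as.vector(read_volume(file.path(sd, "fib1_frac.nii.gz"))$values)
    fld <- orientation_field(ph$grid, ph$brain, mu1 = row_normalize(mu),
                             kappa1 = kap, f1 = fr)
    bold <- read_volume(file.path(sd, "bold.nii.gz"), expect_4d = TRUE,
                        tr_seconds = spec$tr_seconds)
    motion <- as.matrix(utils::read.table(file.path(sd, "motion.tsv")))
    subjects[[i]] <- list(subject_id = sid, group = gt$subjects$group[i],
                          sex = gt$subjects$sex[i],
                          coupling = gt$subjects$coupling[i],
                          field = fld, bold = bold, motion = motion)
  }
  episodes <- read_episode_log(file.path(dir, "episodes.tsv"))
  structure(list(spec = spec, phantom = ph, subjects = subjects,
                 episodes = episodes,
                 ground_truth = list(
                   truth = ph$truth,
                   coupling = stats::setNames(gt$subjects$coupling,
                                              gt$subjects$subject_id),
                   true_rates = gt$true_rates)),
            class = "cohort")
}
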