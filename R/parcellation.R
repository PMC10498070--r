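#' @title Connectivity-based parcellation
#' @description Seed voxels are clustered by the similarity of their
#'   whole-brain connectivity profiles: the profile cross-correlation
#'   matrix is turned into an affinity, embedded with the
#'   symmetric-normalized graph Laplacian, and partitioned with seeded
#'   k-means. The number of clusters is selected by combining the mean
#'   within-subject silhouette with across-subject reproducibility (mean
#'   matched Dice), and subject parcellations are aggregated into a group
#'   maximum probability map (MPM) with a neighbor-probability tie-break.
#' @name parcellation
NULL

#' Cross-correlation matrix of connectivity profiles
#'
#' Entry (i, j) is the Pearson correlation between the connectivity
#' profiles of seed voxels i and j; the diagonal is exactly 1. Seed voxels
#' with a constant profile (zero streamline spread) are excluded with a
#' warning; excluded row indices are recorded in the `"excluded"`
#' attribute.
#'
#' @param profiles a `connectivity_profiles` object (>= 2 seed voxels).
#' @return symmetric correlation matrix with attributes `seed_voxels`,
#'   `seed_lin`, `excluded`.
#' @export
cross_correlation <- function(profiles) {
  x <- profiles$counts
  if (nrow(x) < 2L) stop("need at least 2 seed voxels")
  sds <- apply(x, 1L, stats::sd)
  excl <- which(sds == 0)
  if (length(excl)) {
    warning(length(excl), " seed voxel(s) with constant profile excluded")
    x <- x[-excl, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  attr(r, "seed_voxels") <- if (length(excl))
    profiles$seed_voxels[-excl, , drop = FALSE] else profiles$seed_voxels
  attr(r, "seed_lin") <- if (length(excl))
    profiles$seed_lin[-excl] else profiles$seed_lin
  attr(r, "excluded") <- excl
  r
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized spectral clustering on the affinity `W = (sim + 1) / 2` with
#' a zeroed diagonal: rows of the top-k eigenvectors of the
#' symmetric-normalized affinity `D^-1/2 W D^-1/2` are length-normalized
#' and partitioned with k-means (seeded, multiple restarts). Deterministic
#' given `rng_seed`; `k = 1` returns a single cluster.
#'
#' @param sim symmetric similarity (correlation) matrix, entries in
#'   `[-1, 1]`.
#' @param k number of clusters, `1 <= k <= nrow(sim)`.
#' @param rng_seed integer seed for the k-means restarts.
#' @param n_restarts k-means restarts (default 50).
#' @return integer label vector in `1..k` (every cluster non-empty).
#' @export
spectral_cluster <- function(sim, k, rng_seed = 1L, n_restarts = 50L) {
  n <- nrow(sim)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) stop("k out of range")
  if (k == 1L) return(rep(1L, n))
  w <- (sim + 1) / 2
  diag(w) <- 0
  dg <- rowSums(w)
  dg[dg <= 0] <- 1e-12
  dis <- 1 / sqrt(dg)
  m <- w * tcrossprod(dis)
  ev <- eigen(m, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(k), drop = FALSE]
  emb <- row_normalize(emb)
  km <- with_seed(rng_seed,
                  stats::kmeans(emb, centers = k, nstart = n_restarts,
                                iter.max = 100L))
  as.integer(km$cluster)
}

#' Mean silhouette value of a clustering under profile-correlation distance
#'
#' Uses the distance `d = 1 - sim`. For each point, `a` is its mean
#' distance to its own cluster and `b` the smallest mean distance to
#' another cluster; the silhouette is the mean of `(b - a) / max(a, b)`.
#' Points in singleton clusters contribute 0 (the standard convention).
#'
#' @param sim similarity matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_value <- function(sim, labels) {
  dmat <- 1 - sim
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette needs at least 2 clusters")
  if (all(tabulate(labels) <= 1L))
    stop("silhouette undefined for singleton-only clusterings")
  n <- length(labels)
  sizes <- vapply(ks, function(kk) sum(labels == kk), integer(1))
  # mean distance of every point to every cluster
  msums <- vapply(ks, function(kk) rowSums(dmat[, labels == kk, drop = FALSE]),
                  numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], ks)
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- msums[i, ci] / (sizes[ci] - 1L)
    b <- min(msums[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Dice overlap coefficient of two voxel sets
#'
#' @param a,b vectors of voxel identifiers (e.g. linear indices) from a
#'   common universe; both empty is an error.
#' @return `2 |A intersect B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) stop("both sets empty")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Mean per-cluster Dice between two equal-length label vectors over the
# same voxels, after matching `labels` to `ref` by the permutation that
# maximizes the total Dice (exact search; k is small).
matched_dice <- function(ref, labels, k) {
  dmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ai <- which(ref == i); bj <- which(labels == j)
    dmat[i, j] <- if (length(ai) || length(bj)) {
      2 * length(intersect(ai, bj)) / (length(ai) + length(bj))
    } else 0
  }
  perms <- permutations_of(k)
  scores <- apply(perms, 1L, function(p) sum(dmat[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  list(mean_dice = max(scores) / k, perm = best)
}

#' Match cluster labels of one parcellation to a reference
#'
#' Finds the label permutation maximizing total per-cluster Dice against
#' `ref` (exact assignment over all permutations) and returns the
#' relabeled vector. Used to align labels across subjects before MPM
#' construction.
#'
#' @param ref reference integer labels (values `1..k`).
#' @param labels labels to realign (same length, values `1..k`).
#' @param k number of clusters.
#' @return relabeled integer vector.
#' @export
match_labels <- function(ref, labels, k) {
  perm <- matched_dice(ref, labels, k)$perm
  # cluster j of `labels` is matched to reference cluster i where perm[i]=j
  inv <- integer(k); inv[perm] <- seq_len(k)
  inv[labels]
}

#' Select the number of clusters by silhouette and cross-subject Dice
#'
#' For each candidate k, every subject's similarity matrix is clustered;
#' the mean within-subject silhouette and the mean across-subject-pair
#' Dice (after exact label matching to the first subject) are computed.
#' The chosen k maximizes the sum of the ranks of the two criteria
#' (ties resolved toward the smaller k). A selection whose reproducibility
#' is near chance is flagged unstable.
#'
#' @param sims list (one per subject) of seed-voxel similarity matrices on
#'   a common seed-voxel ordering.
#' @param k_range candidate cluster numbers (integers >= 2).
#' @param rng_seed integer seed driving the k-means restarts.
#' @return the selected k (integer) with attributes `table` (k, mean
#'   silhouette, mean Dice), `stable` (logical), and `labels` (per-subject
#'   matched label vectors at the selected k).
#' @export
select_k <- function(sims, k_range = 2:5, rng_seed = 1L) {
  if (length(sims) < 2L) stop("need at least 2 subjects")
  k_range <- sort(as.integer(k_range))
  if (!length(k_range)) stop("empty k_range")
  if (any(k_range < 2L) || any(k_range > nrow(sims[[1]])))
    stop("k_range must lie within [2, seed-voxel count]")
  ns <- length(sims)
  mean_sil <- mean_dice <- numeric(length(k_range))
  labels_at_k <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    labs <- lapply(seq_len(ns), function(s)
      spectral_cluster(sims[[s]], k, rng_seed = derive_seed(rng_seed, s, k)))
    mean_sil[ki] <- mean(vapply(seq_len(ns), function(s)
      silhouette_value(sims[[s]], labs[[s]]), numeric(1)))
    labs <- c(labs[1], lapply(labs[-1], match_labels, ref = labs[[1]], k = k))
    pair_d <- c()
    for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
      pair_d <- c(pair_d, matched_dice(labs[[i]], labs[[j]], k)$mean_dice)
    }
    mean_dice[ki] <- mean(pair_d)
    labels_at_k[[ki]] <- labs
  }
  score <- rank(mean_sil, ties.method = "average") +
    rank(mean_dice, ties.method = "average")
  best <- which(score == max(score))[1L]  # ties -> smaller k (sorted range)
  out <- k_range[best]
  attr(out, "table") <- data.frame(k = k_range, mean_silhouette = mean_sil,
                                   mean_dice = mean_dice, score = score)
  # chance-level mean matched Dice for balanced random labels is ~ 1/k
  attr(out, "stable") <- mean_dice[best] >= 1 / out + 0.25
  attr(out, "labels") <- labels_at_k[[best]]
  out
}

#' Group maximum probability map (MPM)
#'
#' Each seed voxel's per-label probability is the fraction of subjects
#' assigning it that label (labels must already be matched across
#' subjects). The winning label is the argmax; exact ties go to the label
#' with the higher mean probability over the voxel's immediately adjacent
#' in-mask voxels (6-connectivity by default), and any remaining tie to
#' the lowest label index.
#'
#' @param labels_list per-subject integer label vectors over the same
#'   ordered seed voxels.
#' @param seed_voxels `n x 3` matrix of the seed voxel index triples.
#' @param grid the common `voxel_grid`.
#' @param k number of clusters.
#' @param connectivity neighborhood for the tie-break (default 6).
#' @return list with `labels` (a `label_volume`: MPM labels inside the
#'   seed, 0 outside), `winning_prob` (numeric vector per seed voxel,
#'   always >= 1/k), `prob` (n x k matrix), `seed_voxels`.
#' @export
group_mpm <- function(labels_list, seed_voxels, grid, k, connectivity = 6) {
  ns <- length(labels_list)
  n <- nrow(seed_voxels)
  if (any(vapply(labels_list, length, integer(1)) != n))
    stop("all parcellations must cover the same seed voxels")
  if (any(vapply(labels_list, max, integer(1)) > k))
    stop("labels exceed k")
  prob <- matrix(0, n, k)
  for (lab in labels_list)
    prob[cbind(seq_len(n), lab)] <- prob[cbind(seq_len(n), lab)] + 1
  prob <- prob / ns
  d <- grid$shape
  seed_lin <- lin_index(seed_voxels[, 1], seed_voxels[, 2], seed_voxels[, 3], d)
  pos_of <- integer(prod(d)); pos_of[seed_lin] <- seq_len(n)
  offs <- conn_offsets(as.integer(connectivity))
  winner <- integer(n)
  for (i in seq_len(n)) {
    p <- prob[i, ]
    top <- which(p == max(p))
    if (length(top) > 1L) {
      nb <- sweep(offs, 2L, seed_voxels[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbpos <- pos_of[lin_index(nb[ok, 1], nb[ok, 2], nb[ok, 3], d)]
      nbpos <- nbpos[nbpos > 0]
      if (length(nbpos)) {
        nbp <- colMeans(prob[nbpos, top, drop = FALSE])
        top <- top[nbp == max(nbp)]
      }
    }
    winner[i] <- min(top)   # deterministic final tie-break
  }
  arr <- integer(prod(d)); arr[seed_lin] <- winner
  list(labels = label_volume(array(arr, d), grid),
       winning_prob = prob[cbind(seq_len(n), winner)],
       prob = prob, seed_voxels = seed_voxels)
}
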