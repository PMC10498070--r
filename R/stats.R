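#' @title Statistical kernel
#' @description Exact Mann-Whitney rank-sum test, pooled two-sample t test,
#'   Pearson/Spearman correlation tests, Fisher's z transformation, and a
#'   Shapiro-Wilk normality screen. These are the group-comparison and
#'   correlation tools used throughout the behavior and connectivity modules.
#' @name stats_kernel
NULL

amyg_test <- function(statistic, p, method, n1 = NA_integer_,
                      n2 = NA_integer_, n_pairs = NA_integer_,
                      df = NA_integer_, note = NULL) {
  structure(list(statistic = statistic, p_two_tailed = p, method = method,
                 n1 = n1, n2 = n2, n_pairs = n_pairs, df = df,
                 note = note),
            class = "amyg_test")
}

#' @export
print.amyg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p (two-tailed) = %.4g", x$method,
              x$statistic, x$p_two_tailed))
  if (!is.na(x$df)) cat(sprintf(", df = %d", x$df))
  if (!is.na(x$n1)) cat(sprintf(", n = %d vs %d", x$n1, x$n2))
  if (!is.na(x$n_pairs)) cat(sprintf(", n = %d", x$n_pairs))
  cat("\n")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.amyg_test <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             p_two_tailed = x$p_two_tailed, df = x$df,
             n1 = x$n1, n2 = x$n2, n_pairs = x$n_pairs,
             stringsAsFactors = FALSE)
}

# Null counts of the Mann-Whitney U statistic for group sizes (n1, n2),
# without ties: counts[u + 1] = number of arrangements with U = u, built by
# the standard generating-function recursion
#   N(u; i, j) = N(u - j; i - 1, j) + N(u; i, j - 1),
# dynamic program over i = 0..n1, j = 0..n2. Counts are doubles (exact below
# 2^53, far above desk-scale group sizes).
rank_sum_counts <- function(n1, n2) {
  maxu <- n1 * n2
  # dp[[j]] = counts for group sizes (i, j) as i advances
  dp <- vector("list", n2 + 1L)
  for (j in 0:n2) { v <- rep(0, maxu + 1L); v[1L] <- 1; dp[[j + 1L]] <- v }
  for (i in seq_len(n1)) {
    newdp <- vector("list", n2 + 1L)
    v <- rep(0, maxu + 1L); v[1L] <- 1
    newdp[[1L]] <- v # j = 0
    for (j in seq_len(n2)) {
      a <- dp[[j + 1L]]            # N(u; i-1, j) -> shift by j
      shifted <- c(rep(0, j), a[seq_len(maxu + 1L - j)])
      newdp[[j + 1L]] <- shifted + newdp[[j]]
    }
    dp <- newdp
  }
  dp[[n2 + 1L]]
}

#' Exact two-tailed Mann-Whitney rank-sum p-value
#'
#' Computes the exact null distribution of the Mann-Whitney U statistic for
#' two groups of sizes `n1`, `n2` (no ties) by the count-generating
#' recursion, and returns `p = min(1, 2 * P(U <= min(u, n1*n2 - u)))`. The
#' result is symmetric in `u` about `n1*n2/2`.
#'
#' @param u observed U statistic, integer in `[0, n1*n2]`.
#' @param n1,n2 group sizes (positive integers).
#' @return an `amyg_test` with method `"rank-sum (exact)"`.
#' @export
exact_rank_sum_p <- function(u, n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 1L || n2 < 1L)
    stop("group sizes must be positive")
  if (u < 0 || u > n1 * n2 || u != round(u))
    stop("u must be an integer in [0, n1*n2]")
  counts <- rank_sum_counts(n1, n2)
  total <- sum(counts)
  ult <- min(u, n1 * n2 - u)
  p <- min(1, 2 * sum(counts[seq_len(ult + 1L)]) / total)
  amyg_test(statistic = u, p = p, method = "rank-sum (exact)",
            n1 = n1, n2 = n2)
}

#' Mann-Whitney rank-sum test from raw samples
#'
#' Computes U from the ranks of the pooled sample. Without ties the exact
#' null distribution is used ([exact_rank_sum_p()]); with ties the normal
#' approximation with tie correction is used and the result is flagged.
#'
#' @param x,y numeric samples for the two groups.
#' @return an `amyg_test`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("group sizes must be positive")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties) {
    res <- exact_rank_sum_p(u, n1, n2)
    res$statistic <- u
    return(res)
  }
  # normal approximation with tie correction
  nt <- table(pooled)
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  z <- (u - mu) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  amyg_test(statistic = u, p = p,
            method = "rank-sum (normal approx., tie-corrected)",
            n1 = n1, n2 = n2, note = "ties present; exact null not used")
}

#' Two-tailed p-value for a pooled-variance (Student) t statistic
#'
#' @param t observed t statistic.
#' @param n1,n2 group sizes (each >= 2); `df = n1 + n2 - 2`.
#' @return an `amyg_test` with method `"pooled t"`.
#' @export
pooled_t_p <- function(t, n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 2L || n2 < 2L)
    stop("group sizes must be >= 2")
  df <- n1 + n2 - 2L
  amyg_test(statistic = t, p = 2 * stats::pt(-abs(t), df),
            method = "pooled t", n1 = n1, n2 = n2, df = df)
}

#' Pooled-variance two-sample t test from raw samples
#'
#' @param x,y numeric samples (each of length >= 2). The statistic is
#'   `(mean(x) - mean(y)) / (sp * sqrt(1/n1 + 1/n2))` with the pooled
#'   standard deviation `sp`.
#' @return an `amyg_test`.
#' @export
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pooled_t_p(t, n1, n2)
}

#' Correlation test (Pearson or Spearman) via the t transform
#'
#' Computes r (or the rank correlation) and the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return an `amyg_test` carrying r as the statistic.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: correlation undefined")
  r <- stats::cor(x, y, method = method)
  correlation_p(r, n, method)
}

#' Two-tailed p-value for a given correlation coefficient
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of pairs (>= 3).
#' @param method tag recorded in the result (`"pearson"` or `"spearman"`).
#' @return an `amyg_test` with `df = n - 2`.
#' @export
correlation_p <- function(r, n, method = "pearson") {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("need n >= 3")
  if (abs(r) > 1) stop("r must lie in [-1, 1]")
  df <- n - 2L
  if (abs(r) == 1) {
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    if (p == 0) p <- .Machine$double.xmin
  }
  amyg_test(statistic = r, p = p,
            method = paste0(method, " correlation"), n_pairs = n, df = df)
}

#' Fisher's z (variance-stabilizing) transformation
#'
#' `z = atanh(r)`. Values with `|r| >= 1` (e.g. a seed voxel correlated with
#' itself) are clipped to `1 - 1e-7` in magnitude before the transform; the
#' returned vector carries a logical `"clipped"` attribute marking them.
#'
#' @param r numeric vector of correlations.
#' @param clip clipping margin (default `1e-7`).
#' @return numeric vector of z values with attribute `clipped`.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  clipped <- abs(r) >= 1 - clip
  r2 <- pmin(pmax(r, -(1 - clip)), 1 - clip)
  z <- atanh(r2)
  attr(z, "clipped") <- clipped
  z
}

#' Shapiro-Wilk normality screen
#'
#' @param x numeric vector, `3 <= length(x) <= 5000`.
#' @param alpha significance level (default .05).
#' @return `TRUE` iff the Shapiro-Wilk p-value is >= `alpha` (i.e. the
#'   sample is treated as consistent with normality).
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) return(FALSE) # degenerate: not screened as normal
  stats::shapiro.test(x)$p.value >= alpha
}
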