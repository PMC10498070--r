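#' Derive a child random seed from a parent seed
#'
#' Deterministic seed splitting used so that every subject and pipeline stage
#' receives its own reproducible stream. Uses a Lehmer step
#' `s <- (48271 * s + index) mod (2^31 - 1)` applied once per supplied index;
#' all arithmetic is exact in doubles (products stay below 2^53).
#'
#' @param seed parent seed (non-negative integer).
#' @param ... one or more non-negative integer indices (subject number,
#'   stage code, replicate, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (ix in c(...)) {
    s <- (48271 * (s + as.numeric(ix) + 1)) %% m
  }
  as.integer(if (s < 1) s + 1 else s)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# All k! permutations of 1..k as a matrix (k! rows); k is small here (<= 8).
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
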