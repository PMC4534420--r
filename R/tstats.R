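#' One-tailed paired t-statistic of an ASL difference vector
#'
#' For differences `d_1..d_n` the statistic is `t = u * sqrt(n) / sd`
#' with `u` the sample mean and `sd` the sample standard deviation
#' (n - 1 denominator); the one-sided p-value is the upper tail of the
#' t-distribution with n - 1 degrees of freedom (testing whether the
#' control signal exceeds the label signal, i.e. a positive ASL
#' effect).  Degenerate zero-variance vectors are given sentinel
#' t-values: `+Inf` (p = 0) when `u > 0`, `0` (p = 0.5) when `u = 0`,
#' `-Inf` (p = 1) when `u < 0`, the limiting behavior of the test.
#'
#' @param diffs Numeric vector of control - label differences, length
#'   at least 2.
#' @return A list of class `t_stat` with `t`, `u`, `sd`, `n`, `p`.
#' @examples
#' paired_t(c(2, 3))        # t = 5
#' paired_t(c(1, -1))       # t = 0, p = 0.5
#' @export
paired_t <- function(diffs) {
  if (length(diffs) < 2)
    stop("insufficient data: paired t-test needs at least 2 pairs",
         call. = FALSE)
  if (any(!is.finite(diffs)))
    stop("differences must be finite", call. = FALSE)
  n <- length(diffs)
  u <- mean(diffs)
  s <- sd(diffs)
  if (s == 0) {
    t <- if (u > 0) Inf else if (u < 0) -Inf else 0
  } else {
    t <- u * sqrt(n) / s
  }
  p <- pt(t, df = n - 1, lower.tail = FALSE)
  structure(list(t = t, u = u, sd = s, n = n, p = p), class = "t_stat")
}

# Cumulative-prefix t statistics for a (n_voxels x n_pairs) difference
# matrix, evaluated at the NSA values in grid.  Running sums give linear
# cost in n_pairs per voxel.  Returns matrices (n_voxels x length(grid)).
prefix_t_engine <- function(dm, grid) {
  nv <- nrow(dm); np <- ncol(dm)
  s1 <- t(apply(dm, 1L, cumsum))
  s2 <- t(apply(dm * dm, 1L, cumsum))
  if (np == 1L) { s1 <- matrix(s1, nv, np); s2 <- matrix(s2, nv, np) }
  s1 <- s1[, grid, drop = FALSE]
  s2 <- s2[, grid, drop = FALSE]
  k <- matrix(grid, nv, length(grid), byrow = TRUE)
  u <- s1 / k
  # sample variance with n-1 denominator; clamp tiny negative rounding
  v <- pmax(0, (s2 - s1 * s1 / k) / (k - 1))
  s <- sqrt(v)
  tt <- u * sqrt(k) / s
  zero <- s == 0
  tt[zero & u > 0] <- Inf
  tt[zero & u < 0] <- -Inf
  tt[zero & u == 0] <- 0
  p <- pt(tt, df = k - 1, lower.tail = FALSE)
  list(t = tt, u = u, sd = s, p = p)
}

#' Cumulative t-statistics over a grid of signal averages
#'
#' Evaluates, per voxel, the one-tailed paired t-statistic on the first
#' `k` difference pairs for every `k` in `nsa_grid` (cumulative
#' prefixes of the difference time series), using running sums so the
#' total cost is linear in the number of pairs per voxel.
#'
#' @param diff A `diff_series`, or a numeric matrix with one row per
#'   voxel and one column per pair.
#' @param nsa_grid Strictly increasing integer NSA values in
#'   `[2, n_pairs]`; default every pair from 2 to `n_pairs`.
#' @param mask Optional logical/0-1 3D array restricting voxels (only
#'   for `diff_series` input); voxel order in the result follows
#'   `which(mask)`.
#' @return An object of class `t_curve_set`: list with `nsa_grid`,
#'   matrices `t`, `u`, `sd`, `p` (voxels x grid points), `voxels`
#'   (linear indices into the volume, or row numbers for matrix input),
#'   `shape`, and the `protocol` when known.
#' @examples
#' m <- matrix(rnorm(20), 2, 10)
#' tc <- t_curves(m, nsa_grid = c(2, 5, 10))
#' dim(tc$t)
#' @export
t_curves <- function(diff, nsa_grid = NULL, mask = NULL) {
  if (inherits(diff, "diff_series")) {
    np <- n_pairs(diff)
    shape <- dim(diff$data)[1:3]
    dm <- diff_matrix(diff, mask)
    voxels <- if (is.null(mask)) seq_len(prod(shape))
              else mask_indices(mask, shape)
    protocol <- diff$protocol
  } else {
    dm <- as.matrix(diff)
    np <- ncol(dm)
    shape <- NULL
    voxels <- seq_len(nrow(dm))
    protocol <- NULL
  }
  if (is.null(nsa_grid)) nsa_grid <- seq(2L, np)
  nsa_grid <- as.integer(nsa_grid)
  if (length(nsa_grid) == 0 || any(base::diff(nsa_grid) <= 0))
    stop("'nsa_grid' must be strictly increasing", call. = FALSE)
  if (nsa_grid[1] < 2 || nsa_grid[length(nsa_grid)] > np)
    stop("'nsa_grid' values must lie in [2, n_pairs]", call. = FALSE)
  eng <- prefix_t_engine(dm, nsa_grid)
  structure(list(nsa_grid = nsa_grid, t = eng$t, u = eng$u, sd = eng$sd,
                 p = eng$p, voxels = voxels, shape = shape,
                 protocol = protocol),
            class = "t_curve_set")
}

#' @export
print.t_curve_set <- function(x, ...) {
  cat(sprintf("t_curve_set: %d voxels, NSA grid %d..%d (%d points)\n",
              nrow(x$t), x$nsa_grid[1], x$nsa_grid[length(x$nsa_grid)],
              length(x$nsa_grid)))
  invisible(x)
}

#' t-statistic from population moments
#'
#' The t-score implied by a known mean difference and difference
#' standard deviation at `n` averages: `t = u * sqrt(n) / sd`.  Doubles
#' exactly when `n` quadruples — the square-root-of-N law governing how
#' averaging buys significance.
#'
#' @param u Mean difference (signal units).
#' @param sd Standard deviation of the differences; positive.
#' @param n Number of pairs; vectorized.
#' @return Numeric t-value(s).
#' @export
t_from_moments <- function(u, sd, n) {
  if (any(sd <= 0)) stop("'sd' must be positive", call. = FALSE)
  u * sqrt(n) / sd
}
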