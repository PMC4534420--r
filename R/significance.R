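#' Fraction of voxels with significant ASL signal at each NSA
#'
#' At each NSA grid value, counts the voxels whose one-sided p-value
#' falls below the working threshold: `alpha` uncorrected, or
#' `alpha / m` under Bonferroni correction with `m` the number of
#' voxels in the test family (the analyzed mask).
#'
#' @param curves A [t_curves()] result.
#' @param alpha Significance level in (0, 1); default 0.05 (the 95%
#'   level).
#' @param correction `"none"` or `"bonferroni"`.
#' @param voxels Optional subset of rows of `curves` to analyze
#'   (logical or integer index into the curve set's voxels), e.g. a
#'   sub-mask; default all.  The Bonferroni family size is the subset
#'   size.
#' @return A data.frame of class `significance_curve` with columns
#'   `nsa`, `minutes` (NA if the protocol is unknown), `fraction`,
#'   `alpha`, `correction`, `m`.
#' @examples
#' m <- matrix(rnorm(4000, mean = 0.5), 10, 400)
#' sc <- significant_fraction(t_curves(m, c(10, 100, 400)))
#' sc$fraction
#' @export
significant_fraction <- function(curves, alpha = 0.05,
                                 correction = c("none", "bonferroni"),
                                 voxels = NULL) {
  stopifnot(inherits(curves, "t_curve_set"))
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)",
                                     call. = FALSE)
  p <- subset_rows(curves$p, voxels)
  m <- nrow(p)
  if (m == 0) stop("empty voxel set", call. = FALSE)
  thr <- if (correction == "bonferroni") alpha / m else alpha
  frac <- colMeans(p < thr)
  mins <- if (!is.null(curves$protocol))
    nsa_to_minutes(curves$nsa_grid, curves$protocol) else NA_real_
  out <- data.frame(nsa = curves$nsa_grid, minutes = mins,
                    fraction = unname(frac), alpha = alpha,
                    correction = correction, m = m)
  class(out) <- c("significance_curve", "data.frame")
  out
}

subset_rows <- function(mat, voxels) {
  if (is.null(voxels)) return(mat)
  mat[voxels, , drop = FALSE]
}

#' Time (NSA and minutes) to reach significance per voxel
#'
#' The smallest NSA grid value at which a voxel's one-sided p-value
#' first crosses the working threshold (first crossing, not sustained
#' significance).  Voxels that never qualify get `NA`.
#'
#' @inheritParams significant_fraction
#' @return A data.frame with one row per voxel: `voxel` (linear index
#'   into the volume grid, or row number), `nsa` (first significant
#'   NSA, NA if never), `minutes` (scan time at that NSA, NA if never
#'   or protocol unknown).
#' @export
time_to_significance <- function(curves, alpha = 0.05,
                                 correction = c("none", "bonferroni"),
                                 voxels = NULL) {
  stopifnot(inherits(curves, "t_curve_set"))
  correction <- match.arg(correction)
  p <- subset_rows(curves$p, voxels)
  vox <- if (is.null(voxels)) curves$voxels else curves$voxels[voxels]
  m <- nrow(p)
  if (m == 0) stop("empty voxel set", call. = FALSE)
  thr <- if (correction == "bonferroni") alpha / m else alpha
  sig <- p < thr
  first <- apply(sig, 1L, function(row) {
    w <- which(row)
    if (length(w)) w[1] else NA_integer_
  })
  nsa <- curves$nsa_grid[first]
  mins <- if (!is.null(curves$protocol)) {
    out <- rep(NA_real_, m)
    ok <- !is.na(nsa)
    out[ok] <- nsa_to_minutes(nsa[ok], curves$protocol)
    out
  } else rep(NA_real_, m)
  data.frame(voxel = vox, nsa = nsa, minutes = mins)
}

#' Identify non-responder voxels
#'
#' Non-responders are voxels with no detectable ASL effect regardless
#' of averaging, operationalized as a t-value strictly below zero at
#' every NSA grid value.
#'
#' @inheritParams significant_fraction
#' @return Integer vector of voxel indices (linear indices into the
#'   volume grid, or row numbers for matrix input) of non-responders.
#' @export
find_nonresponders <- function(curves, voxels = NULL) {
  stopifnot(inherits(curves, "t_curve_set"))
  tt <- subset_rows(curves$t, voxels)
  vox <- if (is.null(voxels)) curves$voxels else curves$voxels[voxels]
  vox[rowSums(tt < 0) == ncol(tt)]
}

#' Rebuild a 3D map from per-voxel values
#'
#' Utility to place per-voxel results (e.g. time-to-significance) back
#' onto the volume grid.
#'
#' @param values Numeric vector, one value per voxel index.
#' @param voxels Linear indices into the grid.
#' @param shape Voxel counts of the grid.
#' @param fill Value for voxels outside the set (default `NA`).
#' @return A 3D array.
#' @export
map_to_volume <- function(values, voxels, shape, fill = NA_real_) {
  vol <- array(fill, dim = shape)
  vol[voxels] <- values
  vol
}
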