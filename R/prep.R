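#' Split an interleaved series and form the ASL difference time series
#'
#' Separates an interleaved label/control acquisition into its two
#' sub-series and subtracts voxel-wise, control minus label, so that a
#' positive ASL effect produces positive differences (and hence
#' positive t-values downstream).  Pair `i` is formed from adjacent
#' volumes `2i - 1` and `2i` under the declared ordering; no surround
#' or sinc-interpolated subtraction is applied.
#'
#' @param series An `asl_series` (from [simulate_series()] or
#'   [read_asl_series()]), or a bare 4D array with an even number of
#'   volumes.
#' @param order Interleaving of the input, `"label-first"` or
#'   `"control-first"`.  Defaults to the ordering recorded on the
#'   series, else label-first.
#' @return An object of class `diff_series`: list with `data` (4D array
#'   `[x, y, z, n_pairs]` of control - label differences), `protocol`
#'   (if known) and `voxel_size`.
#' @examples
#' a <- array(0, c(1, 1, 1, 4))
#' a[1, 1, 1, ] <- c(1, 3, 2, 5)  # label, control, label, control
#' split_and_subtract(a)$data[1, 1, 1, ]  # 2 3
#' @export
split_and_subtract <- function(series, order = NULL) {
  if (inherits(series, "asl_series")) {
    if (is.null(order)) order <- series$order
    protocol <- series$protocol
    voxel_size <- series$voxel_size
    data <- series$data
  } else {
    if (is.null(order)) order <- "label-first"
    protocol <- NULL
    voxel_size <- NULL
    data <- series
  }
  order <- match.arg(order, c("label-first", "control-first"))
  if (length(dim(data)) != 4)
    stop("input series must be a 4D volume", call. = FALSE)
  nvol <- dim(data)[4]
  if (nvol %% 2 != 0)
    stop("malformed series: odd number of volumes (", nvol,
         "); label/control pairs require an even count", call. = FALSE)
  first <- data[, , , seq(1L, nvol, by = 2L), drop = FALSE]
  second <- data[, , , seq(2L, nvol, by = 2L), drop = FALSE]
  diffs <- if (order == "label-first") second - first else first - second
  structure(list(data = diffs, protocol = protocol,
                 voxel_size = voxel_size),
            class = "diff_series")
}

#' @export
print.diff_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("diff_series %dx%dx%d, %d pairs\n", d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Number of label/control pairs in a difference series
#' @param diff A `diff_series`.
#' @return Integer pair count.
#' @export
n_pairs <- function(diff) {
  stopifnot(inherits(diff, "diff_series"))
  dim(diff$data)[4]
}

# Extract the (n_voxels x n_pairs) difference matrix for masked voxels.
# mask: logical/0-1 3D array on the series grid, or NULL for all voxels.
diff_matrix <- function(diff, mask = NULL) {
  stopifnot(inherits(diff, "diff_series"))
  d <- dim(diff$data)
  m <- matrix(diff$data, prod(d[1:3]), d[4])
  if (is.null(mask)) return(m)
  idx <- mask_indices(mask, d[1:3])
  m[idx, , drop = FALSE]
}

mask_indices <- function(mask, shape) {
  if (!identical(as.integer(dim(mask)), as.integer(shape)))
    stop("mask grid does not match series grid", call. = FALSE)
  which(as.logical(mask))
}
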