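#' Neighborhood offsets for a connectivity scheme
#'
#' @param connectivity `26` (all 3D neighbors including diagonals,
#'   the default reading of "one voxel outwards in all directions"),
#'   `6` (face neighbors only), or `"2d8"` (in-plane 8-connectivity,
#'   for thick-slice acquisitions where through-plane adjacency is
#'   questionable).
#' @return Integer matrix with columns dx, dy, dz, one row per
#'   neighbor.
#' @export
neighborhood_offsets <- function(connectivity = 26) {
  conn <- as.character(connectivity)
  offs <- switch(conn,
    "26" = expand.grid(dx = -1:1, dy = -1:1, dz = -1:1),
    "6" = data.frame(dx = c(-1, 1, 0, 0, 0, 0),
                     dy = c(0, 0, -1, 1, 0, 0),
                     dz = c(0, 0, 0, 0, -1, 1)),
    "2d8" = expand.grid(dx = -1:1, dy = -1:1, dz = 0),
    stop("unknown connectivity: ", conn, call. = FALSE))
  offs <- as.matrix(offs)
  offs[rowSums(offs != 0) > 0, , drop = FALSE]
}

# Shift a 3D logical array by (dx, dy, dz), padding with FALSE.
shift_mask <- function(mask, dx, dy, dz) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) == 0 || length(sy) == 0 || length(sz) == 0) return(out)
  out[sx, sy, sz] <- mask[sx - dx, sy - dy, sz - dz]
  out
}

#' Binary dilation of a 3D mask
#'
#' Expands the mask by one voxel under the given connectivity (the
#' original voxels are retained).
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param connectivity See [neighborhood_offsets()].
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, connectivity = 26) {
  mask <- array(as.logical(mask), dim = dim(mask))
  out <- mask
  offs <- neighborhood_offsets(connectivity)
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(mask, offs[i, 1], offs[i, 2], offs[i, 3])
  out
}

#' Voxels of one mask adjacent to another
#'
#' Returns the voxels of `mask` that have at least one neighbor (under
#' the given connectivity) inside `other` — e.g. the WM voxels
#' directly bordering GM.
#'
#' @param mask,other Logical 3D arrays on the same grid.
#' @param connectivity See [neighborhood_offsets()].
#' @return Logical 3D array, a subset of `mask`.
#' @export
border_voxels <- function(mask, other, connectivity = 26) {
  stopifnot(identical(dim(mask), dim(other)))
  mask <- array(as.logical(mask), dim = dim(mask))
  other <- array(as.logical(other), dim = dim(other))
  # strict neighbor union: a voxel does not border itself
  near <- array(FALSE, dim = dim(other))
  offs <- neighborhood_offsets(connectivity)
  for (i in seq_len(nrow(offs)))
    near <- near | shift_mask(other, offs[i, 1], offs[i, 2], offs[i, 3])
  mask & near
}

# Fill enclosed holes of a 3D mask: flood the complement from the
# boundary (6-connectivity) and declare unreached complement voxels
# interior.  With per_slice = TRUE (the default, appropriate for
# partial-brain slabs where structures run through the whole slice
# stack) each slice is filled independently, flooding only from its
# in-plane border.
fill_holes <- function(mask, per_slice = TRUE) {
  mask <- array(as.logical(mask), dim = dim(mask))
  d <- dim(mask)
  comp <- !mask
  seed <- array(FALSE, dim = d)
  seed[c(1, d[1]), , ] <- TRUE
  seed[, c(1, d[2]), ] <- TRUE
  if (!per_slice) seed[, , c(1, d[3])] <- TRUE
  seed <- seed & comp
  conn <- if (per_slice) "2d4" else 6
  repeat {
    grown <- flood_step(seed, conn) & comp
    if (sum(grown) == sum(seed)) break
    seed <- grown
  }
  mask | (comp & !seed)
}

# one dilation step for the flood fill (supports in-plane 4-conn)
flood_step <- function(mask, conn) {
  if (identical(conn, "2d4")) {
    out <- mask
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0)))
      out <- out | shift_mask(mask, o[1], o[2], o[3])
    out
  } else dilate_mask(mask, conn)
}
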