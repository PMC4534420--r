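#' Segmentation settings for SIR-based white-matter masking
#'
#' Intensity cut-offs are expressed as fractions of the robust maximum
#' of the SIR volume (its 99th intensity percentile), exploiting the
#' SIR contrast: GM strongly suppressed, WM very bright, partial-volume
#' voxels intermediate, ventricular CSF darkest within the brain.
#'
#' @param wm_threshold Voxels at or above this fraction are WM.
#' @param mixed_exclusion Voxels between this fraction and
#'   `wm_threshold` are partial-volume (mixed) and excluded from both
#'   WM and GM.
#' @param gm_low Lower intensity bound of brain tissue; below it (but
#'   inside the brain) lies ventricular CSF.
#' @param ventricle_threshold Upper intensity bound of ventricle
#'   voxels.
#' @param connectivity Neighborhood used for dilation/adjacency; see
#'   [neighborhood_offsets()].
#' @return A list of class `mask_config`.
#' @export
mask_config <- function(wm_threshold = 0.8, mixed_exclusion = 0.25,
                        gm_low = 0.05, ventricle_threshold = 0.05,
                        connectivity = 26) {
  if (wm_threshold <= 0 || wm_threshold >= 1 ||
      mixed_exclusion <= 0 || mixed_exclusion >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (wm_threshold <= mixed_exclusion)
    stop("'wm_threshold' must exceed 'mixed_exclusion'", call. = FALSE)
  structure(list(wm_threshold = wm_threshold,
                 mixed_exclusion = mixed_exclusion,
                 gm_low = gm_low,
                 ventricle_threshold = ventricle_threshold,
                 connectivity = connectivity),
            class = "mask_config")
}

sir_data <- function(sir) {
  if (inherits(sir, "sir_volume")) sir$data else sir
}

robust_max <- function(x) as.numeric(quantile(x, 0.99, names = FALSE))

#' Segment white matter from a SIR volume
#'
#' Thresholds the single-inversion-recovery volume: voxels at or above
#' `wm_threshold` x robust-max are WM; intermediate-intensity voxels
#' are partial-volume and excluded; GM, CSF and background fall below.
#'
#' @param sir A `sir_volume` or bare 3D array.
#' @param config A [mask_config()].
#' @return Logical 3D array (warns if empty).
#' @export
segment_wm <- function(sir, config = mask_config()) {
  x <- sir_data(sir)
  rmax <- robust_max(x)
  wm <- if (rmax <= 0) array(FALSE, dim = dim(x))
        else x >= config$wm_threshold * rmax
  if (!any(wm)) warning("empty WM mask")
  wm
}

#' Segment gray matter from a SIR volume
#'
#' GM is the suppressed band: intensities between `gm_low` and
#' `mixed_exclusion` fractions of the robust maximum (above ventricular
#' CSF, below partial-volume voxels).
#'
#' @inheritParams segment_wm
#' @return Logical 3D array.
#' @export
segment_gm <- function(sir, config = mask_config()) {
  x <- sir_data(sir)
  rmax <- robust_max(x)
  x >= config$gm_low * rmax & x < config$mixed_exclusion * rmax
}

#' Periventricular white-matter mask
#'
#' Identifies the ventricles as sub-threshold voxels enclosed within
#' the brain (holes of the brain-tissue mask, or an externally
#' supplied ventricle mask), expands them one voxel outwards in all
#' directions of the configured neighborhood, and intersects with the
#' WM mask.
#'
#' @inheritParams segment_wm
#' @param full_wm Logical WM mask on the same grid (from
#'   [segment_wm()]).
#' @param ventricles Optional externally supplied logical ventricle
#'   mask (e.g. manually drawn); when given, thresholding is skipped.
#' @return Logical 3D array, subset of `full_wm` (warns if no
#'   ventricle is found).
#' @export
periventricular_mask <- function(sir, full_wm, config = mask_config(),
                                 ventricles = NULL) {
  x <- sir_data(sir)
  stopifnot(identical(dim(x), dim(full_wm)))
  if (is.null(ventricles)) {
    rmax <- robust_max(x)
    tissue <- x >= config$gm_low * rmax
    brain <- fill_holes(tissue)
    ventricles <- brain & !tissue & x < config$ventricle_threshold * rmax
  }
  if (!any(ventricles)) {
    warning("no ventricle voxels found; periventricular mask is empty")
    return(array(FALSE, dim = dim(x)))
  }
  dilate_mask(ventricles, config$connectivity) & as.logical(full_wm) &
    !ventricles
}

#' Peripheral white-matter mask
#'
#' All WM voxels directly bordering GM under the configured
#' neighborhood.
#'
#' @param full_wm,gm_mask Logical masks on the same grid.
#' @param config A [mask_config()].
#' @return Logical 3D array, subset of `full_wm`.
#' @export
peripheral_mask <- function(full_wm, gm_mask, config = mask_config()) {
  border_voxels(full_wm, gm_mask, config$connectivity)
}

#' Build the full white-matter mask set
#'
#' Segments WM from the SIR volume and partitions it into three
#' disjoint sub-masks: periventricular (WM within one voxel of the
#' ventricles), peripheral (WM bordering GM), and deep (all remaining
#' WM).  A voxel qualifying as both periventricular and peripheral is
#' assigned to the periventricular mask, so the three sub-masks always
#' partition the full mask.
#'
#' @inheritParams segment_wm
#' @param gm_mask Optional externally supplied GM mask; default
#'   segmented from the SIR bands.
#' @param ventricles Optional externally supplied ventricle mask.
#' @return A list of class `wm_mask_set` with logical arrays
#'   `full_wm`, `periventricular`, `peripheral`, `deep` and the
#'   `config`.
#' @examples
#' tm <- sample_tissue_map(seed = 1)
#' sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 2),
#'                        seed = 1)
#' ms <- build_masks(sim$sir)
#' sapply(ms[c("full_wm", "periventricular", "peripheral", "deep")], sum)
#' @export
build_masks <- function(sir, config = mask_config(), gm_mask = NULL,
                        ventricles = NULL) {
  full_wm <- segment_wm(sir, config)
  if (is.null(gm_mask)) gm_mask <- segment_gm(sir, config)
  pv <- periventricular_mask(sir, full_wm, config, ventricles)
  periph <- peripheral_mask(full_wm, gm_mask, config) & !pv
  deep <- full_wm & !pv & !periph
  structure(list(full_wm = full_wm, periventricular = pv,
                 peripheral = periph, deep = deep, config = config),
            class = "wm_mask_set")
}

#' @export
print.wm_mask_set <- function(x, ...) {
  cat(sprintf(
    "wm_mask_set: %d WM voxels = %d periventricular + %d peripheral + %d deep\n",
    sum(x$full_wm), sum(x$periventricular), sum(x$peripheral),
    sum(x$deep)))
  invisible(x)
}
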