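#' @importFrom stats rnorm runif median pt qt sd coef confint lm nls
#'   nls.control quantile
NULL

# Integer codes for tissue classes used throughout the phantom.
#' Tissue class codes
#'
#' Named integer codes used in the `tissue_class` array of a
#' [sample_tissue_map()] phantom: background 0, GM 1, WM 2, CSF 3,
#' mixed 4.
#' @export
TISSUE_CODES <- c(background = 0L, GM = 1L, WM = 2L, CSF = 3L, mixed = 4L)

# Run code with a private RNG stream so callers' RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Settings for the digital tissue phantom
#'
#' Distributional settings for [sample_tissue_map()].  CBF values are in
#' mL/100g/min, transit times in ms.  Defaults place WM perfusion at one
#' third of GM perfusion (within the physiological 2-4x gap) with
#' markedly longer WM transit times, and flag 6% of WM voxels as
#' non-responders, voxels with no positive ASL effect at any amount of
#' averaging.
#'
#' @param gm_cbf_mean,gm_cbf_sd GM perfusion distribution.
#' @param wm_cbf_mean,wm_cbf_sd WM perfusion distribution.
#' @param mixed_cbf_mean,mixed_cbf_sd Mixed (partial-volume) voxels.
#' @param gm_att_mean,gm_att_sd GM arterial transit time distribution.
#' @param wm_att_mean,wm_att_sd WM arterial transit times (longer).
#' @param mixed_att_mean,mixed_att_sd Mixed-voxel transit times.
#' @param nonresponder_fraction Fraction of WM voxels flagged as
#'   non-responders, in `[0, 1]`.
#' @param nonresponder_mean Mean magnitude of the (nonpositive) expected
#'   difference signal assigned to non-responders; drawn from a
#'   half-normal reflected to `<= 0`.  Default 0: no effect at all.
#' @return A list of class `tissue_config`.
#' @export
tissue_config <- function(gm_cbf_mean = 60, gm_cbf_sd = 10,
                          wm_cbf_mean = 20, wm_cbf_sd = 5,
                          mixed_cbf_mean = 40, mixed_cbf_sd = 8,
                          gm_att_mean = 1000, gm_att_sd = 150,
                          wm_att_mean = 1600, wm_att_sd = 200,
                          mixed_att_mean = 1300, mixed_att_sd = 150,
                          nonresponder_fraction = 0.06,
                          nonresponder_mean = 0) {
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1)
    stop("'nonresponder_fraction' must lie in [0, 1]", call. = FALSE)
  if (nonresponder_mean < 0)
    stop("'nonresponder_mean' must be nonnegative (magnitude)", call. = FALSE)
  cfg <- as.list(environment())
  if (cfg$wm_cbf_mean < cfg$gm_cbf_mean / 4 - 1e-9 ||
      cfg$wm_cbf_mean > cfg$gm_cbf_mean / 2 + 1e-9)
    warning("configured WM mean CBF is outside [GM/4, GM/2]; ",
            "the phantom will not honor the 2-4x WM/GM perfusion gap")
  structure(cfg, class = "tissue_config")
}

#' Sample a layered digital head phantom
#'
#' Builds a deterministic concentric-layer geometry on an 8-slice grid
#' (elliptical brain with a GM shell, WM core, a ventricle-like central
#' CSF region, and partial-volume "mixed" voxels interdigitated at the
#' GM/WM interface) and draws per-voxel ground truth: tissue class,
#' CBF, arterial transit time, a responder flag, and the (nonpositive)
#' expected difference signal of non-responder voxels.  Exactly
#' `round(nonresponder_fraction * n_WM)` WM voxels are flagged
#' `responder = FALSE`.
#'
#' @param shape Integer triple of voxel counts, default `c(32, 32, 8)`.
#' @param config A [tissue_config()].
#' @param seed Integer seed; the same seed reproduces the map exactly.
#' @param voxel_size Voxel dimensions in mm, default
#'   `c(3.75, 3.75, 5)`.
#' @return A list of class `tissue_map` with 3D arrays `tissue_class`
#'   (codes in [TISSUE_CODES]), `cbf`, `transit_time`, `responder`,
#'   `nonresp_diff`, plus `shape`, `voxel_size`, `config`, `seed`.
#' @examples
#' tm <- sample_tissue_map(seed = 1)
#' table(tm$tissue_class)
#' @export
sample_tissue_map <- function(shape = c(32L, 32L, 8L),
                              config = tissue_config(),
                              seed = 1L,
                              voxel_size = c(3.75, 3.75, 5)) {
  stopifnot(length(shape) == 3, all(shape >= 1), inherits(config,
                                                          "tissue_config"))
  shape <- as.integer(shape)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]

  ix <- array(rep(seq_len(nx), times = ny * nz), dim = shape)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = shape)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = shape)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- 0.45 * nx; ry <- 0.45 * ny
  r <- sqrt(((ix - cx) / rx)^2 + ((iy - cy) / ry)^2)

  cls <- array(TISSUE_CODES[["background"]], dim = shape)
  cls[r <= 1] <- TISSUE_CODES[["GM"]]
  cls[r <= 0.78] <- TISSUE_CODES[["WM"]]
  cls[r <= 0.20] <- TISSUE_CODES[["CSF"]]
  # partial-volume voxels interleaved along the GM/WM interface
  band <- r > 0.74 & r <= 0.82 & (ix + iy + iz) %% 2L == 0L
  cls[band] <- TISSUE_CODES[["mixed"]]

  gm <- cls == TISSUE_CODES[["GM"]]
  wm <- cls == TISSUE_CODES[["WM"]]
  mx <- cls == TISSUE_CODES[["mixed"]]

  cbf <- array(0, dim = shape)
  att <- array(0, dim = shape)
  responder <- array(TRUE, dim = shape)
  nonresp_diff <- array(0, dim = shape)

  with_seed(seed, {
    cbf[gm] <- pmax(0, rnorm(sum(gm), config$gm_cbf_mean, config$gm_cbf_sd))
    cbf[wm] <- pmax(0, rnorm(sum(wm), config$wm_cbf_mean, config$wm_cbf_sd))
    cbf[mx] <- pmax(0, rnorm(sum(mx), config$mixed_cbf_mean,
                             config$mixed_cbf_sd))
    att[gm] <- pmax(0, rnorm(sum(gm), config$gm_att_mean, config$gm_att_sd))
    att[wm] <- pmax(0, rnorm(sum(wm), config$wm_att_mean, config$wm_att_sd))
    att[mx] <- pmax(0, rnorm(sum(mx), config$mixed_att_mean,
                             config$mixed_att_sd))
    wm_idx <- which(wm)
    n_nr <- round(config$nonresponder_fraction * length(wm_idx))
    if (n_nr > 0) {
      nr_idx <- sample(wm_idx, n_nr)
      responder[nr_idx] <- FALSE
      # half-normal reflected to <= 0; mean magnitude = nonresponder_mean
      sigma <- config$nonresponder_mean * sqrt(pi / 2)
      nonresp_diff[nr_idx] <- -abs(rnorm(n_nr, 0, sigma))
    }
  })

  structure(list(tissue_class = cls, cbf = cbf, transit_time = att,
                 responder = responder, nonresp_diff = nonresp_diff,
                 shape = shape, voxel_size = voxel_size,
                 config = config, seed = as.integer(seed)),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cnt <- table(factor(x$tissue_class, levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES)))
  cat(sprintf("tissue_map %dx%dx%d (%.3gx%.3gx%.3g mm)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  print(cnt)
  wm <- x$tissue_class == TISSUE_CODES[["WM"]]
  cat(sprintf("  WM mean CBF %.1f, mean ATT %.0f ms, %d non-responders\n",
              mean(x$cbf[wm]), mean(x$transit_time[wm]),
              sum(!x$responder[wm])))
  invisible(x)
}
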