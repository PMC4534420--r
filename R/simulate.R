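#' Noise and static-signal settings for series simulation
#'
#' @param sd Standard deviation of the additive Gaussian noise applied
#'   independently to every voxel of every volume, in units of the
#'   equilibrium magnetization.  The default is calibrated so that a
#'   single-pair WM difference sits well below the noise floor (SNR of
#'   roughly 0.4 per pair) while most WM voxels reach one-sided
#'   significance within the first few dozen pairs of averaging.
#' @param static_base Residual static tissue signal surviving
#'   background suppression in the first slice, as a fraction of M0.
#' @param slice_gain Per-slice relative growth of the static residual
#'   (2D readout: suppression is best in slice 1 and decays upward), so
#'   slice z carries `static_base * (1 + slice_gain * (z - 1))`.
#' @param sir_noise_sd Noise sd of the single-inversion-recovery (SIR)
#'   volume, same units.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(sd = 0.35, static_base = 0.05, slice_gain = 0.1,
                         sir_noise_sd = 0.01) {
  if (sd < 0 || static_base < 0 || slice_gain < 0 || sir_noise_sd < 0)
    stop("noise settings must be nonnegative", call. = FALSE)
  structure(list(sd = sd, static_base = static_base,
                 slice_gain = slice_gain, sir_noise_sd = sir_noise_sd),
            class = "noise_config")
}

# SIR contrast: GM strongly suppressed, WM bright, mixed intermediate,
# CSF (long T1, inverted at TI 1800 ms) darkest within the brain.
.sir_levels <- c(background = 0, GM = 0.1, WM = 1, CSF = 0.02, mixed = 0.5)

#' Simulate an interleaved label/control ASL series and SIR volume
#'
#' Generates a 4D PCASL acquisition on the grid of a [sample_tissue_map()]
#' phantom.  Control volumes carry the slice-dependent residual static
#' signal plus Gaussian noise; label volumes carry the same static model
#' minus the expected difference signal (the kinetic model value for
#' responder voxels; the stored nonpositive value for non-responders)
#' plus an independent noise draw.  Volumes are interleaved with the
#' declared ordering (label-first by default).  The SIR volume shares
#' the grid, with GM suppressed, WM bright and mixed voxels
#' intermediate.
#'
#' @param tmap A `tissue_map`.
#' @param protocol An `asl_protocol`; `n_pairs` label/control pairs are
#'   produced.
#' @param kp A [kinetic_params()] object.
#' @param noise A [noise_config()].
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param order `"label-first"` or `"control-first"` interleaving.
#' @return A list with `series` (class `asl_series`: 4D array
#'   `[x, y, z, 2 * n_pairs]` with attributes `protocol`, `order`,
#'   `voxel_size`) and `sir` (class `sir_volume`: 3D array with
#'   `voxel_size`).
#' @examples
#' tm <- sample_tissue_map(shape = c(16, 16, 2), seed = 1)
#' sim <- simulate_series(tm, protocol_preset("exp3", n_pairs = 10),
#'                        seed = 2)
#' dim(sim$series$data)
#' @export
simulate_series <- function(tmap, protocol, kp = kinetic_params(),
                            noise = noise_config(), seed = 1L,
                            order = c("label-first", "control-first")) {
  stopifnot(inherits(tmap, "tissue_map"), inherits(protocol, "asl_protocol"),
            inherits(kp, "kinetic_params"), inherits(noise, "noise_config"))
  order <- match.arg(order)
  shape <- tmap$shape
  nvox <- prod(shape)
  np <- protocol$n_pairs

  # expected difference per voxel
  dm <- array(0, dim = shape)
  resp <- tmap$responder & tmap$cbf > 0
  dm[resp] <- kinetic_delta_m(tmap$cbf[resp], tmap$transit_time[resp],
                              protocol, kp)
  dm[!tmap$responder] <- tmap$nonresp_diff[!tmap$responder]

  zidx <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  static <- noise$static_base * kp$equilibrium_magnetization *
    (1 + noise$slice_gain * (zidx - 1))

  data <- array(0, dim = c(shape, 2L * np))
  sir <- NULL
  with_seed(seed, {
    eps <- if (noise$sd > 0)
      array(rnorm(nvox * 2 * np, 0, noise$sd), dim = c(nvox, 2L * np))
    else matrix(0, nvox, 2L * np)
    ctrl_cols <- if (order == "label-first") seq(2L, 2L * np, by = 2L)
                 else seq(1L, 2L * np, by = 2L)
    lab_cols <- setdiff(seq_len(2L * np), ctrl_cols)
    flat <- matrix(0, nvox, 2L * np)
    flat[, ctrl_cols] <- static + eps[, ctrl_cols]
    flat[, lab_cols] <- (static - as.vector(dm)) + eps[, lab_cols]
    data[] <- flat
    sir_data <- array(.sir_levels[match(tmap$tissue_class,
                                        TISSUE_CODES)] *
                        kp$equilibrium_magnetization, dim = shape)
    if (noise$sir_noise_sd > 0)
      sir_data <- sir_data + rnorm(nvox, 0, noise$sir_noise_sd)
    sir <- sir_data
  })

  series <- structure(list(data = data, protocol = protocol, order = order,
                           voxel_size = tmap$voxel_size),
                      class = "asl_series")
  sirvol <- structure(list(data = sir, voxel_size = tmap$voxel_size),
                      class = "sir_volume")
  list(series = series, sir = sirvol, expected_dm = dm)
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("asl_series %dx%dx%d, %d volumes (%d pairs, %s)\n",
              d[1], d[2], d[3], d[4], d[4] / 2, x$order))
  invisible(x)
}
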