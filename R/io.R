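#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D array, or a `sir_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm; taken from the object if
#'   present.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  if (inherits(vol, "sir_volume")) {
    if (is.null(voxel_size)) voxel_size <- vol$voxel_size
    vol <- vol$data
  }
  img <- RNifti::asNifti(vol * 1)
  if (!is.null(voxel_size)) RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#' @param path NIfTI file path.
#' @return A plain array with attribute `voxel_size`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)
  out
}

#' Write an interleaved ASL series (or difference series) as 4D NIfTI
#'
#' @param x An `asl_series` or `diff_series`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_asl_series <- function(x, path) {
  stopifnot(inherits(x, c("asl_series", "diff_series")))
  img <- RNifti::asNifti(x$data)
  if (!is.null(x$voxel_size)) RNifti::pixdim(img) <- c(x$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an interleaved ASL series from 4D NIfTI
#'
#' @param path NIfTI file path.
#' @param protocol Optional `asl_protocol` describing the acquisition.
#' @param order Interleaving, `"label-first"` (default) or
#'   `"control-first"`.
#' @return An `asl_series`.
#' @export
read_asl_series <- function(path, protocol = NULL,
                            order = c("label-first", "control-first")) {
  order <- match.arg(order)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4)
    stop("expected a 4D NIfTI volume", call. = FALSE)
  structure(list(data = data, protocol = protocol, order = order,
                 voxel_size = RNifti::pixdim(img)[1:3]),
            class = "asl_series")
}

#' Write a tissue phantom's ground truth to disk
#'
#' Writes the class, CBF, transit-time and responder volumes as NIfTI
#' plus a JSON sidecar carrying the generator configuration and seed.
#'
#' @param tmap A `tissue_map`.
#' @param prefix Output path prefix; files `<prefix>_class.nii.gz`,
#'   `_cbf.nii.gz`, `_att.nii.gz`, `_responder.nii.gz`,
#'   `_truth.json` are produced.
#' @return Character vector of the written paths, invisibly.
#' @export
write_tissue_map <- function(tmap, prefix) {
  stopifnot(inherits(tmap, "tissue_map"))
  paths <- c(
    write_volume(tmap$tissue_class, paste0(prefix, "_class.nii.gz"),
                 tmap$voxel_size),
    write_volume(tmap$cbf, paste0(prefix, "_cbf.nii.gz"),
                 tmap$voxel_size),
    write_volume(tmap$transit_time, paste0(prefix, "_att.nii.gz"),
                 tmap$voxel_size),
    write_volume(tmap$responder * 1, paste0(prefix, "_responder.nii.gz"),
                 tmap$voxel_size))
  sidecar <- paste0(prefix, "_truth.json")
  jsonlite::write_json(
    list(config = unclass(tmap$config), seed = tmap$seed,
         shape = tmap$shape, voxel_size = tmap$voxel_size,
         class_codes = as.list(TISSUE_CODES)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, sidecar))
}
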