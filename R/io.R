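# Named-array container and NIfTI export.
#
# Container layout (one RDS file holding a named list):
#   version      - format tag "tvsense-container-1"
#   image        - complex or real H x W matrix (ground truth or recon)
#   sens         - complex H x W x K sensitivity array
#   mask         - 0/1 H x W matrix
#   kspace_real, kspace_imag - real H x W x K arrays (complex data split)
#   meta         - named list of free-form metadata
# Complex k-space is split into real/imag entries so every stored array is a
# plain double array. NIfTI files carry magnitude only (identity affine,
# 1 mm isotropic pixels; no physical geometry is claimed).

CONTAINER_VERSION <- "tvsense-container-1"

#' Write an acquisition/reconstruction container
#'
#' @param path output file path (conventionally `.rds`).
#' @param image complex or real H x W matrix.
#' @param sens complex H x W x K array or [coil_sens()].
#' @param mask 0/1 H x W matrix or [sampling_mask()].
#' @param kspace complex H x W x K array or [coil_data()]; stored split into
#'   `kspace_real` / `kspace_imag`.
#' @param meta named list of metadata.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, image, sens, mask, kspace, meta = list()) {
  obj <- list(version = CONTAINER_VERSION,
              image = as.matrix(image),
              sens = unclass(sens) + 0i,
              mask = matrix(as.double(unclass(mask)), nrow(mask), ncol(mask)),
              kspace_real = Re(unclass(kspace)),
              kspace_imag = Im(unclass(kspace)),
              meta = meta)
  attributes(obj$sens) <- list(dim = dim(unclass(sens)))
  saveRDS(obj, path)
  invisible(path)
}

#' Read an acquisition/reconstruction container
#'
#' @param path file written by [write_container()].
#' @return named list with `image`, `sens` ([coil_sens()]), `mask`
#'   ([sampling_mask()]), `kspace` (complex array, real/imag entries
#'   reassembled), and `meta`.
#' @export
read_container <- function(path) {
  if (!file.exists(path))
    stop_contract("container file not found: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_contract("corrupt container %s: %s",
                                                    path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$version, CONTAINER_VERSION))
    stop_contract("unknown container version tag in %s (expected %s)",
                  path, CONTAINER_VERSION)
  for (entry in c("image", "sens", "mask", "kspace_real", "kspace_imag"))
    if (is.null(obj[[entry]]))
      stop_contract("container %s is missing required entry \"%s\"", path, entry)
  mask <- sampling_mask(obj$mask)
  list(image = obj$image,
       sens = coil_sens(obj$sens),
       mask = mask,
       kspace = coil_data(complex(real = obj$kspace_real,
                                  imaginary = obj$kspace_imag) |>
                            array(dim = dim(obj$kspace_real)), mask),
       meta = if (is.null(obj$meta)) list() else obj$meta)
}

#' Export a magnitude image as NIfTI
#'
#' @param image complex or real H x W matrix; the magnitude is stored with an
#'   identity affine and 1 mm isotropic pixels.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_magnitude_nifti <- function(image, path) {
  mag <- Mod(as.matrix(image))
  RNifti::writeNifti(RNifti::asNifti(mag), path)
  invisible(path)
}
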