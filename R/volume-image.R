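#' A 3D scalar brain image
#'
#' `volume_image()` wraps a 3D numeric array together with its voxel
#' dimensions. It is the carrier type for grey-matter volume maps, ADC maps,
#' tissue-fraction maps and binary masks throughout the package.
#'
#' @param data A 3D numeric array of voxel values.
#' @param voxel_size Numeric length-3 vector of voxel edge lengths in mm
#'   (default 2 mm isotropic).
#' @return An object of class `volume_image`: a list with elements `data`
#'   (the array) and `voxel_size`.
#' @examples
#' img <- volume_image(array(0, dim = c(4, 4, 4)))
#' voxel_volume(img)  # 8 mm^3
#' @export
volume_image <- function(data, voxel_size = c(2, 2, 2)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = voxel_size),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Volume of one voxel in mm^3
#' @param img A `volume_image`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(img) {
  stopifnot(inherits(img, "volume_image"))
  prod(img$voxel_size)
}

is_volume_image <- function(x) inherits(x, "volume_image")

# shared-grid check used by every map/mask pairing
check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("%s must share the same grid shape", what), call. = FALSE)
  }
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-8) {
    stop(sprintf("%s must share the same voxel size", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3D NIfTI image as a `volume_image`
#'
#' @param path Path to a NIfTI file (`.nii` or `.nii.gz`).
#' @return A `volume_image`; voxel size is taken from the NIfTI pixdim.
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  vs <- RNifti::pixdim(nii)[seq_len(3)]
  volume_image(arr, voxel_size = vs)
}

#' Write a `volume_image` to NIfTI
#'
#' @param img A `volume_image`.
#' @param path Output path (`.nii` or `.nii.gz`). The affine is diagonal,
#'   built from the voxel size.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(is_volume_image(img))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Spherical binary mask on a voxel grid
#'
#' Utility used by the phantom generator and handy for constructing test
#' ROIs: voxels whose centre lies within `radius` voxels of `centre` (in
#' voxel units, Euclidean) are set to 1.
#'
#' @param shape Integer length-3 grid shape.
#' @param centre Numeric length-3 sphere centre in voxel coordinates.
#' @param radius Sphere radius in voxels.
#' @return A 3D 0/1 array of dimension `shape`.
#' @export
sphere_mask <- function(shape, centre, radius) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(centre) == 3L, radius >= 0)
  d2 <- outer(
    outer((seq_len(shape[1]) - centre[1])^2, (seq_len(shape[2]) - centre[2])^2, "+"),
    (seq_len(shape[3]) - centre[3])^2, "+"
  )
  array(as.numeric(d2 <= radius^2), dim = shape)
}
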