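#' An aligned stack of 3D images with group labels
#'
#' The container for voxelwise analyses: all images share one grid and are
#' stored as a voxels-by-subjects matrix for fast permutation loops.
#'
#' @param data Either a voxels-by-subjects numeric matrix (with `shape`
#'   giving the grid), or a list of [volume_image] objects on a common grid.
#' @param shape Integer length-3 grid shape (required when `data` is a
#'   matrix).
#' @param voxel_size Voxel edge lengths in mm.
#' @param subject_id Character vector of subject identifiers.
#' @param group Group label per image (two-sample designs need two
#'   nonempty groups).
#' @param covariates Optional data frame of per-image covariates (e.g. age,
#'   sex) to be residualised out before inference.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, shape = NULL, voxel_size = c(2, 2, 2),
                        subject_id = NULL, group = NULL, covariates = NULL) {
  if (is.list(data) && !is.matrix(data)) {
    stopifnot(all(vapply(data, is_volume_image, logical(1))))
    shape <- dim(data[[1]]$data)
    voxel_size <- data[[1]]$voxel_size
    for (img in data) check_same_grid(data[[1]], img, "stack images")
    data <- vapply(data, function(img) as.vector(img$data), numeric(prod(shape)))
  }
  if (!is.matrix(data)) stop("`data` must be a matrix or list of volume_image", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 3L || prod(shape) != nrow(data)) {
    stop("`shape` must be 3 integers with prod(shape) == nrow(data)", call. = FALSE)
  }
  n <- ncol(data)
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(n))
  if (length(subject_id) != n) stop("one subject_id per image", call. = FALSE)
  if (!is.null(group) && length(group) != n) stop("one group label per image", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("one covariate row per image", call. = FALSE)
    if (anyNA(covariates)) stop("covariates must be complete", call. = FALSE)
  }
  structure(
    list(data = data, shape = shape, voxel_size = as.numeric(voxel_size),
         subject_id = as.character(subject_id),
         group = if (is.null(group)) NULL else as.character(group),
         covariates = covariates),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d images on a %s grid\n",
              ncol(x$data), paste(x$shape, collapse = " x ")))
  if (!is.null(x$group)) print(table(x$group))
  invisible(x)
}

#' Number of images in a stack
#' @param x An `image_stack`.
#' @export
n_images <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  ncol(x$data)
}

#' Extract one image of a stack as a `volume_image`
#' @param x An `image_stack`.
#' @param i Image index or subject id.
#' @export
stack_image <- function(x, i) {
  stopifnot(inherits(x, "image_stack"))
  if (is.character(i)) i <- match(i, x$subject_id)
  volume_image(array(x$data[, i], dim = x$shape), x$voxel_size)
}

#' Summarise an image stack as a tibble
#'
#' One row per image with subject id, group, covariates and simple
#' intensity summaries — convenient for joining with cohort tables.
#'
#' @param x An `image_stack`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy image_stack
#' @export
tidy.image_stack <- function(x, ...) {
  out <- tibble::tibble(
    subject_id = x$subject_id,
    group = if (is.null(x$group)) NA_character_ else x$group,
    mean_intensity = colMeans(x$data),
    sd_intensity = apply(x$data, 2, stats::sd)
  )
  if (!is.null(x$covariates)) out <- dplyr::bind_cols(out, tibble::as_tibble(x$covariates))
  out
}
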