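#' Mean grey-matter ADC within a mask
#'
#' Unweighted mean of an apparent-diffusion-coefficient map over the voxels
#' where the grey-matter mask is at or above `threshold`. ADC maps are
#' consumed in 1e-6 mm^2/s; computing ADC from diffusion-weighted signals
#' is preprocessing and out of scope.
#'
#' @param adc_map A [volume_image] of ADC values.
#' @param gm_mask A [volume_image] grey-matter fraction (or binary) mask on
#'   the same grid.
#' @param threshold Mask inclusion threshold in \[0, 1\]; default 0.5.
#' @return Scalar mean ADC over the included voxels.
#' @examples
#' adc <- volume_image(array(1004, c(8, 8, 8)))
#' gm  <- volume_image(array(0.9,  c(8, 8, 8)))
#' mean_gm_adc(adc, gm)  # 1004
#' @export
mean_gm_adc <- function(adc_map, gm_mask, threshold = 0.5) {
  stopifnot(is_volume_image(adc_map), is_volume_image(gm_mask))
  check_same_grid(adc_map, gm_mask, "ADC map and GM mask")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  keep <- gm_mask$data >= threshold
  if (!any(keep)) {
    stop("GM mask is empty after thresholding", call. = FALSE)
  }
  mean(adc_map$data[keep])
}

#' Per-subject mean grey-matter ADC table for an image stack
#'
#' Applies [mean_gm_adc()] to every image of a stack against a common GM
#' mask, returning a tidy per-subject table ready for group comparison.
#'
#' @param stack An [image_stack()] of ADC maps.
#' @param gm_mask A [volume_image] mask on the stack's grid.
#' @param threshold Mask inclusion threshold; default 0.5.
#' @return A tibble: `subject_id`, `group` (if present), `gm_adc`.
#' @export
gm_adc_table <- function(stack, gm_mask, threshold = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  vals <- vapply(seq_len(n_images(stack)), function(i) {
    mean_gm_adc(stack_image(stack, i), gm_mask, threshold)
  }, numeric(1))
  tibble::tibble(
    subject_id = stack$subject_id,
    group = if (is.null(stack$group)) NA_character_ else stack$group,
    gm_adc = vals
  )
}
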