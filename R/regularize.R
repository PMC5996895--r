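#' Regularization configuration
#'
#' @param smooth_sigma_mm Gaussian width (mm) applied to the probability map
#'   before thresholding; default 2 mm.
#' @param prob_threshold Probability cutoff in (0, 1); the default 0.25 is
#'   deliberately below 0.5 because non-lesion voxels vastly outnumber lesion
#'   voxels, biasing tree probabilities downwards.
#' @param struct_radius_vox Radius (voxels) of the cube structuring element
#'   (side `2r + 1`) used for closing then opening.
#' @return A list of class `regularize_config`.
#' @export
regularize_config <- function(smooth_sigma_mm = 2, prob_threshold = 0.25,
                              struct_radius_vox = 1L) {
  stopifnot(smooth_sigma_mm >= 0,
            prob_threshold > 0, prob_threshold < 1,
            struct_radius_vox >= 0)
  structure(list(smooth_sigma_mm = smooth_sigma_mm,
                 prob_threshold = prob_threshold,
                 struct_radius_vox = as.integer(struct_radius_vox)),
            class = "regularize_config")
}

#' Spatially regularize a probability map into a lesion mask
#'
#' Smooths the voxelwise probability map with an isotropic 3-D Gaussian
#' kernel (mask-renormalized at the brain boundary so probabilities are not
#' diluted by out-of-brain zeros), thresholds at `prob_threshold`
#' (inclusive, `>=`), then morphologically closes (fills small holes /
#' false-negative noise) and opens (removes small islands / false-positive
#' noise) with the same cube structuring element. The result is restricted
#' to the brain mask. With `smooth_sigma_mm = 0` and `struct_radius_vox = 0`
#' this reduces to plain thresholding.
#'
#' @param prob Probability `volume` (values in \[0, 1\]).
#' @param brain_mask Binary `volume` on the same grid.
#' @param cfg A [regularize_config()].
#' @return Binary `volume` (final lesion mask), a subset of the brain mask.
#' @export
regularize_map <- function(prob, brain_mask, cfg = regularize_config()) {
  stopifnot(is_volume(prob), is_volume(brain_mask),
            inherits(cfg, "regularize_config"))
  stop_if_grid_mismatch(prob, brain_mask, "prob/brain_mask")
  if (any(prob$data < -1e-9) || any(prob$data > 1 + 1e-9))
    stop("probability map must lie in [0, 1]")
  brain <- brain_mask$data > 0.5
  sm <- masked_gaussian_smooth(prob$data, cfg$smooth_sigma_mm, prob$spacing,
                               brain)
  m <- sm >= cfg$prob_threshold & brain
  if (cfg$struct_radius_vox > 0L) {
    m <- binary_close(m, cfg$struct_radius_vox)
    m <- binary_open(m, cfg$struct_radius_vox)
  }
  m <- m & brain
  vol_like(prob, array(as.numeric(m), dim(m)))
}
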