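#' Preprocessing configuration
#'
#' Parameters of the feature-map construction: the Gaussian kernel width
#' applied to the flipped image before the critical-intensity filter, the
#' neighbourhood radius of that filter, and the contralateral-side rule used
#' by slice-wise DWI normalization.
#'
#' @param smooth_sigma_mm Isotropic Gaussian sigma (mm) for the flipped
#'   image; default 2 mm.
#' @param critical_radius_vox Neighbourhood radius (voxels) of the
#'   critical-intensity filter; default 1 (a 3x3x3 cube).
#' @param contralateral_side `"left"`, `"right"` or `"auto"` (pick the
#'   hemisphere with the smaller hyperintense burden).
#' @param normalize_slicewise Normalize the DWI per axial slice (the default)
#'   rather than with a single whole-volume mean.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_sigma_mm = 2,
                              critical_radius_vox = 1L,
                              contralateral_side = c("auto", "left", "right"),
                              normalize_slicewise = TRUE) {
  stopifnot(smooth_sigma_mm >= 0, critical_radius_vox >= 0)
  structure(list(smooth_sigma_mm = smooth_sigma_mm,
                 critical_radius_vox = as.integer(critical_radius_vox),
                 contralateral_side = match.arg(contralateral_side),
                 normalize_slicewise = isTRUE(normalize_slicewise)),
            class = "preprocess_config")
}

# Left hemisphere = voxels with axis-1 index at or below the brain-mask
# centroid (RAS: low x is the patient's left).
hemisphere_split <- function(mask_arr) {
  d <- dim(mask_arr)
  idx <- which(mask_arr > 0.5)
  mid <- mean(arrayInd(idx, d)[, 1])
  xi <- slice.index(array(0, d), 1)
  list(left = xi <= mid, right = xi > mid, midline = mid)
}

slice_means <- function(arr, sel) {
  d <- dim(arr)
  v <- arr; v[!sel] <- 0
  cnt <- array(as.numeric(sel), d)
  dim(v) <- c(d[1] * d[2], d[3]); dim(cnt) <- c(d[1] * d[2], d[3])
  s <- colSums(v); n <- colSums(cnt)
  list(mean = ifelse(n > 0, s / n, NA_real_), n = n)
}

#' Slice-wise contralateral DWI normalization
#'
#' Divides each axial slice of the DWI by the mean intensity over the
#' brain-mask voxels of the contralateral (healthy) hemisphere in that slice,
#' making intensities comparable across patients and scanners. Voxels
#' outside the brain mask are set to 0. Slices whose contralateral region is
#' empty or has non-positive mean fall back to the whole-slice brain mean; an
#' all-zero slice passes through as zeros.
#'
#' In `"auto"` mode the contralateral hemisphere is the one with the smaller
#' count of voxels above the 98th percentile of a roughly normalized DWI
#' (the lesion side carries the hyperintense burden). The choice is recorded
#' in attributes `contralateral_side` and `side_ambiguous` (counts within
#' 10% of each other).
#'
#' @param dwi DWI `volume`.
#' @param brain_mask Binary `volume` on the same grid.
#' @param contralateral_side `"left"`, `"right"` or `"auto"`.
#' @return Normalized DWI `volume` (unitless), zero outside the brain mask.
#' @export
normalize_dwi <- function(dwi, brain_mask,
                          contralateral_side = c("auto", "left", "right")) {
  contralateral_side <- match.arg(contralateral_side)
  stopifnot(is_volume(dwi), is_volume(brain_mask))
  stop_if_grid_mismatch(dwi, brain_mask, "dwi/brain_mask")
  d <- dim(dwi$data)
  brain <- brain_mask$data > 0.5
  if (!any(brain)) stop("brain mask is empty")
  hemi <- hemisphere_split(brain_mask$data)
  ambiguous <- FALSE

  whole <- slice_means(dwi$data, brain)
  if (contralateral_side == "auto") {
    rough_fac <- ifelse(is.finite(whole$mean) & whole$mean > 0, whole$mean, 1)
    rough <- sweep(dwi$data, 3, rough_fac, FUN = "/")
    q98 <- stats::quantile(rough[brain], 0.98, names = FALSE)
    nl <- sum(rough > q98 & brain & hemi$left)
    nr <- sum(rough > q98 & brain & hemi$right)
    contralateral_side <- if (nl <= nr) "left" else "right"
    ambiguous <- abs(nl - nr) <= 0.1 * max(nl, nr, 1)
    if (ambiguous)
      message("auto contralateral side is ambiguous (hyperintense counts ",
              nl, " left vs ", nr, " right)")
  }
  contra <- if (contralateral_side == "left") hemi$left else hemi$right
  cm <- slice_means(dwi$data, brain & contra)

  global_mean <- mean(dwi$data[brain])
  fac <- cm$mean
  for (k in seq_len(d[3])) {
    if (!is.finite(fac[k]) || fac[k] <= 0) {
      fac[k] <- whole$mean[k]                      # fallback: whole-slice mean
      if (!is.finite(fac[k])) fac[k] <- 1          # slice without brain voxels
      else if (fac[k] <= 0) {
        if (all(dwi$data[, , k][brain[, , k]] == 0)) {
          fac[k] <- 1                              # all-zero slice: stays zero
        } else if (global_mean > 0) {
          fac[k] <- global_mean     # noise-only edge slice of the brain mask
        } else {
          stop("slice ", k, ": non-positive normalization mean")
        }
      }
    }
  }
  out <- sweep(dwi$data, 3, fac, FUN = "/")
  out[!brain] <- 0
  res <- vol_like(dwi, out)
  attr(res, "contralateral_side") <- contralateral_side
  attr(res, "side_ambiguous") <- ambiguous
  res
}

#' Critical-intensity neighbourhood filter
#'
#' Assigns to each voxel the most critical intensity in the cube
#' neighbourhood of the given radius around it: the maximum for DWI-like
#' images (lesions are hyperintense) or the minimum for ADC-like images
#' (lesions are hypointense). Radius 0 is the identity.
#'
#' @param v A `volume`.
#' @param mode `"max"` or `"min"`.
#' @param radius_vox Neighbourhood radius in voxels ((2r+1)^3 cube).
#' @return Filtered `volume`.
#' @export
critical_filter <- function(v, mode = c("max", "min"), radius_vox = 1L) {
  mode <- match.arg(mode)
  stopifnot(is_volume(v), radius_vox >= 0)
  if (radius_vox == 0L) return(v)
  off <- neighbourhood_offsets(as.integer(radius_vox), "cube")
  vol_like(v, extremum_filter(v$data, off, mode))
}

#' Mirror-corrected feature map
#'
#' Subtracts from each voxel the most critical value of the smoothed,
#' mirror-transformed image in a small neighbourhood around it:
#' `v - critical_filter(smooth(mirror(v)), mode, r)`. For DWI (`mode =
#' "max"`) unilateral hyperintensities stay positive while bilaterally
#' symmetric structure and artifacts cancel to non-positive values; for ADC
#' (`mode = "min"`) the signs are reversed.
#'
#' @param v A `volume` on the grid of the b0 used for `t` (normalized DWI or
#'   native-unit ADC).
#' @param t A `mirror_transform` from [estimate_mirror_transform()].
#' @param cfg A [preprocess_config()].
#' @param mode `"max"` for DWI, `"min"` for ADC.
#' @return Mirror-corrected `volume`.
#' @export
mirror_correct <- function(v, t, cfg = preprocess_config(),
                           mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(is_volume(v), inherits(t, "mirror_transform"))
  if (!identical(dim(v$data), t$dim))
    stop("volume grid does not match the transform grid")
  flipped <- apply_mirror_transform(v, t)
  sm <- gaussian_smooth(flipped$data, cfg$smooth_sigma_mm, v$spacing)
  crit <- if (cfg$critical_radius_vox > 0L)
    extremum_filter(sm, neighbourhood_offsets(cfg$critical_radius_vox, "cube"),
                    mode)
  else sm
  vol_like(v, v$data - crit)
}

#' Preprocess one patient case
#'
#' Runs the full feature construction for a case: estimates the mirror
#' transform from b0, normalizes the DWI slice-wise against the
#' contralateral hemisphere, and computes the two mirror-corrected maps
#' (of the normalized DWI with `mode = "max"`, of the native-unit ADC with
#' `mode = "min"`).
#'
#' @param case A `patient_case`.
#' @param cfg A [preprocess_config()].
#' @param transform Optional precomputed `mirror_transform` (skips
#'   registration).
#' @return A list with the feature tibble (`features`: one row per
#'   brain-mask voxel with `patient_id, i, j, k, dwi_norm, adc, mc_dwi,
#'   mc_adc, label`), the four feature `volume`s (`maps`), the
#'   `mirror_transform` and the contralateral side used.
#' @export
preprocess_case <- function(case, cfg = preprocess_config(), transform = NULL) {
  stopifnot(inherits(case, "patient_case"))
  if (is.null(transform))
    transform <- estimate_mirror_transform(case$b0, case$brain_mask)
  dwi_norm <- normalize_dwi(case$dwi, case$brain_mask, cfg$contralateral_side)
  mc_dwi <- mirror_correct(dwi_norm, transform, cfg, "max")
  mc_adc <- mirror_correct(case$adc, transform, cfg, "min")

  idx <- which(case$brain_mask$data > 0.5)
  ijk <- arrayInd(idx, dim(case$brain_mask$data))
  label <- if (is.null(case$expert_mask)) NA_integer_
           else as.integer(case$expert_mask$data[idx] > 0.5)
  features <- tibble::tibble(
    patient_id = case$patient_id,
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    dwi_norm = dwi_norm$data[idx],
    adc = case$adc$data[idx],
    mc_dwi = mc_dwi$data[idx],
    mc_adc = mc_adc$data[idx],
    label = label
  )
  list(features = features,
       maps = list(dwi_norm = dwi_norm, adc = case$adc,
                   mc_dwi = mc_dwi, mc_adc = mc_adc),
       transform = transform,
       contralateral_side = attr(dwi_norm, "contralateral_side"))
}

#' Build the voxel feature table for a cohort
#'
#' One row per brain-mask voxel per case, with the four tree inputs
#' (`dwi_norm`, `adc`, `mc_dwi`, `mc_adc`), the expert label, the patient id
#' and the voxel index (for reconstructing maps from predictions).
#'
#' @param cases List of `patient_case` objects.
#' @param cfg A [preprocess_config()].
#' @param require_labels Error if a case lacks an expert mask (training
#'   mode).
#' @return A tibble (the `FeatureTable`).
#' @export
build_feature_table <- function(cases, cfg = preprocess_config(),
                                require_labels = TRUE) {
  if (inherits(cases, "patient_case")) cases <- list(cases)
  if (require_labels) {
    missing <- vapply(cases, function(cs) is.null(cs$expert_mask), logical(1))
    if (any(missing))
      stop("expert mask absent for: ",
           paste(vapply(cases[missing], `[[`, "", "patient_id"),
                 collapse = ", "))
  }
  dplyr::bind_rows(lapply(cases, function(cs) preprocess_case(cs, cfg)$features))
}

feature_names <- function() c("dwi_norm", "adc", "mc_dwi", "mc_adc")

# Rebuild a volume from per-voxel values at (i,j,k) rows; `fill` elsewhere.
map_from_table <- function(values, ijk, ref_volume, fill = 0) {
  a <- array(fill, dim(ref_volume$data))
  a[as.matrix(ijk)] <- values
  vol_like(ref_volume, a)
}
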