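#' Construct a volume
#'
#' A `volume` is the package's lightweight container for a 3-D scalar grid:
#' a numeric array plus voxel spacing in mm and a 4x4 voxel-to-world affine.
#' All images, maps and masks (DWI, ADC, b0, probability maps, binary masks)
#' are carried as volumes. After [load_case()] the first array axis is the
#' patient left-right axis (RAS convention), which is what every mirror
#' operation flips.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix (must be invertible). Defaults to a
#'   diagonal scaling by `spacing`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

#' Replace the data of a volume, keeping its grid
#' @param v A `volume`.
#' @param data New array of identical shape.
#' @return A `volume` on the same grid.
#' @export
vol_like <- function(v, data) {
  stopifnot(is_volume(v))
  data <- as.array(data)
  if (!identical(dim(data), dim(v$data))) stop("shape mismatch")
  volume(data, v$spacing, v$affine)
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, ": grid shape mismatch (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  invisible(TRUE)
}

#' Read a NIfTI file as a volume in canonical RAS orientation
#'
#' Volumes are reoriented on load so axis 1 runs left to right (RAS);
#' this fixes the left-right axis that mirror correction flips.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A `volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (!is.na(RNifti::orientation(img)) && RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("expected a 3-D NIfTI volume: ", path)
    img <- array(as.numeric(img), dim = d[1:3])
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  if (is.null(aff) || abs(det(aff)) < 1e-12) aff <- diag(c(sp, 1))
  volume(array(as.numeric(img), dim = dim(img)[1:3]), sp, aff)
}

#' Write a volume to NIfTI
#'
#' Masks (0/1 integer content) are stored as 8-bit unsigned integers,
#' everything else as 32-bit floats.
#'
#' @param v A `volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"auto"` picks `uint8` for binary
#'   content and `float` otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "auto") {
  stopifnot(is_volume(v))
  if (identical(datatype, "auto")) {
    datatype <- if (all(v$data %in% c(0, 1))) "uint8" else "float"
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Assemble a patient case from per-channel volumes
#'
#' A `patient_case` bundles one patient's co-registered channels: DWI at
#' b=1000 s/mm2, the ADC map, the b=0 image, a brain mask and (optionally)
#' the expert lesion mask. All channels must share one grid.
#'
#' @param patient_id Identifier string.
#' @param dwi,adc,b0 `volume`s on one common grid.
#' @param brain_mask Binary `volume`; derived from `b0` via
#'   [compute_brain_mask()] when `NULL`.
#' @param expert_mask Binary `volume` or `NULL` (pure-prediction mode).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient_id, dwi, adc, b0,
                         brain_mask = NULL, expert_mask = NULL) {
  for (v in list(dwi, adc, b0)) stopifnot(is_volume(v))
  stop_if_grid_mismatch(dwi, adc, "dwi/adc")
  stop_if_grid_mismatch(dwi, b0, "dwi/b0")
  if (is.null(brain_mask)) brain_mask <- compute_brain_mask(b0)
  stop_if_grid_mismatch(dwi, brain_mask, "dwi/brain_mask")
  if (!any(brain_mask$data > 0)) stop("brain mask is empty")
  if (!is.null(expert_mask)) {
    stop_if_grid_mismatch(dwi, expert_mask, "dwi/expert_mask")
    if (any(expert_mask$data > 0 & brain_mask$data == 0))
      stop("expert mask extends outside the brain mask")
  }
  structure(list(patient_id = as.character(patient_id),
                 dwi = dwi, adc = adc, b0 = b0,
                 brain_mask = brain_mask, expert_mask = expert_mask),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case> ", x$patient_id, ": ",
      paste(dim(x$dwi$data), collapse = "x"), " grid, ",
      sum(x$brain_mask$data > 0), " brain voxels, ",
      if (is.null(x$expert_mask)) "no expert mask"
      else paste0(sum(x$expert_mask$data > 0), " lesion voxels"),
      "\n", sep = "")
  invisible(x)
}

#' Load a patient case from NIfTI files
#'
#' @param dwi_path,adc_path,b0_path NIfTI paths for the three channels.
#' @param expert_path Optional NIfTI path for the expert lesion mask.
#' @param patient_id Identifier; defaults to the DWI file stem.
#' @return A `patient_case` with all channels reoriented to RAS and verified
#'   to share one grid.
#' @export
load_case <- function(dwi_path, adc_path, b0_path, expert_path = NULL,
                      patient_id = NULL) {
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(dwi_path))
  dwi <- read_volume(dwi_path)
  adc <- read_volume(adc_path)
  b0  <- read_volume(b0_path)
  expert <- NULL
  if (!is.null(expert_path) && !is.na(expert_path) && nzchar(expert_path)) {
    expert <- read_volume(expert_path)
    expert$data <- array(as.numeric(expert$data > 0.5), dim(expert$data))
  }
  patient_case(patient_id, dwi, adc, b0, expert_mask = expert)
}

#' Write a patient case as NIfTI files
#'
#' @param case A `patient_case`.
#' @param dir Output directory (created if needed).
#' @return A named list of file paths (used as a manifest row).
#' @export
save_case <- function(case, dir) {
  stopifnot(inherits(case, "patient_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pid <- case$patient_id
  paths <- list(
    patient_id = pid,
    dwi_path = file.path(dir, paste0(pid, "_dwi.nii.gz")),
    adc_path = file.path(dir, paste0(pid, "_adc.nii.gz")),
    b0_path = file.path(dir, paste0(pid, "_b0.nii.gz"))
  )
  write_volume(case$dwi, paths$dwi_path, "float")
  write_volume(case$adc, paths$adc_path, "float")
  write_volume(case$b0, paths$b0_path, "float")
  if (!is.null(case$expert_mask)) {
    paths$expert_path <- file.path(dir, paste0(pid, "_expert.nii.gz"))
    write_volume(case$expert_mask, paths$expert_path, "uint8")
  } else {
    paths$expert_path <- NA_character_
  }
  paths
}

#' Read a cohort manifest and load its cases
#'
#' The manifest is a CSV with columns `patient_id, dwi_path, adc_path,
#' b0_path, expert_path` (paths relative to the manifest's directory or
#' absolute).
#'
#' @param manifest_path CSV path.
#' @return A list of `patient_case` objects.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dwi_path", "adc_path", "b0_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) {
    if (is.na(p) || !nzchar(p)) return(NA_character_)
    if (file.exists(p)) p else file.path(base, p)
  }
  lapply(seq_len(nrow(man)), function(i) {
    ep <- if ("expert_path" %in% names(man)) resolve(man$expert_path[i]) else NULL
    load_case(resolve(man$dwi_path[i]), resolve(man$adc_path[i]),
              resolve(man$b0_path[i]), ep, patient_id = man$patient_id[i])
  })
}

# Global Otsu threshold on a 256-bin histogram (maximize between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  h <- as.numeric(tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                           nbins = nbins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nbins))
  n <- w[nbins]; mtot <- mu[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mtot * w0[valid] - n * mu[k][valid])^2 /
    (w0[valid] * w1[valid])
  kbest <- which.max(between)
  rng[1] + kbest / nbins * diff(rng)
}

#' Derive a brain mask from the b=0 image
#'
#' Automatic bimodal (Otsu) intensity thresholding, followed by retention of
#' the largest 6-connected foreground component and binary closing with a
#' cube of radius 2 voxels. Invariant to positive affine rescaling of the
#' intensities.
#'
#' @param b0 The b=0 `volume` (must be non-constant).
#' @param close_radius_vox Radius of the closing structuring element, voxels.
#' @return A binary `volume` (0/1).
#' @export
compute_brain_mask <- function(b0, close_radius_vox = 2L) {
  stopifnot(is_volume(b0))
  thr <- otsu_threshold(b0$data)
  fg <- b0$data > thr
  if (!any(fg)) stop("empty foreground after thresholding")
  fg <- largest_component(fg)
  fg <- binary_close(fg, close_radius_vox)
  vol_like(b0, array(as.numeric(fg), dim(fg)))
}
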