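# Mirror transform: reflection across the mid-sagittal plane composed with a
# small 6-DOF rigid correction, estimated by registering the b0 image to its
# own left-right flip. Applying it maps each hemisphere onto the other, so
# subtracting a (smoothed, critical-intensity-filtered) transformed image
# from the original highlights unilateral anomalies.

#' Construct a mirror transform
#'
#' The transform is the composition of a flip of the left-right axis (axis 1)
#' about the grid center with a rigid correction `(tx, ty, tz, rx, ry, rz)`
#' (translations in mm, rotations in radians about the grid center). With a
#' zero rigid part it reduces to an exact index reversal of axis 1.
#'
#' @param rigid Numeric length-6 rigid parameters.
#' @param dim Grid shape the transform was estimated on.
#' @param spacing Voxel spacing in mm.
#' @param converged Logical; `FALSE` when estimation fell back to the pure
#'   midplane flip.
#' @return An object of class `mirror_transform`.
#' @export
mirror_transform <- function(rigid = rep(0, 6), dim, spacing,
                             converged = TRUE) {
  stopifnot(length(rigid) == 6L, length(dim) == 3L, length(spacing) == 3L)
  structure(list(rigid = as.numeric(rigid), dim = as.integer(dim),
                 spacing = as.numeric(spacing),
                 converged = isTRUE(converged)),
            class = "mirror_transform")
}

#' @export
print.mirror_transform <- function(x, ...) {
  cat("<mirror_transform> flip axis 1; t = (",
      paste(signif(x$rigid[1:3], 3), collapse = ", "), ") mm, r = (",
      paste(signif(x$rigid[4:6] * 180 / pi, 3), collapse = ", "), ") deg",
      if (!x$converged) " [fallback: pure midplane flip]", "\n", sep = "")
  invisible(x)
}

rotation_matrix <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Map mm coordinates (n x 3, relative to voxel (1,1,1) at 0) through the
# transform: flip axis 1 about the grid center, then rotate about the center
# and translate.
mirror_map_points <- function(t, pts_mm) {
  ctr <- (t$dim - 1) * t$spacing / 2
  q <- pts_mm
  q[, 1] <- 2 * ctr[1] - q[, 1]
  R <- rotation_matrix(t$rigid[4], t$rigid[5], t$rigid[6])
  q <- sweep(q, 2, ctr)
  q <- q %*% t(R)
  sweep(q, 2, ctr + t$rigid[1:3], FUN = "+")
}

#' Apply a mirror transform to a volume
#'
#' Resamples `v` at the mirrored (and rigidly corrected) coordinates with
#' trilinear interpolation. When the rigid part is exactly zero the result is
#' the exact index reversal of axis 1 (no interpolation).
#'
#' @param v A `volume` on the grid the transform was estimated on.
#' @param t A `mirror_transform`.
#' @return The transformed `volume`.
#' @export
apply_mirror_transform <- function(v, t) {
  stopifnot(is_volume(v), inherits(t, "mirror_transform"))
  d <- dim(v$data)
  if (!identical(d, t$dim)) stop("volume grid does not match the transform grid")
  if (all(t$rigid == 0)) {
    return(vol_like(v, v$data[d[1]:1, , , drop = FALSE]))
  }
  ijk <- arrayInd(seq_len(prod(d)), d)
  pts <- sweep(ijk - 1, 2, v$spacing, FUN = "*")
  src_mm <- mirror_map_points(t, pts)
  src_vox <- sweep(src_mm, 2, v$spacing, FUN = "/") + 1
  vol_like(v, array(interp_trilinear(v$data, src_vox), d))
}

#' Estimate the mirror transform from the b0 image
#'
#' Flips the b0 image across the grid midplane and estimates the 6-DOF rigid
#' correction minimizing the mean squared intensity difference to the
#' original within the brain mask (Nelder-Mead, trilinear sampling on a
#' deterministic subsample of mask voxels). If the optimum explains no more
#' of the masked intensity variance than chance (e.g. a structureless noise
#' volume) the function warns and falls back to the pure midplane flip.
#'
#' @param b0 The b=0 `volume`.
#' @param brain_mask Binary `volume` on the same grid (non-empty).
#' @param max_points Subsample size for the registration metric.
#' @param maxit Nelder-Mead iteration budget.
#' @return A `mirror_transform`.
#' @export
estimate_mirror_transform <- function(b0, brain_mask, max_points = 8000L,
                                      maxit = 400L) {
  stopifnot(is_volume(b0), is_volume(brain_mask))
  stop_if_grid_mismatch(b0, brain_mask, "b0/brain_mask")
  d <- dim(b0$data)
  if (!any(brain_mask$data > 0.5)) stop("brain mask is empty")
  # sample from the slightly dilated mask: the brain/background edge is what
  # constrains the rigid fit (interior tissue is nearly flat)
  idx <- which(binary_dilate(brain_mask$data > 0.5, 2L))
  if (length(idx) > max_points)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_points)))]
  ijk <- arrayInd(idx, d)
  pts_mm <- sweep(ijk - 1, 2, b0$spacing, FUN = "*")
  target <- b0$data[idx]

  tmpl <- mirror_transform(dim = d, spacing = b0$spacing)
  metric <- function(par) {
    tt <- tmpl; tt$rigid <- par
    src <- sweep(mirror_map_points(tt, pts_mm), 2, b0$spacing, FUN = "/") + 1
    mean((target - interp_trilinear(b0$data, src)) ^ 2)
  }

  # init: translate so the flipped mask centroid lands on the original one
  ctr <- (d - 1) * b0$spacing / 2
  centroid <- colMeans(sweep(arrayInd(which(brain_mask$data > 0.5), d) - 1,
                             2, b0$spacing, FUN = "*"))
  par0 <- c(2 * (centroid[1] - ctr[1]), 0, 0, 0, 0, 0)

  fit <- tryCatch(
    stats::optim(par0, metric, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) NULL)

  vtot <- stats::var(target)
  ok <- !is.null(fit) && all(is.finite(fit$par)) &&
    max(abs(fit$par[1:3])) <= 25 && max(abs(fit$par[4:6])) <= 0.35 &&
    is.finite(fit$value) && fit$value < vtot
  if (!ok) {
    warning("mirror registration did not converge; ",
            "falling back to the pure midplane flip")
    return(mirror_transform(dim = d, spacing = b0$spacing, converged = FALSE))
  }
  mirror_transform(fit$par, d, b0$spacing, converged = TRUE)
}
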