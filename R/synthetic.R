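# Seeded synthetic cohorts: bilaterally quasi-symmetric ellipsoidal "brains"
# with one hyperintense-DWI / hypointense-ADC lesion in one hemisphere,
# per-slice intensity drift (exercising the slice-wise normalization),
# additive Gaussian noise, a small random head offset (exercising the mirror
# registration) and optional bilaterally mirrored lesion-like artifacts
# (exercising what mirror correction is for: bilateral structure must not be
# read as lesion).

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions every stage of the pipeline is
#' exercised under: a 32 x 36 x 30 grid of 2.5 mm voxels, DWI background
#' around 100 (arbitrary units) with lesions 1.5-2.5 times brighter, ADC
#' background around 800 (1e-6 mm^2/s) with lesions reduced to 0.4-0.7 of
#' background, 5% additive Gaussian noise, a ~0.5 mm random head offset and
#' two bilaterally mirrored lesion-like artifact pairs per volume.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing_mm Voxel spacing (mm).
#' @param n_patients Cohort size.
#' @param lesion_volume_ml_range Uniform range of target lesion volumes (ml).
#' @param lesion_dwi_contrast Range of multiplicative DWI elevation in the
#'   lesion.
#' @param lesion_adc_contrast Range of multiplicative ADC reduction.
#' @param noise_sd_frac Additive Gaussian noise sd as a fraction of the
#'   tissue mean, per channel.
#' @param asymmetry_sd_mm Sd (mm) of the random head-center offset from the
#'   grid center.
#' @param artifact_rate Number of mirrored bilateral artifact pairs per
#'   volume (each pair is lesion-like in both DWI and ADC contrast, so
#'   intensity bands cannot exclude them while mirror correction can).
#' @param seed Integer; together with the case index it fixes every draw.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(32L, 36L, 30L),
                             spacing_mm = c(2.5, 2.5, 2.5),
                             n_patients = 12L,
                             lesion_volume_ml_range = c(2, 10),
                             lesion_dwi_contrast = c(1.5, 2.5),
                             lesion_adc_contrast = c(0.4, 0.7),
                             noise_sd_frac = 0.05,
                             asymmetry_sd_mm = 0.5,
                             artifact_rate = 3L,
                             seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            n_patients >= 1L,
            all(lesion_volume_ml_range > 0),
            all(lesion_dwi_contrast > 0), all(lesion_adc_contrast > 0),
            noise_sd_frac >= 0, asymmetry_sd_mm >= 0, artifact_rate >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 n_patients = as.integer(n_patients),
                 lesion_volume_ml_range = as.numeric(lesion_volume_ml_range),
                 lesion_dwi_contrast = as.numeric(lesion_dwi_contrast),
                 lesion_adc_contrast = as.numeric(lesion_adc_contrast),
                 noise_sd_frac = noise_sd_frac,
                 asymmetry_sd_mm = asymmetry_sd_mm,
                 artifact_rate = as.integer(artifact_rate),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# mm coordinate arrays of the voxel centers (origin at voxel (1,1,1))
coord_arrays <- function(d, sp) {
  list(x = array(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d),
       y = array(rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]),
                     times = d[3]), d),
       z = array(rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]), d))
}

ellipsoid_field <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2
}

#' Generate one synthetic patient case
#'
#' Fully determined by `(cfg$seed, index)`: identical inputs give
#' bit-identical cases. See [synthetic_config()] for what is emulated.
#'
#' @param cfg A [synthetic_config()].
#' @param index Case index (1-based).
#' @return A `patient_case` whose `expert_mask` is the exact lesion
#'   ellipsoid, with attributes `lesion_side`, `lesion_volume_ml` (target),
#'   `dwi_contrast`, `adc_contrast`.
#' @export
generate_case <- function(cfg, index) {
  stopifnot(inherits(cfg, "synthetic_config"), index >= 1L)
  case_seed <- (as.numeric(cfg$seed) * 10007 + index * 101) %% 2147483647
  with_seed(as.integer(case_seed), generate_case_impl(cfg, index))
}

generate_case_impl <- function(cfg, index) {
  d <- cfg$grid_shape; sp <- cfg$spacing_mm
  ext <- (d - 1) * sp
  ctr <- ext / 2
  co <- coord_arrays(d, sp)

  # head center: grid center plus a small random offset (mild asymmetry
  # relative to the grid midplane that registration must recover)
  delta <- if (cfg$asymmetry_sd_mm > 0) stats::rnorm(3, 0, cfg$asymmetry_sd_mm)
           else c(0, 0, 0)
  bctr <- ctr + delta
  bsemi <- c(0.40, 0.42, 0.40) * ext

  Eb <- ellipsoid_field(co, bctr, bsemi)
  brain <- Eb <= 1

  # smooth symmetric-in-x tissue modulation; per-slice intensity drift
  # affects the relative-scale channels (DWI, b0) but not the quantitative
  # ADC map — slice-wise normalization is what removes it from the DWI
  phase <- stats::runif(1, 0, 2 * pi)
  freq <- sample(1:2, 1)
  drift <- 1 + 0.10 * sin(2 * pi * freq * (seq_len(d[3]) - 1) / d[3] + phase)
  modulation <- 1 + 0.06 * (Eb - 0.5)
  tissue <- array(as.numeric(brain), d) * modulation
  drifted <- tissue * rep(drift, each = d[1] * d[2])

  # lesion: one ellipsoid entirely inside one hemisphere
  side <- if (stats::runif(1) < 0.5) -1 else 1
  vol_ml <- stats::runif(1, cfg$lesion_volume_ml_range[1],
                         cfg$lesion_volume_ml_range[2])
  shape <- c(0.75, 1.2, 1.1)
  r <- (3 * vol_ml * 1000 / (4 * pi * prod(shape)))^(1 / 3)
  lsemi <- shape * r
  jit <- stats::runif(2, -0.12, 0.12)
  off <- 0.5 * bsemi[1]
  lesion <- NULL
  for (try in 1:80) {
    lctr <- c(bctr[1] + side * off,
              bctr[2] + jit[1] * bsemi[2], bctr[3] + jit[2] * bsemi[3])
    El <- ellipsoid_field(co, lctr, lsemi)
    les <- El <= 1
    if (!any(les)) break
    xs <- co$x[les]
    crosses <- if (side < 0) any(xs > bctr[1] - 0.2 * sp[1])
               else any(xs < bctr[1] + 0.2 * sp[1])
    outside <- max(Eb[les]) > 0.92
    if (!crosses && !outside) { lesion <- les; break }
    if (outside && !crosses) off <- off * 0.93
    else if (crosses && !outside) off <- off * 1.07
    else { jit <- jit * 0.7; off <- off * 0.97 }
  }
  if (is.null(lesion) || !any(lesion))
    stop("lesion volume ", signif(vol_ml, 3),
         " ml infeasible for this grid/brain geometry")

  dwi_contrast <- stats::runif(1, cfg$lesion_dwi_contrast[1],
                               cfg$lesion_dwi_contrast[2])
  adc_contrast <- stats::runif(1, cfg$lesion_adc_contrast[1],
                               cfg$lesion_adc_contrast[2])

  dwi <- 100 * drifted
  adc <- 800 * tissue
  b0 <- 1000 * drifted
  dwi[lesion] <- dwi[lesion] * dwi_contrast
  adc[lesion] <- adc[lesion] * adc_contrast

  # mirrored bilateral artifact pairs: lesion-like contrast on BOTH sides,
  # symmetric about the head midplane, away from the lesion
  if (cfg$artifact_rate > 0L) {
    # mirror-symmetric exclusion zone: the lesion plus a one-voxel rim AND
    # its mirror image, so carving never breaks an artifact's bilaterality
    # (a half-carved pair would itself look like a unilateral anomaly)
    mlctr <- c(2 * bctr[1] - lctr[1], lctr[2], lctr[3])
    excl <- ellipsoid_field(co, lctr, lsemi + sp) <= 1 |
            ellipsoid_field(co, mlctr, lsemi + sp) <= 1
    for (a in seq_len(cfg$artifact_rate)) {
      for (try in 1:30) {
        rad <- stats::runif(1, 5, 9)
        actr <- c(bctr[1] + sign(stats::runif(1) - 0.5) *
                    stats::runif(1, 0.3, 0.7) * bsemi[1],
                  bctr[2] + stats::runif(1, -0.5, 0.5) * bsemi[2],
                  bctr[3] + stats::runif(1, -0.5, 0.5) * bsemi[3])
        mctr <- c(2 * bctr[1] - actr[1], actr[2], actr[3])
        blob <- ellipsoid_field(co, actr, rep(rad, 3)) <= 1 |
                ellipsoid_field(co, mctr, rep(rad, 3)) <= 1
        blob <- blob & brain & !excl
        if (sum(blob) >= 8) {
          # the first pair shares the lesion's own contrast (an intensity
          # band cannot separate it); further pairs draw their own
          if (a == 1L) {
            adwi <- dwi_contrast; aadc <- adc_contrast
          } else {
            adwi <- stats::runif(1, 1.5, 2.3)
            aadc <- stats::runif(1, 0.4, 0.65)
          }
          dwi[blob] <- dwi[blob] * adwi
          adc[blob] <- adc[blob] * aadc
          break
        }
      }
    }
  }

  if (cfg$noise_sd_frac > 0) {
    dwi <- dwi + stats::rnorm(length(dwi), 0, cfg$noise_sd_frac * 100)
    adc <- adc + stats::rnorm(length(adc), 0, cfg$noise_sd_frac * 800)
    b0 <- b0 + stats::rnorm(length(b0), 0, cfg$noise_sd_frac * 1000)
  }

  mk <- function(a) volume(array(a, d), sp)
  case <- patient_case(sprintf("syn%03d", index),
                       dwi = mk(dwi), adc = mk(adc), b0 = mk(b0),
                       expert_mask = mk(as.numeric(lesion)))
  attr(case, "lesion_side") <- if (side < 0) "left" else "right"
  attr(case, "lesion_volume_ml") <- vol_ml
  attr(case, "dwi_contrast") <- dwi_contrast
  attr(case, "adc_contrast") <- adc_contrast
  case
}

#' Generate a synthetic cohort
#'
#' Draws `cfg$n_patients` independent cases (lesion sizes, sides and
#' contrasts vary per case) and optionally writes them to disk as NIfTI
#' files plus a CSV manifest in the layout [load_cohort()] reads, so
#' synthetic and real cohorts are path-identical downstream.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional output directory.
#' @return List of `patient_case` objects; when `dir` is given the manifest
#'   tibble is attached as attribute `manifest` and written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  cases <- lapply(seq_len(cfg$n_patients), function(i) generate_case(cfg, i))
  if (!is.null(dir)) {
    rows <- lapply(cases, save_case, dir = dir)
    manifest <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    attr(cases, "manifest") <- manifest
  }
  cases
}
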