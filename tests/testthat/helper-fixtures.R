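# Programmatic fixtures: small phantoms and compact synthetic configurations.

# A dark volume containing one bright axis-aligned box.
box_volume <- function(dim = c(24, 24, 24), lo = 7, hi = 18,
                       bright = 100, dark = 2, spacing = c(1, 1, 1)) {
  a <- array(dark, dim)
  a[lo:hi, lo:hi, lo:hi] <- bright
  volume(a, spacing)
}

# Compact synthetic configuration for fast pipeline tests.
quick_cfg <- function(n = 4, seed = 11, noise = 0.05, asymmetry = 0.4,
                      artifacts = 1L, ...) {
  synthetic_config(grid_shape = c(22L, 26L, 20L), spacing_mm = c(3, 3, 3),
                   n_patients = n, lesion_volume_ml_range = c(1.5, 4),
                   noise_sd_frac = noise, asymmetry_sd_mm = asymmetry,
                   artifact_rate = artifacts, seed = seed, ...)
}

# Noiseless, perfectly grid-symmetric case (up to the one-sided lesion).
noiseless_case <- function(seed = 5, lesion = TRUE) {
  cfg <- synthetic_config(
    grid_shape = c(24L, 28L, 22L), spacing_mm = c(3, 3, 3),
    n_patients = 1L, lesion_volume_ml_range = c(2.5, 3.5),
    lesion_dwi_contrast = if (lesion) c(1.8, 2.2) else c(1, 1),
    lesion_adc_contrast = if (lesion) c(0.5, 0.6) else c(1, 1),
    noise_sd_frac = 0, asymmetry_sd_mm = 0, artifact_rate = 0L, seed = seed)
  generate_case(cfg, 1)
}

# A small labelled feature table with class structure, for tree tests.
random_feature_table <- function(n, seed, signal = TRUE, pid = "p1") {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.3)
    X <- matrix(rnorm(4 * n), n, 4)
    if (signal) X[, 1] <- X[, 1] + 2.5 * y
    tibble::tibble(patient_id = pid, i = seq_len(n), j = 1L, k = 1L,
                   dwi_norm = X[, 1], adc = X[, 2],
                   mc_dwi = X[, 3], mc_adc = X[, 4], label = y)
  })
}
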