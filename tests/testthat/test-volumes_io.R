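test_that("NIfTI round-trip preserves data, spacing and affine", {
  dir <- withr::local_tempdir()
  v <- volume(array(rnorm(16 * 18 * 14), c(16, 18, 14)), c(1.5, 2, 2.5))
  p <- file.path(dir, "v.nii.gz")
  write_volume(v, p, "float")
  v2 <- read_volume(p)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-5)
  expect_equal(v2$affine, v$affine, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(v2$data, v$data, tolerance = 1e-6)  # float32 storage
})

test_that("save_case / load_case round-trips a whole case", {
  dir <- withr::local_tempdir()
  cs <- generate_case(quick_cfg(seed = 3), 1)
  paths <- save_case(cs, dir)
  cs2 <- load_case(paths$dwi_path, paths$adc_path, paths$b0_path,
                   paths$expert_path, patient_id = cs$patient_id)
  expect_equal(cs2$dwi$data, cs$dwi$data, tolerance = 1e-6)
  expect_equal(cs2$adc$data, cs$adc$data, tolerance = 1e-6)
  expect_identical(cs2$expert_mask$data > 0.5, cs$expert_mask$data > 0.5)
  # masks stored as 0/1 uint8 must survive exactly
  expect_true(all(cs2$expert_mask$data %in% c(0, 1)))
})

test_that("case assembly enforces grid agreement and mask invariants", {
  v1 <- volume(array(1, c(8, 8, 6)))
  v2 <- volume(array(1, c(8, 8, 5)))
  expect_error(patient_case("p", v1, v2, v1), "mismatch")
  expect_error(volume(array(1, c(4, 4, 4)), spacing = c(1, -1, 1)), "positive")
  expect_error(volume(array(1, c(4, 4, 4)), affine = matrix(0, 4, 4)),
               "invertible")
  # expert mask outside the brain mask is rejected
  b0 <- box_volume(c(16, 16, 16), 5, 12)
  brain <- compute_brain_mask(b0)
  bad <- vol_like(brain, array(0, dim(brain$data)))
  bad$data[1, 1, 1] <- 1
  expect_error(patient_case("p", b0, b0, b0, brain, bad), "outside")
})

test_that("brain mask recovers a bright box and keeps the largest blob", {
  v <- box_volume(c(32, 32, 32), 9, 24)
  m <- compute_brain_mask(v)
  truth <- array(FALSE, dim(v$data)); truth[9:24, 9:24, 9:24] <- TRUE
  # agreement up to a 1-voxel boundary layer
  core <- array(FALSE, dim(v$data)); core[10:23, 10:23, 10:23] <- TRUE
  expect_true(all(m$data[core] == 1))
  outer1 <- array(FALSE, dim(v$data)); outer1[8:25, 8:25, 8:25] <- TRUE
  expect_true(all(m$data[!outer1] == 0))

  # two blobs: only the larger is kept
  v2 <- volume(array(0, c(40, 24, 24)))
  v2$data[4:19, 5:20, 5:20] <- 100   # 16^3
  v2$data[30:35, 9:14, 9:14] <- 100  # 6^3
  m2 <- compute_brain_mask(v2)
  expect_true(all(m2$data[30:35, 9:14, 9:14] == 0))
  expect_gt(sum(m2$data), 14^3)
})

test_that("brain mask errors on constant input, invariant to rescaling", {
  expect_error(compute_brain_mask(volume(array(5, c(10, 10, 10)))), "constant")
  v <- box_volume()
  m1 <- compute_brain_mask(v)
  m2 <- compute_brain_mask(vol_like(v, 3.7 * v$data + 11))
  expect_identical(m1$data, m2$data)
})

test_that("cohort manifest round-trips through disk", {
  dir <- withr::local_tempdir()
  cases <- generate_cohort(quick_cfg(n = 2, seed = 9), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- attr(cases, "manifest")
  expect_equal(nrow(man), 2L)
  back <- load_cohort(file.path(dir, "manifest.csv"))
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$dwi$data, cases[[1]]$dwi$data, tolerance = 1e-6)
  expect_identical(back[[2]]$expert_mask$data > 0.5,
                   cases[[2]]$expert_mask$data > 0.5)
})
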