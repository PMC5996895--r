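test_that("Dice matches the worked confusion-count example and conventions", {
  d <- c(6, 6, 3)
  a <- volume(array(0, d)); b <- volume(array(0, d))
  a$data[1:8] <- 1; b$data[1:8] <- 1
  expect_equal(dice(a, b), 1.0)                      # identical masks
  b2 <- volume(array(0, d)); b2$data[20:24] <- 1
  expect_equal(dice(a, b2), 0.0)                     # disjoint
  # TP = 5, FP = 3, FN = 2 -> 10/15
  p <- volume(array(0, d)); e <- volume(array(0, d))
  p$data[1:8] <- 1                                   # prediction: 8 voxels
  e$data[c(1:5, 9:10)] <- 1                          # truth: 5 shared + 2
  expect_equal(dice(p, e), 2 * 5 / (2 * 5 + 3 + 2))
  # degenerate conventions and symmetry
  z <- volume(array(0, d))
  expect_equal(dice(z, z), 1.0)
  expect_equal(dice(a, z), 0.0)
  expect_equal(dice(z, a), 0.0)
  expect_equal(dice(p, e), dice(e, p))
  expect_error(dice(a, volume(array(0, c(5, 5, 3)))), "mismatch")
})

test_that("mask volumes convert voxel counts to milliliters", {
  v <- volume(array(0, c(20, 10, 10)))
  v$data[1:1000] <- 1
  expect_equal(volume_ml(v), 1.0)
  expect_equal(volume_ml(vol_like(v, array(0, dim(v$data)))), 0.0)
  v2 <- volume(array(0, c(10, 10, 10)), spacing = c(2, 2, 2))
  v2$data[1:100] <- 1
  expect_equal(volume_ml(v2), 0.8)
})

test_that("residual SD is the sample SD of volume differences", {
  rec <- function(p, e) tibble::tibble(predicted_volume_ml = p,
                                       expert_volume_ml = e)
  expect_equal(residual_sd(rec(c(3, 7, 2), c(3, 7, 2))), 0.0)
  expect_equal(residual_sd(rec(c(4, 2), c(3, 3))), sqrt(2))
  expect_equal(residual_sd(rec(c(5, 5, 8), c(5, 5, 5))), sqrt(3))
  expect_error(residual_sd(rec(1, 1)), "at least 2")
})

test_that("two-threshold optimum matches brute force on random volumes", {
  withr::local_seed(505)
  for (rep in 1:20) {
    d <- c(10, 10, 10)
    vals <- sample(seq(0, 5, by = 0.25), prod(d), replace = TRUE)
    v <- volume(array(vals, d))
    brain <- volume(array(1, d))
    e <- array(0, d)
    e[sample(prod(d), sample(20:200, 1))] <- 1
    expert <- volume(e)
    got <- optimal_two_threshold_dice(v, expert, brain)
    want <- oracle_band(vals, e > 0.5)
    expect_true(got$exact)
    expect_identical(got$dice, want$dice)
    expect_identical(got$lo, want$lo)
    expect_identical(got$hi, want$hi)
    # optimality: no fixed band does better
    for (k in 1:20) {
      b <- sort(runif(2, 0, 5))
      inband <- vals >= b[1] & vals <= b[2]
      dk <- 2 * sum(inband & e > 0.5) / (sum(inband) + sum(e))
      expect_gte(got$dice, dk)
    }
  }
})

test_that("two-threshold edge cases: realizable bands and constant images", {
  d <- c(8, 8, 8)
  withr::local_seed(506)
  vals <- array(runif(prod(d), 0, 10), d)
  v <- volume(vals)
  brain <- volume(array(1, d))
  expert <- volume(array(as.numeric(vals >= 5), d))
  got <- optimal_two_threshold_dice(v, expert, brain)
  expect_equal(got$dice, 1.0)
  expect_identical(got$hi, Inf)
  # the realizable lower cut is the smallest in-lesion value (just above 5)
  expect_identical(got$lo, min(vals[vals >= 5]))
  # constant image: only all-or-nothing bands exist
  cv <- volume(array(2, d))
  e2 <- array(0, d); e2[1:50] <- 1
  got2 <- optimal_two_threshold_dice(cv, volume(e2), brain)
  expect_equal(got2$dice, 2 * 50 / (50 + prod(d)))
  expect_error(optimal_two_threshold_dice(v, volume(array(0, d)), brain),
               "empty")
})

test_that("quantile-grid approximation reports near-exact band quality", {
  withr::local_seed(507)
  d <- c(12, 12, 8)
  vals <- array(rnorm(prod(d)), d)
  e <- array(as.numeric(vals > 1), d)
  v <- volume(vals); brain <- volume(array(1, d))
  exact <- optimal_two_threshold_dice(v, volume(e), brain,
                                      max_exact = 2000)
  approx <- optimal_two_threshold_dice(v, volume(e), brain,
                                       max_exact = 100, n_grid = 256)
  expect_true(exact$exact); expect_false(approx$exact)
  expect_lte(approx$dice, exact$dice + 1e-12)
  expect_gt(approx$dice, exact$dice - 0.05)
})

test_that("paired Wilcoxon comparison returns a valid p-value", {
  rec <- tibble::tibble(
    patient_id = rep(sprintf("p%02d", 1:8), 2),
    method = rep(c("atlas", "threshold_adc"), each = 8),
    dice = c(seq(0.8, 0.94, length.out = 8), seq(0.5, 0.72, length.out = 8)))
  cmp <- compare_methods(rec, "atlas", "threshold_adc")
  expect_equal(cmp$n, 8L)
  expect_lt(cmp$p_value, 0.05)
  expect_gte(cmp$p_value, 0)
})
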