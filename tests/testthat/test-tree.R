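test_that("pseudo-count node probability follows (n1+1)/(n+2)", {
  expect_equal(node_prediction(0, 0), 0.5)
  expect_equal(node_prediction(3, 10), 4 / 12)
  expect_equal(node_prediction(1000, 1000), 1001 / 1002)
  for (n in c(0, 1, 5, 17, 400)) {
    for (n1 in unique(round(seq(0, n, length.out = 5)))) {
      expect_identical(node_prediction(n1, n), (n1 + 1) / (n + 2))
    }
  }
  expect_error(node_prediction(5, 3), "n1 <= n")
  expect_error(node_prediction(-1, 3), "n1 <= n")
})

test_that("Youden split solves the worked examples", {
  s <- best_youden_split(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$youden_j, 1.0)
  # alternating labels: J = 0.5 at thresholds 1.5 and 3.5; tie -> 1.5
  s2 <- best_youden_split(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(s2$threshold, 1.5)
  expect_equal(s2$youden_j, 0.5)
  # constant values: no valid split
  expect_null(best_youden_split(rep(2, 5), c(0, 1, 0, 1, 1)))
  expect_error(best_youden_split(1:4, c(1, 1, 1, 1)), "both classes")
  # inverted orientation (low values positive) found via |J|
  s3 <- best_youden_split(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(s3$threshold, 2.5)
  expect_equal(s3$youden_j, 1.0)
  expect_lt(s3$j_signed, 0)
})

test_that("Youden split matches the exhaustive oracle on random instances", {
  withr::local_seed(202)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    vals <- if (rep %% 2 == 0) sample(1:8, n, replace = TRUE) else rnorm(n)
    labs <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labs)) < 2) labs[1:2] <- c(0, 1)
    got <- best_youden_split(vals, labs)
    want <- oracle_youden(vals, labs)
    if (is.null(want)) expect_null(got)
    else {
      expect_identical(got$threshold, want$threshold)
      expect_identical(got$youden_j, want$youden_j)
    }
  }
})

test_that("tree growth: separable, XOR, and forced-leaf termination", {
  mk <- function(x1, x2, y)
    tibble::tibble(patient_id = "p", i = seq_along(y), j = 1L, k = 1L,
                   dwi_norm = x1, adc = x2, mc_dwi = 0, mc_adc = 0, label = y)
  t1 <- build_tree(mk(c(1, 2, 3, 4), c(5, 5, 5, 5), c(0, 0, 1, 1)))
  expect_equal(t1$height, 1L)
  expect_equal(t1$n_nodes, 3L)
  expect_true(all(vapply(collect_nodes(t1),
                         function(nd) !nd$leaf || nd$n1 %in% c(0L, nd$n),
                         logical(1))))

  # XOR on two variables needs depth 2 and 4 pure leaves
  t2 <- build_tree(mk(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 1, 1, 0)))
  expect_equal(t2$height, 2L)
  leaves <- Filter(function(nd) nd$leaf, collect_nodes(t2))
  expect_equal(length(leaves), 4L)
  expect_true(all(vapply(leaves, function(nd) nd$n == 1L, logical(1))))

  # duplicate feature vectors with mixed labels: forced leaf, p = 0.5
  t3 <- build_tree(mk(c(1, 1), c(2, 2), c(0, 1)))
  expect_equal(t3$n_nodes, 1L)
  expect_true(t3$root$forced)
  expect_equal(t3$root$p, 0.5)
})

test_that("full-depth trees are pure (or forced) with exact conservation", {
  withr::local_seed(77)
  for (rep in 1:12) {
    n <- sample(50:600, 1)
    tbl <- random_feature_table(n, seed = 1000 + rep, signal = rep %% 2 == 0)
    tr <- build_tree(tbl)
    dup_conflict <- any(vapply(collect_nodes(tr),
                               function(nd) isTRUE(nd$forced), logical(1)))
    for (nd in collect_nodes(tr)) {
      expect_identical(nd$p, (nd$n1 + 1) / (nd$n + 2))
      if (!nd$leaf) {
        expect_identical(nd$ge$n + nd$lt$n, nd$n)
        expect_identical(nd$ge$n1 + nd$lt$n1, nd$n1)
        expect_gte(min(nd$ge$n, nd$lt$n), 1L)
      } else if (!nd$forced) {
        expect_true(nd$n1 == 0L || nd$n1 == nd$n)
      }
    }
    if (!dup_conflict) {
      expect_equal(auc(predict_at_depth(tr, tbl, tr$height), tbl$label), 1.0)
    }
  }
})

test_that("tree growth is deterministic", {
  tbl <- random_feature_table(300, seed = 5, signal = TRUE)
  t1 <- build_tree(tbl); t2 <- build_tree(tbl)
  expect_identical(tidy(t1), tidy(t2))
})

test_that("depth-indexed prediction clamps at leaves and matches traversal", {
  tbl <- random_feature_table(200, seed = 8)
  tr <- build_tree(tbl)
  X <- tbl
  expect_equal(predict_at_depth(tr, X, 0),
               rep(tr$root$p, nrow(X)))
  pfull <- predict_at_depth(tr, X, tr$height)
  expect_equal(predict_at_depth(tr, X, tr$height + 5), pfull)
  expect_equal(predict(tr, X), pfull)
  # hand-traced intermediate depth on a 3-level tree
  mk <- function(x1, y)
    tibble::tibble(patient_id = "p", i = seq_along(y), j = 1L, k = 1L,
                   dwi_norm = x1, adc = 0, mc_dwi = 0, mc_adc = 0, label = y)
  t3 <- build_tree(mk(c(1, 2, 3, 4, 5, 6, 7, 8), c(0, 0, 0, 0, 1, 1, 0, 0)))
  # root splits at 4.5 (J = 2/3, ge-side {5..8}); row with value 5:
  row <- mk(5, 1)
  expect_equal(predict_at_depth(t3, row, 0), t3$root$p)
  expect_equal(predict_at_depth(t3, row, 1), t3$root$ge$p)
  expect_error(predict_at_depth(tr, matrix(0, 2, 3), 1), "arity")
})

test_that("probability maps carry leaf values inside the brain mask only", {
  cs <- generate_case(quick_cfg(seed = 61, artifacts = 0L), 1)
  prep <- suppressMessages(preprocess_case(cs))
  tr <- build_tree(prep$features, max_depth = 6)
  m0 <- predict_map(tr, cs, d = 0, prep = prep)
  brain <- cs$brain_mask$data > 0.5
  expect_true(all(m0$data[brain] == tr$root$p))
  expect_true(all(m0$data[!brain] == 0))
  mfull <- predict_map(tr, cs, prep = prep)
  expect_true(all(mfull$data[brain] > 0 & mfull$data[brain] < 1))
})

test_that("tree JSON serialization round-trips predictions exactly", {
  dir <- withr::local_tempdir()
  tbl <- random_feature_table(250, seed = 13)
  tr <- build_tree(tbl, max_depth = 8)
  p <- file.path(dir, "tree.json")
  write_tree_json(tr, p)
  tr2 <- read_tree_json(p)
  expect_identical(predict_at_depth(tr2, tbl, tr2$height),
                   predict_at_depth(tr, tbl, tr$height))
  expect_identical(tidy(tr), tidy(tr2))
  expect_error(read_tree_json(file.path(dir, "missing.json")))
})
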