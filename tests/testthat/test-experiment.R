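test_that("stratified k-fold splits are disjoint, covering, balanced and seeded", {
  labs <- rep(c(0L, 1L), each = 5)
  folds <- kfold_split(labs, 5, seed = 3)
  expect_identical(sort(unlist(folds)), 1:10)
  expect_true(all(lengths(folds) == 2))
  expect_true(all(vapply(folds, function(f) length(unique(labs[f])), integer(1)) == 2))

  labs11 <- c(rep(0L, 6), rep(1L, 5))
  folds11 <- kfold_split(labs11, 5, seed = 3)
  expect_identical(sort(lengths(folds11), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  expect_identical(sort(unlist(folds11)), 1:11)

  expect_identical(kfold_split(labs, 5, seed = 9), kfold_split(labs, 5, seed = 9))
  expect_error(kfold_split(labs, 11), "k <= n")
  expect_error(kfold_split(labs, 1), "2 <= k")
})

test_that("every instance is tested exactly once per repeat", {
  set.seed(1)
  labs <- sample(c(0L, 1L), 23, replace = TRUE)
  for (r in 1:3) {
    folds <- kfold_split(labs, 4, seed = r)
    expect_identical(sort(unlist(folds)), seq_along(labs))
    expect_identical(sum(lengths(folds)), 23L)
  }
})

test_that("dunn test matches an independent closed-form rank computation", {
  samples <- list(a = c(0, 0, 0, 0), b = c(10, 10, 10, 10), c = c(20, 20, 20, 20))
  res <- dunn_test(samples)
  # independent route: pooled ranks, tie-corrected variance
  pooled <- unlist(samples)
  N <- length(pooled)
  rk <- rank(pooled)
  rbar <- c(mean(rk[1:4]), mean(rk[5:8]), mean(rk[9:12]))
  tie <- table(pooled)
  sg2 <- (N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1)))
  z_ab <- (rbar[1] - rbar[2]) / sqrt(sg2 * (1 / 4 + 1 / 4))
  z_ac <- (rbar[1] - rbar[3]) / sqrt(sg2 * (1 / 4 + 1 / 4))
  expect_equal(res$z["a", "b"], z_ab, tolerance = 1e-12)
  expect_equal(res$z["a", "c"], z_ac, tolerance = 1e-12)
  expect_equal(res$p["a", "b"], 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)
  # extreme pair has the smallest p
  off <- res$p[upper.tri(res$p)]
  expect_equal(min(off), res$p["a", "c"])
  expect_identical(unname(diag(res$p)), c(1, 1, 1))
  expect_true(isSymmetric(res$p))
})

test_that("dunn test reports unit p-values for identical groups", {
  res <- dunn_test(list(x = c(1, 2, 3), y = c(1, 2, 3), z = c(1, 2, 3)))
  expect_true(all(res$p == 1))
  expect_true(all(res$z == 0))
})

test_that("kruskal-wallis comparison matches the closed-form H statistic", {
  g1 <- c(1, 2, 3); g2 <- c(100, 101, 102)
  res <- compare_architectures(g1, g2)
  # closed form without ties
  rk <- rank(c(g1, g2)); N <- 6
  H <- 12 / (N * (N + 1)) * (3 * (mean(rk[1:3]) - (N + 1) / 2)^2 +
                             3 * (mean(rk[4:6]) - (N + 1) / 2)^2)
  expect_equal(unname(res$statistic), H, tolerance = 1e-12)
  expect_lt(res$p.value, 0.05)
  same <- compare_architectures(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  three <- compare_architectures(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(three$p.value, 1)
  expect_error(compare_architectures(c(1, 2, 3)), "at least two")
  expect_error(compare_architectures(c(1, 2, 3), 5), "at least 2 observations")
})

test_that("wilcoxon order comparison flags degenerate self-pairs", {
  r1 <- structure(list(error_rates = matrix(c(1, 2, 3, 4), 2)),
                  class = "experiment_result")
  res <- compare_orders(list(r1, r1))
  expect_equal(res$p[1, 2], 1)
  expect_true(res$degenerate[1, 2])
  # constant shift: all signed ranks on one side, small p
  r2 <- structure(list(error_rates = matrix(c(1, 2, 3, 4), 2) + 10),
                  class = "experiment_result")
  res2 <- compare_orders(list(r1, r2))
  expect_false(res2$degenerate[1, 2])
  w <- suppressWarnings(wilcox.test(c(1, 2, 3, 4), c(11, 12, 13, 14),
                                    paired = TRUE, exact = FALSE))
  expect_equal(res2$p[1, 2], w$p.value)
  expect_error(compare_orders(list(r1)), "at least two")
})

test_that("order comparison rejects near the nominal rate under the null", {
  # same-distribution error samples paired arbitrarily: rejection should be
  # rare (loose bound around the 5% level)
  set.seed(41)
  rejections <- 0L
  reps <- 40
  for (i in seq_len(reps)) {
    e1 <- matrix(rbinom(10, 20, 0.1) / 20 * 100, 2)
    e2 <- matrix(rbinom(10, 20, 0.1) / 20 * 100, 2)
    ra <- structure(list(error_rates = e1), class = "experiment_result")
    rb <- structure(list(error_rates = e2), class = "experiment_result")
    p <- compare_orders(list(ra, rb))$p[1, 2]
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / reps, 0.2)
})

test_that("run_condition bookkeeping: shapes, determinism, seed lineage", {
  d <- separable_dataset(n = 16, m = 2, seed = 37)
  tc <- quick_config(max_epochs = 3, patience = 2)
  r <- run_condition(d, condition("GASF", image_size = 16), tc,
                     repeats = 1, k = 2, base_seed = 5)
  expect_identical(dim(r$error_rates), c(1L, 2L))
  expect_true(all(r$error_rates >= 0 & r$error_rates <= 100))
  expect_equal(r$mean_error, mean(r$repeat_means))
  r2 <- run_condition(d, condition("GASF", image_size = 16), tc,
                      repeats = 1, k = 2, base_seed = 5)
  expect_identical(r$error_rates, r2$error_rates)
  expect_identical(r$seeds, r2$seeds)
  expect_false(any(is.na(r$seeds)))
})

test_that("report writes a deterministic per-fold CSV and a summary", {
  d <- separable_dataset(n = 16, m = 2, seed = 43)
  tc <- quick_config(max_epochs = 3, patience = 2)
  r <- run_condition(d, condition("GADF", image_size = 16), tc,
                     repeats = 2, k = 2, base_seed = 1)
  dir <- withr::local_tempdir()
  paths <- report_results(list(r, r), list(dunn = dunn_test(
    list(a = 1:4, b = 2:5))), dir)
  csv <- read.csv(file.path(dir, "results.csv"))
  expect_identical(nrow(csv), 2L * 2L * 2L)
  expect_true(all(c("encoder", "architecture", "order", "repeat_", "fold",
                    "error_rate") %in% names(csv)))
  before <- readBin(file.path(dir, "results.csv"), "raw", 1e6)
  report_results(list(r, r), list(), dir)
  after <- readBin(file.path(dir, "results.csv"), "raw", 1e6)
  expect_identical(before, after)
  report_results(list(), list(), dir)
  empty <- read.csv(file.path(dir, "results.csv"))
  expect_identical(nrow(empty), 0L)
  expect_identical(ncol(empty), 7L)
})
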