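# Confusion matrices, macro metrics, paired t-tests, noise and PSNR.

test_that("confusion matrix counts and validates correctly", {
  true <- rep(1:3, times = c(5, 3, 2))
  cm <- confusion_matrix(true, true, 3L)
  expect_equal(diag(cm), c(`1` = 5L, `2` = 3L, `3` = 2L),
               ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  # all predictions class 1 on balanced 2-class input of 10
  cm2 <- confusion_matrix(rep(1:2, each = 5), rep(1L, 10), 2L)
  ct <- cm_counts(cm2)
  expect_equal(ct[1, c("TP", "FP", "FN", "TN")],
               data.frame(TP = 5L, FP = 5L, FN = 0L, TN = 0L),
               ignore_attr = TRUE)

  set.seed(50)
  t3 <- sample(4L, 60, TRUE)
  p3 <- sample(4L, 60, TRUE)
  expect_equal(sum(confusion_matrix(t3, p3, 4L)), 60L)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 4L), "out of range")
})

test_that("per-class metrics match hand arithmetic and flag degeneracy", {
  cm <- confusion_matrix(rep(1:2, times = c(10, 10)),
                         c(rep(1L, 8), rep(2L, 2), rep(1L, 1), rep(2L, 9)),
                         2L)
  expect_equal(unclass(cm), matrix(c(8L, 1L, 2L, 9L), 2, 2),
               ignore_attr = TRUE)
  pc <- per_class_metrics(cm)
  expect_equal(pc$sensitivity[1], 80)
  expect_equal(pc$precision[1], 8 / 9 * 100, tolerance = 1e-12)

  cmp <- per_class_metrics(confusion_matrix(c(1, 1, 2), c(1, 1, 1), 3L))
  expect_true(is.na(cmp$sensitivity[3]))  # class 3 absent from truth
  expect_true(is.na(cmp$precision[2]))    # class 2 never predicted
  expect_false(anyNA(cmp$accuracy))       # accuracy defined through TN
  # perfect diagonal: every metric 100
  pd <- per_class_metrics(confusion_matrix(1:3, 1:3, 3L))
  expect_equal(unlist(pd[, -1]), rep(100, 9), ignore_attr = TRUE)
})

test_that("overall metrics are micro OA plus macro OS/OP", {
  set.seed(51)
  for (i in 1:10) {
    t <- sample(3L, 40, TRUE)
    p <- sample(3L, 40, TRUE)
    cm <- confusion_matrix(t, p, 3L)
    ov <- overall_metrics(cm)
    pc <- per_class_metrics(cm)
    expect_equal(ov$OA, 100 * mean(t == p), tolerance = 1e-12)
    expect_equal(ov$OS, mean(pc$sensitivity, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(ov$OP, mean(pc$precision, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("uniform random prediction scores near chance accuracy", {
  set.seed(52)
  t <- rep(1:4, each = 1500)
  p <- sample(4L, 6000, TRUE)
  ov <- overall_metrics(confusion_matrix(t, p, 4L))
  expect_lt(abs(ov$OA - 25), 2.5)
})

test_that("fold aggregation averages metrics (or pools matrices)", {
  r1 <- data.frame(OA = 90, OS = 80, OP = 85)
  r2 <- data.frame(OA = 92, OS = 84, OP = 87)
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(agg$OA, 91)
  expect_equal(agg$OS, 82)

  cms <- list(confusion_matrix(1:2, 1:2, 2L),
              confusion_matrix(c(1, 1), c(1, 2), 2L))
  pooled <- aggregate_folds(cms, mode = "pool")
  expect_equal(pooled$OA, 75)
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  set.seed(53)
  for (i in 1:20) {
    a <- rnorm(10, 90, 2)
    b <- a - rnorm(10, 1, 0.5)
    got <- paired_ttest(a, b)
    ref <- closed_form_ttest(a, b)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  }
  dg <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t))

  b <- rnorm(10, 85, 3)
  a <- b + 1 + runif(10, -0.01, 0.01)
  expect_lt(paired_ttest(a, b)$p_value, 1e-4)
  expect_error(paired_ttest(1:3, 1:4), "equal-length")
})

test_that("Gaussian noise is seeded, sized, and clipped correctly", {
  img <- matrix(0.5, 200, 200)
  expect_identical(add_gaussian_noise(img, 0), img)
  n1 <- add_gaussian_noise(img, 0.1, seed = 9L)
  n2 <- add_gaussian_noise(img, 0.1, seed = 9L)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_gaussian_noise(img, 0.1, seed = 10L)))
  expect_lt(abs(sd(n1 - img) - 0.1) / 0.1, 0.02)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(add_gaussian_noise(img, -1), "nonnegative")
})

test_that("PSNR follows its closed form and decreases with noise", {
  img <- matrix(128, 50, 50)
  expect_identical(psnr(img, img), Inf)
  off <- img + 16
  expect_equal(psnr(img, off, peak = 255), 10 * log10(255^2 / 256),
               tolerance = 1e-10)
  base <- matrix(runif(64 * 64), 64, 64)
  vals <- vapply(c(0.02, 0.05, 0.1, 0.2), function(s) {
    psnr(base, add_gaussian_noise(base, s, seed = 1L), peak = 1)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "same shape")
})

test_that("noise calibration reaches a requested mean PSNR", {
  set.seed(54)
  imgs <- lapply(1:10, function(i) matrix(runif(48 * 48), 48, 48))
  cal <- calibrate_noise_sigma(imgs, target_psnr = 30, seed = 2L,
                               tol = 0.05)
  expect_lt(abs(cal$mean_psnr - 30), 0.05 + 1e-9)
  expect_gt(cal$sigma, 0)
})

test_that("bundled benchmark fixtures load with reported overall metrics", {
  for (ds in c("oct2017", "srinivasan2014")) {
    ref <- reference_results(ds)
    expect_true(all(c("method", "class", "sensitivity", "precision",
                      "reported_os", "reported_op") %in% names(ref)))
    expect_equal(length(unique(ref$method)), 5L)
  }
  expect_equal(nrow(reference_results("oct2017")), 20L)
  expect_equal(nrow(reference_results("srinivasan2014")), 15L)
})
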