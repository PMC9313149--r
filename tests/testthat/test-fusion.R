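# Adaptive fusion, classification head, cross-entropy loss, and end-to-end
# differentiability.

test_that("equal fusion scores yield the midpoint; saturated scores pick a branch", {
  p <- zero_tree(fusion_init(4L))
  a <- matrix(rnorm(8), 2, 4)
  b <- matrix(rnorm(8), 2, 4)
  r <- fuse(a, b, p, return_weights = TRUE)
  expect_equal(r$weights[, 1, ], matrix(0.5, 2, 4))
  expect_equal(r$out, (a + b) / 2, tolerance = 1e-12)

  psat <- p
  psat$bt[] <- 50   # transformer-branch score saturates the softmax
  expect_equal(fuse(a, b, psat), a, tolerance = 1e-10)
})

test_that("fusion matches hand-computed two-way softmax at D = 2", {
  p <- fusion_init(2L)
  p$Wt <- matrix(c(1, 0, 0, -1), 2, 2); p$bt <- c(0.2, 0)
  p$Wc <- matrix(c(0.5, 0.5, 1, 0), 2, 2); p$bc <- c(0, -0.3)
  tf <- matrix(c(0.4, -0.2), 1, 2)
  cf <- matrix(c(1.1, 0.6), 1, 2)
  st <- as.numeric(tf %*% p$Wt) + p$bt
  sc <- as.numeric(cf %*% p$Wc) + p$bc
  wt <- exp(st) / (exp(st) + exp(sc))
  ref <- wt * tf[1, ] + (1 - wt) * cf[1, ]
  expect_equal(as.numeric(fuse(tf, cf, p)), ref, tolerance = 1e-12)
})

test_that("fused features are coordinatewise between the branch features", {
  set.seed(30)
  for (i in 1:10) {
    p <- fusion_init(6L)
    a <- matrix(rnorm(18, sd = 2), 3, 6)
    b <- matrix(rnorm(18, sd = 2), 3, 6)
    out <- fuse(a, b, p)
    expect_true(all(out >= pmin(a, b) - 1e-12))
    expect_true(all(out <= pmax(a, b) + 1e-12))
  }
  expect_error(fuse(matrix(0, 1, 3), matrix(0, 1, 4), fusion_init(3L)),
               "equal branch dimensions")
})

test_that("classification head produces normalized probabilities and argmax labels", {
  p <- zero_tree(head_init(5L, 4L))
  r <- classify(matrix(rnorm(20), 4, 5), p)
  expect_equal(r$probabilities, matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(r$labels, rep(1L, 4))  # uniform ties break to class 1

  # logits (2, 0, 0, 0): argmax class 1 with probability e^2/(e^2 + 3)
  p2 <- head_init(4L, 4L)
  p2$W <- diag(4) * 2
  p2$b <- numeric(4)
  r2 <- classify(matrix(c(1, 0, 0, 0), 1, 4), p2)
  expect_equal(r2$labels, 1L)
  expect_equal(r2$probabilities[1, 1], exp(2) / (exp(2) + 3),
               tolerance = 1e-12)

  set.seed(31)
  r3 <- classify(matrix(rnorm(40, sd = 5), 8, 5), head_init(5L, 4L))
  expect_lt(max(abs(rowSums(r3$probabilities) - 1)), 1e-6)
})

test_that("cross-entropy loss matches closed forms and validates its input", {
  g <- diag(4)[c(1, 2), ]
  perfect <- g
  expect_equal(cross_entropy_loss(perfect, g), 0, tolerance = 1e-9)
  uniform <- matrix(0.25, 2, 4)
  expect_equal(cross_entropy_loss(uniform, g), log(4), tolerance = 1e-12)

  p <- matrix(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3,
                0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE)
  expect_equal(cross_entropy_loss(p, g), (log(2) + log(4)) / 2,
               tolerance = 1e-12)

  bad <- g
  bad[1, ] <- c(0.5, 0.5, 0, 0)
  expect_error(cross_entropy_loss(uniform, bad), "one-hot")
})

test_that("one gradient step on a tiny batch reduces the loss", {
  set.seed(32)
  cfg <- tiny_cfg()
  p <- ns$init_hctnet_params(cfg)
  x <- array(rnorm(4 * 1 * 32 * 32), c(4, 1, 32, 32))
  g <- ns$one_hot(c(1L, 2L, 3L, 1L), 3L)
  fw <- ns$model_fwd(p, x, cfg)
  probs <- ns$softmax_rows(fw$logits)
  l0 <- cross_entropy_loss(probs, g)
  grads <- ns$model_bwd((probs - g) / 4, fw$cache, p, cfg)
  p2 <- ns$tree_map2(function(a, b) a - 0.01 * b, p, grads)
  l1 <- cross_entropy_loss(ns$softmax_rows(ns$model_fwd(p2, x, cfg)$logits), g)
  expect_lt(l1, l0)
})

test_that("every parameter group receives gradient on a random batch", {
  set.seed(33)
  cfg <- tiny_cfg()
  p <- ns$init_hctnet_params(cfg)
  x <- array(rnorm(2 * 1 * 32 * 32), c(2, 1, 32, 32))
  g <- ns$one_hot(c(2L, 3L), 3L)
  fw <- ns$model_fwd(p, x, cfg)
  probs <- ns$softmax_rows(fw$logits)
  grads <- ns$model_bwd((probs - g) / 2, fw$cache, p, cfg)
  for (group in c("llfe", "t_branch", "c_branch", "fusion", "head")) {
    leaves <- ns$flatten_params(grads[[group]])
    total <- sum(vapply(leaves, function(v) sum(abs(v)), numeric(1)))
    expect_gt(total, 0)
  }
})
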