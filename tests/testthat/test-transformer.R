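# Tokenization, attention, MLP, encoder blocks, transformer branch.

test_that("tokenize yields N + 1 tokens and honors the zero projection", {
  set.seed(10)
  emb <- embed_init(56, 56, 2, 7, 16)
  f <- array(rnorm(2 * 2 * 56 * 56), c(2, 2, 56, 56))
  z <- tokenize(f, emb)
  expect_identical(dim(z), c(2L, 65L, 16L))  # 56*56/49 + class token

  emb0 <- emb
  emb0$E[] <- 0
  emb0$Epos[] <- 0
  z0 <- tokenize(f, emb0)
  expect_equal(z0[1, 1, ], emb0$Eclass)
  expect_equal(z0[2, 1, ], emb0$Eclass)
  expect_equal(max(abs(z0[, -1, ])), 0)

  expect_error(tokenize(array(0, c(1, 2, 55, 55)), emb), "divisible")
})

test_that("tokenize matches a hand-computed projection on a 2x2 map", {
  # 2x2 feature map, 1 channel, P = 1: patch i is the single cell scanned
  # row-major, so patches are f[1,1], f[1,2], f[2,1], f[2,2].
  emb <- embed_init(2, 2, 1, 1, 3)
  emb$E <- matrix(c(1, 2, -1), 1, 3)
  emb$Eclass <- c(0.5, -0.5, 0.25)
  emb$Epos <- matrix(seq(0.1, 1.5, by = 0.1), 5, 3)
  f <- array(0, c(1, 1, 2, 2))
  f[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)  # rows x cols
  z <- tokenize(f, emb)
  vals <- c(f[1, 1, 1, 1], f[1, 1, 1, 2], f[1, 1, 2, 1], f[1, 1, 2, 2])
  for (i in 1:4) {
    expect_equal(z[1, i + 1, ], vals[i] * emb$E[1, ] + emb$Epos[i + 1, ],
                 tolerance = 1e-12)
  }
  expect_equal(z[1, 1, ], emb$Eclass + emb$Epos[1, ], tolerance = 1e-12)
})

test_that("single-head attention matches the brute-force oracle", {
  set.seed(11)
  p <- encoder_init(4L, 1L)$attn
  for (nm in names(p)) p[[nm]][] <- rnorm(length(p[[nm]]), sd = 0.5)
  Z <- matrix(rnorm(3 * 4), 3, 4)
  z <- array(0, c(1, 3, 4))
  z[1, , ] <- Z
  got <- msa(z, p, h = 1L)
  expect_equal(got[1, , ], brute_attention(Z, p), tolerance = 1e-10)

  # identical tokens: every attention row is uniform
  zc <- array(0, c(1, 5, 4))
  zc[1, , ] <- matrix(rep(rnorm(4), each = 5), 5, 4)
  at <- msa(zc, p, h = 1L, return_attention = TRUE)
  expect_equal(at$attention[[1]][[1]],
               matrix(1 / 5, 5, 5), tolerance = 1e-10)
})

test_that("attention rows sum to one for random inputs, all heads", {
  set.seed(12)
  p <- encoder_init(8L, 2L)$attn
  for (i in 1:5) {
    z <- array(rnorm(2 * 6 * 8), c(2, 6, 8))
    at <- msa(z, p, h = 2L, return_attention = TRUE)
    for (b in 1:2) {
      for (hd in 1:2) {
        expect_lt(max(abs(rowSums(at$attention[[b]][[hd]]) - 1)), 1e-6)
      }
    }
  }
  expect_error(msa(array(0, c(1, 3, 8)), p, h = 3L), "divisible")
})

test_that("token-wise MLP matches direct matrix arithmetic", {
  p <- list(W1 = matrix(0, 2, 4), b1 = numeric(4),
            W2 = matrix(0, 4, 2), b2 = numeric(2))
  z <- array(rnorm(1 * 3 * 2), c(1, 3, 2))
  expect_equal(max(abs(mlp(z, p))), 0)

  # scalar identity-weight reduction: output = GELU(input)
  ps <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0)
  zs <- array(c(-1.3, 0.4, 2.1), c(1, 3, 1))
  expect_equal(as.numeric(mlp(zs, ps)),
               as.numeric(zs) * pnorm(as.numeric(zs)), tolerance = 1e-12)

  set.seed(13)
  pr <- list(W1 = matrix(rnorm(2 * 4), 2, 4), b1 = rnorm(4),
             W2 = matrix(rnorm(4 * 2), 4, 2), b2 = rnorm(2))
  zr <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  got <- mlp(zr, pr)
  for (b in 1:2) {
    for (t in 1:3) {
      x <- zr[b, t, ]
      h <- as.numeric(x %*% pr$W1) + pr$b1
      ref <- as.numeric((h * pnorm(h)) %*% pr$W2) + pr$b2
      expect_equal(got[b, t, ], ref, tolerance = 1e-12)
    }
  }
})

test_that("encoder block with zeroed weights is the identity", {
  p <- encoder_init(8L, 2L)
  p$attn <- zero_tree(p$attn)
  p$mlp <- zero_tree(p$mlp)
  z <- array(rnorm(2 * 5 * 8), c(2, 5, 8))
  expect_equal(encoder_forward(z, p, h = 2L), z, tolerance = 1e-12)
})

test_that("encoder block matches a scalar hand-unrolled evaluation", {
  # one token, D = 1: LN maps any scalar to beta (the centered value is 0),
  # single-token softmax weight is 1, so the block reduces to closed form.
  p <- encoder_init(1L, 1L, K_mlp = 1L)
  p$ln1$gamma <- 2; p$ln1$beta <- 0.3
  p$ln2$gamma <- -1; p$ln2$beta <- 0.7
  for (nm in names(p$attn)) p$attn[[nm]][] <- 0.5
  p$mlp <- list(W1 = matrix(1.5, 1, 1), b1 = 0.2,
                W2 = matrix(-0.8, 1, 1), b2 = 0.1)
  x <- 1.234
  n1 <- p$ln1$beta                       # LN of a lone scalar
  v <- n1 * 0.5 + 0.5                    # value head on the normed token
  att <- v * 0.5 + 0.5                   # output projection (weight 1 row)
  z1 <- x + att
  n2 <- p$ln2$beta
  h <- n2 * 1.5 + 0.2
  mlp_out <- (h * pnorm(h)) * -0.8 + 0.1
  expected <- z1 + mlp_out
  z <- array(x, c(1, 1, 1))
  expect_equal(as.numeric(encoder_forward(z, p, h = 1L)), expected,
               tolerance = 1e-9)
})

test_that("token shape is preserved through all twelve encoder blocks", {
  set.seed(14)
  cfg <- hctnet_config("full")
  z <- array(rnorm(1 * 65 * cfg$D), c(1, 65, cfg$D))
  layers <- lapply(1:12, function(i) encoder_init(cfg$D, cfg$h, cfg$K_mlp))
  cur <- z
  for (l in 1:12) {
    cur <- encoder_forward(cur, layers[[l]], h = cfg$h)
    expect_identical(dim(cur), dim(z))
  }
  expect_true(all(is.finite(cur)))
})

test_that("transformer branch output is (batch, D) and zeroes out cleanly", {
  set.seed(15)
  p <- t_branch_init(8, 8, 2, 2, 12, 2, 2)
  f <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  y <- t_branch_forward(f, p, h = 2L)
  expect_identical(dim(y), c(3L, 12L))

  pz <- zero_tree(p)
  pz$ln_f$gamma <- rep(1, 12)
  y0 <- t_branch_forward(f, pz, h = 2L)
  expect_equal(max(abs(y0)), 0)  # LN of the zero vector is zero
})

test_that("transformer branch equals the explicit composition at L = 1", {
  set.seed(16)
  p <- t_branch_init(4, 4, 1, 2, 6, 2, 1)
  f <- array(rnorm(2 * 1 * 4 * 4), c(2, 1, 4, 4))
  y <- t_branch_forward(f, p, h = 2L)
  z <- tokenize(f, p$embed)
  z <- encoder_forward(z, p$layers[[1]], h = 2L)
  cls <- z[, 1, ]
  ref <- ns$layernorm_fwd(cls, p$ln_f$gamma, p$ln_f$beta, 1e-6)$out
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("position table is the sole carrier of patch-order information", {
  set.seed(17)
  p <- t_branch_init(4, 4, 1, 2, 6, 2, 1)
  f <- array(rnorm(1 * 1 * 4 * 4), c(1, 1, 4, 4))
  # permute the four 2x2 patches (swap quadrants)
  fp <- f
  fp[1, 1, 1:2, 1:2] <- f[1, 1, 3:4, 3:4]
  fp[1, 1, 3:4, 3:4] <- f[1, 1, 1:2, 1:2]
  expect_gt(max(abs(t_branch_forward(f, p, h = 2L) -
                      t_branch_forward(fp, p, h = 2L))), 1e-8)

  # with a zero position table the class-token representation is invariant
  # to patch order (self-attention is permutation-equivariant)
  p0 <- p
  p0$embed$Epos[] <- 0
  expect_equal(t_branch_forward(f, p0, h = 2L),
               t_branch_forward(fp, p0, h = 2L), tolerance = 1e-10)
})
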