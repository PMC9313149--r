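# Independent reference implementations used as oracles. These are written
# as plain elementwise loops, deliberately sharing no code with the package
# internals they check.

ns <- asNamespace("hctnet")

tiny_cfg <- function(...) {
  hctnet_config("reduced", image_size = 32L, stem_channels = 2L,
                growth = 2L, P = 2L, D = 8L, h = 2L, L = 1L,
                K_mlp = 16L, n_classes = 3L, ...)
}

# Naive single-image 2D convolution (zero padding, stride 1), weight array
# (Cout, Cin, kh, kw), image array (Cin, H, W).
naive_conv2d <- function(img, W, b) {
  kd <- dim(W)
  d <- dim(img)
  pad <- (kd[3] - 1) %/% 2
  out <- array(0, c(kd[1], d[2], d[3]))
  for (co in seq_len(kd[1])) {
    for (r in seq_len(d[2])) {
      for (cc in seq_len(d[3])) {
        acc <- b[co]
        for (ci in seq_len(kd[2])) {
          for (ki in seq_len(kd[3])) {
            for (kj in seq_len(kd[4])) {
              rr <- r + ki - 1 - pad
              cj <- cc + kj - 1 - pad
              if (rr >= 1 && rr <= d[2] && cj >= 1 && cj <= d[3]) {
                acc <- acc + W[co, ci, ki, kj] * img[ci, rr, cj]
              }
            }
          }
        }
        out[co, r, cc] <- acc
      }
    }
  }
  out
}

naive_lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)

# Naive residual dense block on one image (Cin, H, W), mirroring the
# documented wiring: three conv+LReLU blocks with dense concatenation,
# 1x1 fusion back to Cin, residual sum.
naive_rdb <- function(img, params, slope) {
  o1 <- naive_lrelu(naive_conv2d(img, params$conv1$W, params$conv1$b),
                    slope)
  cat2 <- abind2(img, o1)
  o2 <- naive_lrelu(naive_conv2d(cat2, params$conv2$W, params$conv2$b),
                    slope)
  cat3 <- abind2(cat2, o2)
  o3 <- naive_lrelu(naive_conv2d(cat3, params$conv3$W, params$conv3$b),
                    slope)
  cat4 <- abind2(cat3, o3)
  img + naive_conv2d(cat4, params$fuse$W, params$fuse$b)
}

abind2 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

naive_maxpool <- function(img, p = 2) {
  d <- dim(img)
  out <- array(0, c(d[1], d[2] %/% p, d[3] %/% p))
  for (c in seq_len(d[1])) {
    for (r in seq_len(d[2] %/% p)) {
      for (cc in seq_len(d[3] %/% p)) {
        out[c, r, cc] <- max(img[c, (r - 1) * p + seq_len(p),
                                 (cc - 1) * p + seq_len(p)])
      }
    }
  }
  out
}

# Brute-force single-head attention on one token matrix Z ((N+1) x D):
# explicit Q/K/V, explicit softmax per row, explicit weighted sum, output
# projection.
brute_attention <- function(Z, p) {
  D <- ncol(Z)
  Q <- Z %*% p$Wq + matrix(p$bq, nrow(Z), D, byrow = TRUE)
  K <- Z %*% p$Wk + matrix(p$bk, nrow(Z), D, byrow = TRUE)
  V <- Z %*% p$Wv + matrix(p$bv, nrow(Z), D, byrow = TRUE)
  O <- matrix(0, nrow(Z), D)
  for (i in seq_len(nrow(Z))) {
    s <- numeric(nrow(Z))
    for (j in seq_len(nrow(Z))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(D)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(nrow(Z))) O[i, ] <- O[i, ] + w[j] * V[j, ]
  }
  O %*% p$Wo + matrix(p$bo, nrow(Z), D, byrow = TRUE)
}

# Per-pixel bilinear resize oracle (center-aligned, clamped edges); valid
# as a reference when upscaling, where no anti-alias filter is involved.
naive_bilinear <- function(img, oh, ow) {
  ih <- nrow(img); iw <- ncol(img)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    sy <- (i - 0.5) * ih / oh - 0.5
    y0 <- floor(sy); fy <- sy - y0
    y0c <- min(max(y0, 0), ih - 1); y1c <- min(max(y0 + 1, 0), ih - 1)
    for (j in seq_len(ow)) {
      sx <- (j - 0.5) * iw / ow - 0.5
      x0 <- floor(sx); fx <- sx - x0
      x0c <- min(max(x0, 0), iw - 1); x1c <- min(max(x0 + 1, 0), iw - 1)
      out[i, j] <-
        (1 - fy) * ((1 - fx) * img[y0c + 1, x0c + 1] +
                      fx * img[y0c + 1, x1c + 1]) +
        fy * ((1 - fx) * img[y1c + 1, x0c + 1] +
                fx * img[y1c + 1, x1c + 1])
    }
  }
  out
}

# Zero every numeric leaf of a parameter tree.
zero_tree <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, zero_tree)
}

# Closed-form paired t statistic and two-sided p.
closed_form_ttest <- function(a, b) {
  d <- a - b
  k <- length(d)
  t <- mean(d) / (sd(d) / sqrt(k))
  list(t = t, p = 2 * pt(-abs(t), df = k - 1))
}
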