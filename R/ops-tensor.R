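# Low-level differentiable primitives. Feature maps are R arrays with dim
# (batch, channels, rows, cols); token blocks are matrices with one row per
# token. Every *_fwd returns list(out, cache); every *_bwd consumes the
# upstream gradient plus that cache and returns input/parameter gradients.
# Convolution is expressed as a single BLAS product over the im2col matrix
# (built in C++); pooling argmaxes are tracked in C++ for the backward pass.

conv2d_fwd <- function(x, W, b, pad = 1L, stride = 1L) {
  d <- dim(x)
  kd <- dim(W)
  if (d[2] != kd[2]) {
    stop(sprintf("conv2d: input has %d channels but kernel expects %d",
                 d[2], kd[2]), call. = FALSE)
  }
  Xt <- im2col_cpp(x, d[1], d[2], d[3], d[4], kd[3], kd[4], pad, stride)
  out_t <- tcrossprod(Xt, matrix(W, nrow = kd[1]))
  out_t <- out_t + rep(b, each = nrow(out_t))
  Ho <- (d[3] + 2L * pad - kd[3]) %/% stride + 1L
  Wo <- (d[4] + 2L * pad - kd[4]) %/% stride + 1L
  list(out = mat_to_nchw_cpp(out_t, d[1], kd[1], Ho, Wo),
       cache = list(dims = d, Xt = Xt, pad = pad, stride = stride))
}

conv2d_bwd <- function(dout, cache, W) {
  d <- cache$dims
  kd <- dim(W)
  do_ <- dim(dout)
  dout_t <- nchw_to_mat_cpp(dout, do_[1], do_[2], do_[3], do_[4])
  Xt <- cache$Xt
  dW <- array(crossprod(dout_t, Xt), dim = kd)
  db <- colSums(dout_t)
  dXt <- dout_t %*% matrix(W, nrow = kd[1])
  dx <- col2im_cpp(dXt, d[1], d[2], d[3], d[4], kd[3], kd[4],
                   cache$pad, cache$stride)
  list(dx = dx, dW = dW, db = db)
}

lrelu_fwd <- function(x, slope) {
  out <- x
  neg <- x < 0
  out[neg] <- slope * x[neg]
  list(out = out, cache = neg)
}

lrelu_bwd <- function(dout, neg, slope) {
  dx <- dout
  dx[neg] <- slope * dout[neg]
  dx
}

maxpool_fwd <- function(x, window = 2L, stride = window) {
  d <- dim(x)
  r <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4], window, window, stride)
  list(out = r$out, cache = list(idx = r$idx, dims = d))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$dims
  maxpool_bwd_cpp(dout, cache$idx, d[1], d[2], d[3], d[4])
}

linear_fwd <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(X))
  list(out = out, cache = X)
}

linear_bwd <- function(dout, X, W, has_bias = TRUE) {
  list(dX = tcrossprod(dout, W), dW = crossprod(X, dout),
       db = if (has_bias) colSums(dout) else NULL)
}

# Layer normalization across the feature (last) dimension of a token matrix.
# A zero row maps to a zero row: the epsilon keeps 1/sqrt finite.
layernorm_fwd <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  out <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- dout * rep(gamma, each = nrow(dout))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dgamma = colSums(dout * xhat), dbeta = colSums(dout))
}

# Numerically stabilized row-wise softmax (max subtracted before exp).
softmax_rows <- function(X) {
  X <- X - apply(X, 1L, max)
  E <- exp(X)
  E / rowSums(E)
}

# Exact (erf-based) GELU, sigma(x) = x * Phi(x).
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Xavier/Glorot uniform initialization with explicit fan counts.
xavier_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

xavier_conv <- function(c_out, c_in, kh, kw = kh) {
  xavier_init(c(c_out, c_in, kh, kw), c_in * kh * kw, c_out * kh * kw)
}

xavier_linear <- function(d_in, d_out) {
  xavier_init(c(d_in, d_out), d_in, d_out)
}

# Truncated-normal (|z| <= 2) draws used for class-token and position tables,
# where Xavier fans are ill-defined.
trunc_normal <- function(n, std = 0.02) {
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > 2)) z[bad] <- stats::rnorm(sum(bad))
  z * std
}
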