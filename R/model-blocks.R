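# Residual dense block (RDB) and the low-level feature extraction (LLFE)
# stem. An RDB holds three 3x3 conv + leaky-ReLU blocks wired densely (block
# j sees the block input concatenated with every earlier block output),
# followed by a 1x1 fusion convolution that maps the full concatenation back
# to the input channel count so the residual sum is well defined.

cat_ch <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[2L], integer(1))
  out <- array(0, c(d[1L], sum(cs), d[3L], d[4L]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, at + seq_len(cs[i]), , ] <- xs[[i]]
    at <- at + cs[i]
  }
  out
}

split_ch <- function(x, counts) {
  at <- 0L
  lapply(counts, function(ci) {
    seg <- x[, at + seq_len(ci), , , drop = FALSE]
    at <<- at + ci
    seg
  })
}

check_feature_map <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(sprintf("%s must be a rank-4 (batch, channels, rows, cols) array",
                 name), call. = FALSE)
  }
  invisible(x)
}

#' Initialize residual dense block parameters
#'
#' Creates Xavier-initialized weights for one residual dense block: three
#' densely connected 3x3 convolutional blocks (each followed by a leaky
#' rectifier) plus a 1x1 fusion convolution that returns to `channels` so
#' the residual connection can add the block input to the fused output.
#'
#' @param channels Input (= output) channel count of the block.
#' @param growth Channels produced by each internal convolutional block.
#' @param kernel Spatial kernel size of the internal convolutions.
#' @return A named list of convolution parameter sets (`conv1..conv3`,
#'   `fuse`), each holding a weight array `W` of shape
#'   (out, in, kernel, kernel) and a bias vector `b`.
#' @export
rdb_init <- function(channels, growth = channels, kernel = 3L) {
  list(
    conv1 = list(W = xavier_conv(growth, channels, kernel),
                 b = numeric(growth)),
    conv2 = list(W = xavier_conv(growth, channels + growth, kernel),
                 b = numeric(growth)),
    conv3 = list(W = xavier_conv(growth, channels + 2L * growth, kernel),
                 b = numeric(growth)),
    fuse = list(W = xavier_conv(channels, channels + 3L * growth, 1L),
                b = numeric(channels))
  )
}

rdb_fwd <- function(x, params, slope) {
  cin <- dim(x)[2L]
  if (dim(params$fuse$W)[1L] != cin) {
    stop(sprintf(paste0("RDB fuse layer emits %d channels but the residual ",
                        "input has %d: residual addends must match"),
                 dim(params$fuse$W)[1L], cin), call. = FALSE)
  }
  pad <- (dim(params$conv1$W)[3L] - 1L) %/% 2L
  c1 <- conv2d_fwd(x, params$conv1$W, params$conv1$b, pad = pad)
  a1 <- lrelu_fwd(c1$out, slope)
  in2 <- cat_ch(list(x, a1$out))
  c2 <- conv2d_fwd(in2, params$conv2$W, params$conv2$b, pad = pad)
  a2 <- lrelu_fwd(c2$out, slope)
  in3 <- cat_ch(list(x, a1$out, a2$out))
  c3 <- conv2d_fwd(in3, params$conv3$W, params$conv3$b, pad = pad)
  a3 <- lrelu_fwd(c3$out, slope)
  inf_ <- cat_ch(list(x, a1$out, a2$out, a3$out))
  cf <- conv2d_fwd(inf_, params$fuse$W, params$fuse$b, pad = 0L)
  list(out = x + cf$out,
       cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                    a2 = a2$cache, c3 = c3$cache, a3 = a3$cache,
                    cf = cf$cache, cin = cin,
                    growth = dim(params$conv1$W)[1L], slope = slope))
}

rdb_bwd <- function(dout, cache, params) {
  cin <- cache$cin
  g <- cache$growth
  slope <- cache$slope
  gf <- conv2d_bwd(dout, cache$cf, params$fuse$W)
  parts <- split_ch(gf$dx, c(cin, g, g, g))
  dx <- dout + parts[[1L]]
  do3 <- lrelu_bwd(parts[[4L]], cache$a3, slope)
  g3 <- conv2d_bwd(do3, cache$c3, params$conv3$W)
  parts3 <- split_ch(g3$dx, c(cin, g, g))
  dx <- dx + parts3[[1L]]
  do2 <- lrelu_bwd(parts[[3L]] + parts3[[3L]], cache$a2, slope)
  g2 <- conv2d_bwd(do2, cache$c2, params$conv2$W)
  parts2 <- split_ch(g2$dx, c(cin, g))
  dx <- dx + parts2[[1L]]
  do1 <- lrelu_bwd(parts[[2L]] + parts3[[2L]] + parts2[[2L]], cache$a1, slope)
  g1 <- conv2d_bwd(do1, cache$c1, params$conv1$W)
  dx <- dx + g1$dx
  list(dx = dx,
       grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    conv3 = list(W = g3$dW, b = g3$db),
                    fuse = list(W = gf$dW, b = gf$db)))
}

#' Apply a residual dense block
#'
#' Runs one residual dense block forward: three densely connected
#' convolution + leaky-ReLU blocks, a 1x1 fusion convolution over the
#' concatenation of the input and all block outputs, and a residual sum
#' with the input. Output shape equals input shape; with all weights and
#' biases at zero the block is exactly the identity map.
#'
#' @param x Rank-4 feature map array (batch, channels, rows, cols).
#' @param params Parameters from [rdb_init()].
#' @param slope Negative-region slope of the leaky rectifier.
#' @return Feature map with the same shape as `x`.
#' @examples
#' p <- rdb_init(2, growth = 2)
#' x <- array(rnorm(2 * 2 * 8 * 8), c(2, 2, 8, 8))
#' dim(rdb_forward(x, p))
#' @export
rdb_forward <- function(x, params, slope = 0.2) {
  check_feature_map(x)
  rdb_fwd(x, params, slope)$out
}

#' Initialize the low-level feature extraction stem
#'
#' The LLFE stem is one convolutional layer followed by two residual dense
#' blocks, each trailed by 2x2 max pooling, so the output spatial size is
#' the input size divided by four.
#'
#' @param in_channels Image channel count (1 for grayscale OCT).
#' @param stem_channels Channel count after the stem convolution and
#'   through both residual dense blocks.
#' @param growth Growth rate of the residual dense blocks.
#' @param kernel Convolution kernel size.
#' @return Named parameter list (`stem`, `rdb1`, `rdb2`).
#' @export
llfe_init <- function(in_channels = 1L, stem_channels = 32L,
                      growth = stem_channels, kernel = 3L) {
  list(stem = list(W = xavier_conv(stem_channels, in_channels, kernel),
                   b = numeric(stem_channels)),
       rdb1 = rdb_init(stem_channels, growth, kernel),
       rdb2 = rdb_init(stem_channels, growth, kernel))
}

llfe_fwd <- function(x, params, slope, stem_activation = TRUE) {
  d <- dim(x)
  if (d[3L] %% 4L != 0L || d[4L] %% 4L != 0L) {
    stop(sprintf(paste0("LLFE input spatial size %dx%d must be divisible ",
                        "by 4 (two 2x2 poolings)"), d[3L], d[4L]),
         call. = FALSE)
  }
  pad <- (dim(params$stem$W)[3L] - 1L) %/% 2L
  st <- conv2d_fwd(x, params$stem$W, params$stem$b, pad = pad)
  act <- if (stem_activation) lrelu_fwd(st$out, slope) else
    list(out = st$out, cache = NULL)
  r1 <- rdb_fwd(act$out, params$rdb1, slope)
  p1 <- maxpool_fwd(r1$out)
  r2 <- rdb_fwd(p1$out, params$rdb2, slope)
  p2 <- maxpool_fwd(r2$out)
  list(out = p2$out,
       cache = list(st = st$cache, act = act$cache, r1 = r1$cache,
                    p1 = p1$cache, r2 = r2$cache, p2 = p2$cache,
                    slope = slope, stem_activation = stem_activation))
}

llfe_bwd <- function(dout, cache, params) {
  d2 <- maxpool_bwd(dout, cache$p2)
  b2 <- rdb_bwd(d2, cache$r2, params$rdb2)
  d1 <- maxpool_bwd(b2$dx, cache$p1)
  b1 <- rdb_bwd(d1, cache$r1, params$rdb1)
  da <- if (cache$stem_activation)
    lrelu_bwd(b1$dx, cache$act, cache$slope) else b1$dx
  gs <- conv2d_bwd(da, cache$st, params$stem$W)
  list(dx = gs$dx,
       grads = list(stem = list(W = gs$dW, b = gs$db),
                    rdb1 = b1$grads, rdb2 = b2$grads))
}

#' Run the low-level feature extraction stem
#'
#' Applies stem convolution (with leaky-ReLU unless disabled), then
#' RDB -> max pool -> RDB -> max pool. Spatial dimensions shrink by a
#' factor of four; the channel count equals the stem width.
#'
#' @inheritParams rdb_forward
#' @param params Parameters from [llfe_init()].
#' @param stem_activation Apply a leaky rectifier after the stem
#'   convolution (the default).
#' @return Feature map of shape (batch, stem_channels, rows/4, cols/4).
#' @export
llfe_forward <- function(x, params, slope = 0.2, stem_activation = TRUE) {
  check_feature_map(x)
  llfe_fwd(x, params, slope, stem_activation)$out
}
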