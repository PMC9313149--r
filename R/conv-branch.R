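# ConvNet branch: three residual dense blocks alternating with 2x2 max
# pooling, then global average pooling and a fully connected projection to
# the shared branch dimension D, producing the local-feature representation.

#' Initialize the convolutional branch
#'
#' @param channels Channel count of the incoming feature map (kept constant
#'   across all three stages).
#' @param growth Growth rate of the residual dense blocks.
#' @param D Output dimension (must match the transformer branch).
#' @param kernel Convolution kernel size.
#' @return Parameter list (`rdb1`, `rdb2`, `rdb3`, `fc`).
#' @export
c_branch_init <- function(channels, growth = channels, D, kernel = 3L) {
  list(rdb1 = rdb_init(channels, growth, kernel),
       rdb2 = rdb_init(channels, growth, kernel),
       rdb3 = rdb_init(channels, growth, kernel),
       fc = list(W = xavier_linear(channels, D), b = numeric(D)))
}

gap_fwd <- function(x) {
  d <- dim(x)
  out <- matrix(rowMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])),
                d[1L], d[2L])
  list(out = out, cache = d)
}

gap_bwd <- function(dout, d) {
  array(rep(as.vector(dout) / (d[3L] * d[4L]), d[3L] * d[4L]), d)
}

c_branch_fwd <- function(f, params, slope) {
  d <- dim(f)
  if (d[3L] %% 8L != 0L || d[4L] %% 8L != 0L) {
    stop(sprintf(paste0("C-branch input spatial size %dx%d must be ",
                        "divisible by 8 (three 2x2 poolings)"),
                 d[3L], d[4L]), call. = FALSE)
  }
  r1 <- rdb_fwd(f, params$rdb1, slope)
  p1 <- maxpool_fwd(r1$out)
  r2 <- rdb_fwd(p1$out, params$rdb2, slope)
  p2 <- maxpool_fwd(r2$out)
  r3 <- rdb_fwd(p2$out, params$rdb3, slope)
  p3 <- maxpool_fwd(r3$out)
  gp <- gap_fwd(p3$out)
  fc <- linear_fwd(gp$out, params$fc$W, params$fc$b)
  list(out = fc$out,
       cache = list(r1 = r1$cache, p1 = p1$cache, r2 = r2$cache,
                    p2 = p2$cache, r3 = r3$cache, p3 = p3$cache,
                    gp = gp$cache, fc = fc$cache))
}

c_branch_bwd <- function(dout, cache, params) {
  gfc <- linear_bwd(dout, cache$fc, params$fc$W)
  dgp <- gap_bwd(gfc$dX, cache$gp)
  d3 <- maxpool_bwd(dgp, cache$p3)
  b3 <- rdb_bwd(d3, cache$r3, params$rdb3)
  d2 <- maxpool_bwd(b3$dx, cache$p2)
  b2 <- rdb_bwd(d2, cache$r2, params$rdb2)
  d1 <- maxpool_bwd(b2$dx, cache$p1)
  b1 <- rdb_bwd(d1, cache$r1, params$rdb1)
  list(df = b1$dx,
       grads = list(rdb1 = b1$grads, rdb2 = b2$grads, rdb3 = b3$grads,
                    fc = list(W = gfc$dW, b = gfc$db)))
}

#' Run the convolutional branch
#'
#' Applies (residual dense block -> 2x2 max pool) three times, global
#' average pooling over the remaining spatial grid, and a linear projection
#' to the branch dimension D. With all weights at zero the output equals
#' the fully connected bias vector.
#'
#' @param f Rank-4 feature map (batch, channels, rows, cols), spatial size
#'   divisible by 8.
#' @param params Parameters from [c_branch_init()].
#' @param slope Leaky-rectifier slope.
#' @return Matrix (batch, D).
#' @export
c_branch_forward <- function(f, params, slope = 0.2) {
  check_feature_map(f)
  c_branch_fwd(f, params, slope)$out
}
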