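# Transformer branch: patch tokenization of the LLFE feature map, a stack of
# pre-norm encoder blocks (multi-head self-attention + token-wise MLP, each
# with a residual connection), and a final layer norm of the class token.
#
# Token blocks travel internally as matrices with rows ordered batch-fastest
# (row of token t in sample b is b + B*(t-1)); arrays of dim (B, N+1, D) are
# only materialized at the public boundaries.
#
# Patch serialization convention (fixed; checkpoints depend on it): patches
# are scanned row-major over the patch grid, and within a patch the vector
# runs channel-fastest, then column, then row.

#' Initialize a patch embedding
#'
#' Builds the learnable tokenization parameters: the linear projection `E`
#' from flattened patches (length `P^2 * C`) to `D`-dimensional embeddings,
#' the class token `Eclass`, and the position table `Epos` with `N + 1`
#' rows where `N = (H/P) * (W/P)`.
#'
#' `E` uses Xavier initialization; `Eclass` and `Epos` use truncated-normal
#' draws (sd 0.02), since Xavier fans are not defined for token tables.
#'
#' @param H,W Spatial size of the incoming feature map.
#' @param C Channel count of the incoming feature map.
#' @param P Patch side length; must divide `H` and `W`.
#' @param D Embedding dimension.
#' @return List with the learnable arrays `E` (`(P^2 C) x D`), `Eclass`
#'   (length `D`) and `Epos` (`(N+1) x D`). The patch size is implied by
#'   the shape of `E` relative to the incoming channel count.
#' @export
embed_init <- function(H, W, C, P, D) {
  if (H %% P != 0L || W %% P != 0L) {
    stop(sprintf("feature map %dx%d is not divisible by patch size %d",
                 H, W, P), call. = FALSE)
  }
  N <- (H %/% P) * (W %/% P)
  list(E = xavier_linear(P * P * C, D),
       Eclass = trunc_normal(D),
       Epos = matrix(trunc_normal((N + 1L) * D), N + 1L, D))
}

# The patch side length is implied by nrow(E) = P^2 * C.
embed_patch_size <- function(emb, C) {
  P <- sqrt(nrow(emb$E) / C)
  if (abs(P - round(P)) > 1e-9) {
    stop(sprintf(paste0("embedding expects %d values per patch, which is ",
                        "not a square patch over %d channels"),
                 nrow(emb$E), C), call. = FALSE)
  }
  as.integer(round(P))
}

patches_to_matrix <- function(f, P) {
  d <- dim(f)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  nr <- H %/% P; nc <- W %/% P
  N <- nr * nc
  fp <- matrix(0, B * N, P * P * C)
  for (pr in seq_len(nr)) {
    for (pc in seq_len(nc)) {
      i <- (pr - 1L) * nc + pc
      block <- f[, , (pr - 1L) * P + seq_len(P),
                 (pc - 1L) * P + seq_len(P), drop = FALSE]
      fp[(i - 1L) * B + seq_len(B), ] <-
        matrix(aperm(block, c(1L, 2L, 4L, 3L)), nrow = B)
    }
  }
  fp
}

matrix_to_patches <- function(fp, B, C, H, W, P) {
  nr <- H %/% P; nc <- W %/% P
  f <- array(0, c(B, C, H, W))
  for (pr in seq_len(nr)) {
    for (pc in seq_len(nc)) {
      i <- (pr - 1L) * nc + pc
      block <- array(fp[(i - 1L) * B + seq_len(B), ], c(B, C, P, P))
      f[, , (pr - 1L) * P + seq_len(P), (pc - 1L) * P + seq_len(P)] <-
        aperm(block, c(1L, 2L, 4L, 3L))
    }
  }
  f
}

tokenize_fwd <- function(f, emb) {
  d <- dim(f)
  B <- d[1L]
  P <- embed_patch_size(emb, d[2L])
  if (d[3L] %% P != 0L || d[4L] %% P != 0L) {
    stop(sprintf("feature map %dx%d is not divisible by patch size %d",
                 d[3L], d[4L], P), call. = FALSE)
  }
  N <- (d[3L] %/% P) * (d[4L] %/% P)
  if (N + 1L != nrow(emb$Epos)) {
    stop(sprintf("position table has %d rows but the patch grid yields %d tokens",
                 nrow(emb$Epos), N + 1L), call. = FALSE)
  }
  fp <- patches_to_matrix(f, P)
  tok <- fp %*% emb$E
  Zm <- matrix(0, B * (N + 1L), ncol(emb$E))
  Zm[seq_len(B), ] <- rep(emb$Eclass, each = B)
  Zm[-seq_len(B), ] <- tok
  # position table: row t of Epos is added to token t of every sample
  Zm <- Zm + emb$Epos[rep(seq_len(N + 1L), each = B), ]
  list(out = Zm, cache = list(fp = fp, dims = d, N = N, P = P))
}

tokenize_bwd <- function(dZm, cache, emb) {
  d <- cache$dims
  B <- d[1L]; N <- cache$N
  tokidx <- rep(seq_len(N + 1L), each = B)
  dEpos <- rowsum(dZm, tokidx)
  dimnames(dEpos) <- NULL
  dEclass <- colSums(dZm[seq_len(B), , drop = FALSE])
  dtok <- dZm[-seq_len(B), , drop = FALSE]
  dE <- crossprod(cache$fp, dtok)
  dfp <- tcrossprod(dtok, emb$E)
  df <- matrix_to_patches(dfp, B, d[2L], d[3L], d[4L], cache$P)
  list(df = df, grads = list(E = dE, Eclass = dEclass, Epos = dEpos))
}

#' Tokenize a feature map into an embedded patch sequence
#'
#' Splits the feature map into `N = HW/P^2` ordered patches, flattens and
#' linearly projects each into a `D`-dimensional token, prepends the class
#' token, and adds the position table, yielding the sequence that enters
#' the encoder stack.
#'
#' @param f Rank-4 feature map (batch, channels, rows, cols).
#' @param emb Embedding parameters from [embed_init()].
#' @return Rank-3 array (batch, N + 1, D); token 1 is the class token.
#' @export
tokenize <- function(f, emb) {
  check_feature_map(f)
  r <- tokenize_fwd(f, emb)
  B <- dim(f)[1L]
  array(r$out, c(B, nrow(r$out) %/% B, ncol(emb$E)))
}

#' Initialize one transformer encoder block
#'
#' @param D Token dimension.
#' @param h Head count (must divide `D`).
#' @param K_mlp Hidden width of the token-wise MLP.
#' @return Parameter list with layer norms (`ln1`, `ln2`), attention
#'   projections (`Wq`, `Wk`, `Wv`, `Wo` and biases), and MLP weights.
#' @export
encoder_init <- function(D, h, K_mlp = 4L * D) {
  if (D %% h != 0L) {
    stop(sprintf("token dimension %d is not divisible by %d heads", D, h),
         call. = FALSE)
  }
  list(
    ln1 = list(gamma = rep(1, D), beta = numeric(D)),
    attn = list(Wq = xavier_linear(D, D), bq = numeric(D),
                Wk = xavier_linear(D, D), bk = numeric(D),
                Wv = xavier_linear(D, D), bv = numeric(D),
                Wo = xavier_linear(D, D), bo = numeric(D)),
    ln2 = list(gamma = rep(1, D), beta = numeric(D)),
    mlp = list(W1 = xavier_linear(D, K_mlp), b1 = numeric(K_mlp),
               W2 = xavier_linear(K_mlp, D), b2 = numeric(D))
  )
}

# Multi-head self-attention on a token matrix (rows batch-fastest). Queries,
# keys and values come from three learned linear maps; each head applies a
# softmax over scaled dot products (scale 1/sqrt(d_head), which reduces to
# the single-block 1/sqrt(D) form when h = 1) and the concatenated head
# outputs are re-projected to D.
msa_core_fwd <- function(Zm, B, Tn, p, h) {
  D <- ncol(Zm)
  if (D %% h != 0L) {
    stop(sprintf("token dimension %d is not divisible by %d heads", D, h),
         call. = FALSE)
  }
  dh <- D %/% h
  Q <- Zm %*% p$Wq + rep(p$bq, each = nrow(Zm))
  K <- Zm %*% p$Wk + rep(p$bk, each = nrow(Zm))
  V <- Zm %*% p$Wv + rep(p$bv, each = nrow(Zm))
  O <- matrix(0, nrow(Zm), D)
  A <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(Tn) - 1L)
    Ab <- vector("list", h)
    for (hd in seq_len(h)) {
      cols <- (hd - 1L) * dh + seq_len(dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dh)
      Ab[[hd]] <- softmax_rows(S)
      O[rows, cols] <- Ab[[hd]] %*% V[rows, cols, drop = FALSE]
    }
    A[[b]] <- Ab
  }
  out <- O %*% p$Wo + rep(p$bo, each = nrow(Zm))
  list(out = out,
       cache = list(Zm = Zm, Q = Q, K = K, V = V, O = O, A = A,
                    B = B, Tn = Tn, h = h, dh = dh))
}

msa_core_bwd <- function(dout, cache, p) {
  B <- cache$B; Tn <- cache$Tn; h <- cache$h; dh <- cache$dh
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- tcrossprod(dout, p$Wo)
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(Tn) - 1L)
    for (hd in seq_len(h)) {
      cols <- (hd - 1L) * dh + seq_len(dh)
      A <- cache$A[[b]][[hd]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- (dA - rowSums(dA * A)) * A / sqrt(dh)
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  dZm <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dZm = dZm,
       grads = list(Wq = crossprod(cache$Zm, dQ), bq = colSums(dQ),
                    Wk = crossprod(cache$Zm, dK), bk = colSums(dK),
                    Wv = crossprod(cache$Zm, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

#' Multi-head self-attention over a token sequence
#'
#' @param z Rank-3 token array (batch, tokens, D).
#' @param params Attention parameters (the `attn` element of
#'   [encoder_init()] output).
#' @param h Head count; `D` must be divisible by `h`.
#' @param return_attention Also return the per-sample, per-head attention
#'   weight matrices.
#' @return Token array shaped like `z`, or (with attention) a list with
#'   elements `out` and `attention`.
#' @export
msa <- function(z, params, h = 1L, return_attention = FALSE) {
  d <- dim(z)
  r <- msa_core_fwd(matrix(z, d[1L] * d[2L], d[3L]), d[1L], d[2L], params, h)
  out <- array(r$out, d)
  if (return_attention) list(out = out, attention = r$cache$A) else out
}

mlp_core_fwd <- function(Zm, p) {
  H1 <- Zm %*% p$W1 + rep(p$b1, each = nrow(Zm))
  A1 <- gelu(H1)
  out <- A1 %*% p$W2 + rep(p$b2, each = nrow(Zm))
  list(out = out, cache = list(Zm = Zm, H1 = H1, A1 = A1))
}

mlp_core_bwd <- function(dout, cache, p) {
  dW2 <- crossprod(cache$A1, dout)
  db2 <- colSums(dout)
  dA1 <- tcrossprod(dout, p$W2)
  dH1 <- dA1 * gelu_grad(cache$H1)
  list(dZm = tcrossprod(dH1, p$W1),
       grads = list(W1 = crossprod(cache$Zm, dH1), b1 = colSums(dH1),
                    W2 = dW2, b2 = db2))
}

#' Token-wise MLP block
#'
#' Applies `gelu(z W1 + b1) W2 + b2` independently to every token
#' (dimension expansion to the hidden width, GELU, reduction back to D).
#'
#' @param z Rank-3 token array (batch, tokens, D).
#' @param params MLP parameters (`W1`, `b1`, `W2`, `b2`).
#' @return Token array shaped like `z`.
#' @export
mlp <- function(z, params) {
  d <- dim(z)
  array(mlp_core_fwd(matrix(z, d[1L] * d[2L], d[3L]), params)$out, d)
}

encoder_core_fwd <- function(Zm, B, Tn, p, h, eps) {
  n1 <- layernorm_fwd(Zm, p$ln1$gamma, p$ln1$beta, eps)
  at <- msa_core_fwd(n1$out, B, Tn, p$attn, h)
  z1 <- Zm + at$out
  n2 <- layernorm_fwd(z1, p$ln2$gamma, p$ln2$beta, eps)
  ml <- mlp_core_fwd(n2$out, p$mlp)
  list(out = z1 + ml$out,
       cache = list(n1 = n1$cache, at = at$cache, n2 = n2$cache,
                    ml = ml$cache))
}

encoder_core_bwd <- function(dout, cache, p) {
  dml <- mlp_core_bwd(dout, cache$ml, p$mlp)
  dn2 <- layernorm_bwd(dml$dZm, cache$n2, p$ln2$gamma)
  dz1 <- dout + dn2$dX
  dat <- msa_core_bwd(dz1, cache$at, p$attn)
  dn1 <- layernorm_bwd(dat$dZm, cache$n1, p$ln1$gamma)
  list(dZm = dz1 + dn1$dX,
       grads = list(ln1 = list(gamma = dn1$dgamma, beta = dn1$dbeta),
                    attn = dat$grads,
                    ln2 = list(gamma = dn2$dgamma, beta = dn2$dbeta),
                    mlp = dml$grads))
}

#' One pre-norm transformer encoder block
#'
#' Computes `z' = MSA(LN(z)) + z` followed by `MLP(LN(z')) + z'`. The
#' output shape always equals the input shape, so blocks stack freely;
#' with all learnable attention/MLP weights at zero the block is the
#' identity map.
#'
#' @param z Rank-3 token array (batch, tokens, D).
#' @param params Block parameters from [encoder_init()].
#' @param h Head count.
#' @param eps Layer-norm epsilon.
#' @return Token array shaped like `z`.
#' @export
encoder_forward <- function(z, params, h = 1L, eps = 1e-6) {
  d <- dim(z)
  r <- encoder_core_fwd(matrix(z, d[1L] * d[2L], d[3L]), d[1L], d[2L],
                        params, h, eps)
  array(r$out, d)
}

#' Initialize the full transformer branch
#'
#' @param H,W,C Shape of the incoming feature map.
#' @param P Patch side length.
#' @param D Token dimension.
#' @param h Head count.
#' @param L Number of stacked encoder blocks.
#' @param K_mlp MLP hidden width.
#' @return Parameter list: `embed`, `layers` (length `L`), and the final
#'   layer norm `ln_f`.
#' @export
t_branch_init <- function(H, W, C, P, D, h, L, K_mlp = 4L * D) {
  list(embed = embed_init(H, W, C, P, D),
       layers = lapply(seq_len(L), function(i) encoder_init(D, h, K_mlp)),
       ln_f = list(gamma = rep(1, D), beta = numeric(D)))
}

t_branch_fwd <- function(f, params, h, eps) {
  B <- dim(f)[1L]
  tk <- tokenize_fwd(f, params$embed)
  Zm <- tk$out
  Tn <- nrow(Zm) %/% B
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    r <- encoder_core_fwd(Zm, B, Tn, params$layers[[l]], h, eps)
    Zm <- r$out
    caches[[l]] <- r$cache
  }
  # image representation: layer norm of the class token (token 1)
  cls <- Zm[seq_len(B), , drop = FALSE]
  nf <- layernorm_fwd(cls, params$ln_f$gamma, params$ln_f$beta, eps)
  list(out = nf$out,
       cache = list(tk = tk$cache, layers = caches, nf = nf$cache,
                    B = B, Tn = Tn, nrowZ = nrow(Zm)))
}

t_branch_bwd <- function(dy, cache, params) {
  B <- cache$B
  dnf <- layernorm_bwd(dy, cache$nf, params$ln_f$gamma)
  dZm <- matrix(0, cache$nrowZ, ncol(dy))
  dZm[seq_len(B), ] <- dnf$dX
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    r <- encoder_core_bwd(dZm, cache$layers[[l]], params$layers[[l]])
    dZm <- r$dZm
    glayers[[l]] <- r$grads
  }
  dtk <- tokenize_bwd(dZm, cache$tk, params$embed)
  list(df = dtk$df,
       grads = list(embed = dtk$grads, layers = glayers,
                    ln_f = list(gamma = dnf$dgamma, beta = dnf$dbeta)))
}

#' Run the transformer branch
#'
#' Tokenizes the feature map, applies the `L` stacked encoder blocks, and
#' returns the layer-normalized final class token as the global image
#' representation.
#'
#' @param f Rank-4 feature map (batch, channels, rows, cols).
#' @param params Parameters from [t_branch_init()].
#' @param h Head count.
#' @param eps Layer-norm epsilon.
#' @return Matrix (batch, D).
#' @export
t_branch_forward <- function(f, params, h = 1L, eps = 1e-6) {
  check_feature_map(f)
  t_branch_fwd(f, params, h, eps)$out
}
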