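# Adaptive re-weighting fusion of the two branch representations, the final
# fully connected classification head, and the multi-class cross-entropy
# loss. Two learned linear maps score each branch per feature coordinate; a
# softmax across the branch axis turns the stacked scores into a feature
# aggregating matrix whose rows sum to one, and the fused feature is the
# resulting elementwise convex combination of the ORIGINAL branch features.

#' Initialize the fusion module
#'
#' Two independent linear score maps, one per branch.
#'
#' @param D Branch feature dimension.
#' @return Parameter list (`Wt`, `bt`, `Wc`, `bc`).
#' @export
fusion_init <- function(D) {
  list(Wt = xavier_linear(D, D), bt = numeric(D),
       Wc = xavier_linear(D, D), bc = numeric(D))
}

fuse_fwd <- function(tf, cf, p) {
  if (ncol(tf) != ncol(cf)) {
    stop(sprintf(paste0("fusion requires equal branch dimensions; got ",
                        "T-branch %d and C-branch %d"),
                 ncol(tf), ncol(cf)), call. = FALSE)
  }
  st <- tf %*% p$Wt + rep(p$bt, each = nrow(tf))
  sc <- cf %*% p$Wc + rep(p$bc, each = nrow(cf))
  # two-way softmax over the branch axis, computed as a stable sigmoid
  wt <- stats::plogis(st - sc)
  wc <- 1 - wt
  list(out = wt * tf + wc * cf,
       cache = list(tf = tf, cf = cf, wt = wt, wc = wc))
}

fuse_bwd <- function(dout, cache, p) {
  wt <- cache$wt; wc <- cache$wc
  dtf <- dout * wt
  dcf <- dout * wc
  ddelta <- dout * (cache$tf - cache$cf) * wt * wc
  dtf <- dtf + tcrossprod(ddelta, p$Wt)
  dcf <- dcf - tcrossprod(ddelta, p$Wc)
  list(dtf = dtf, dcf = dcf,
       grads = list(Wt = crossprod(cache$tf, ddelta), bt = colSums(ddelta),
                    Wc = -crossprod(cache$cf, ddelta),
                    bc = -colSums(ddelta)))
}

#' Fuse the transformer and convolutional branch features
#'
#' @param t_feat,c_feat Matrices (batch, D) of branch representations.
#' @param params Parameters from [fusion_init()].
#' @param return_weights Also return the feature aggregating matrix.
#' @return The fused (batch, D) matrix, or a list with `out` and `weights`
#'   (a rank-3 array (batch, 2, D): branch 1 weights belong to the
#'   transformer branch; weights are in `[0, 1]` and sum to one across the
#'   branch axis).
#' @examples
#' p <- fusion_init(4)
#' p$Wt[] <- 0; p$Wc[] <- 0   # equal scores: fused = midpoint
#' a <- matrix(1, 2, 4); b <- matrix(3, 2, 4)
#' fuse(a, b, p)
#' @export
fuse <- function(t_feat, c_feat, params, return_weights = FALSE) {
  r <- fuse_fwd(t_feat, c_feat, params)
  if (!return_weights) return(r$out)
  B <- nrow(t_feat); D <- ncol(t_feat)
  w <- array(0, c(B, 2L, D))
  w[, 1L, ] <- r$cache$wt
  w[, 2L, ] <- r$cache$wc
  list(out = r$out, weights = w)
}

#' Initialize the classification head
#'
#' @param D Input feature dimension.
#' @param n_classes Class count.
#' @return Parameter list (`W`, `b`).
#' @export
head_init <- function(D, n_classes) {
  list(W = xavier_linear(D, n_classes), b = numeric(n_classes))
}

head_fwd <- function(x, p) linear_fwd(x, p$W, p$b)

#' Classify fused features
#'
#' Applies the final fully connected layer and a stabilized softmax. The
#' predicted label is the argmax of the probabilities, with ties broken
#' toward the lowest class index.
#'
#' @param fused Matrix (batch, D).
#' @param params Parameters from [head_init()].
#' @return List with `logits` (batch, I), `probabilities` (rows sum to 1)
#'   and `labels` (integer, 1-based class indices).
#' @export
classify <- function(fused, params) {
  logits <- head_fwd(fused, params)$out
  probs <- softmax_rows(logits)
  list(logits = logits, probabilities = probs,
       labels = apply(probs, 1L, which.max))
}

#' Multi-class cross-entropy loss
#'
#' Mean over the batch of the negative log probability assigned to the
#' true class. Probabilities are clamped below at `floor` before the log,
#' so the loss is finite even for a confidently wrong prediction.
#'
#' @param probabilities Matrix (batch, I) of predicted class probabilities.
#' @param truth Matrix (batch, I) of one-hot ground-truth rows.
#' @param floor Lower clamp applied to probabilities before the log.
#' @return Nonnegative scalar loss in nats; 0 exactly when every sample
#'   puts probability 1 on its true class.
#' @examples
#' p <- matrix(0.25, 2, 4)
#' g <- diag(4)[1:2, ]
#' cross_entropy_loss(p, g)  # log(4)
#' @export
cross_entropy_loss <- function(probabilities, truth, floor = 1e-12) {
  if (!all(truth %in% c(0, 1)) || !all(rowSums(truth) == 1)) {
    stop("truth rows must be one-hot (a single 1 per row, rest 0)",
         call. = FALSE)
  }
  if (!all(dim(probabilities) == dim(truth))) {
    stop("probabilities and truth must have identical dimensions",
         call. = FALSE)
  }
  -mean(log(pmax(probabilities[truth == 1], floor)))
}

one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}
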