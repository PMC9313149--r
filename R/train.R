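# Training protocol: patient-level k-fold splitting, image preprocessing,
# Adam with step learning-rate decay, Xavier initialization and early
# stopping on validation loss, plus the ablation-mode model assembly.

#' Patient-level k-fold split plan
#'
#' Shuffles patients (never individual scans) and deals them into `k`
#' near-equal folds, then assigns fold roles for each of the `k`
#' repetitions. Two schemes are supported: `"3:1:1"` uses 3/5 of the folds
#' for training and 1/5 each for validation and testing (3/1/1 folds at
#' k = 5), rotating roles across repetitions; `"one-train"` trains on a
#' single fold and splits the remaining folds 1:8 between validation and
#' testing by fold index. Within every repetition the train, validation
#' and test patient sets are pairwise disjoint.
#'
#' @param records Data frame with at least a `patient_id` column, one row
#'   per scan.
#' @param k Fold count; there must be at least `k` distinct patients.
#' @param scheme `"3:1:1"` or `"one-train"`.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return An object of class `"hctnet_split_plan"`.
#' @export
make_splits <- function(records, k, scheme = c("3:1:1", "one-train"),
                        seed = 1L) {
  scheme <- match.arg(scheme)
  if (!"patient_id" %in% names(records)) {
    stop("records must contain a patient_id column", call. = FALSE)
  }
  patients <- unique(as.character(records$patient_id))
  if (length(patients) < k) {
    stop(sprintf("only %d distinct patients for %d folds",
                 length(patients), k), call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of_patient <- stats::setNames(rep(seq_len(k),
                                         length.out = length(shuffled)),
                                     shuffled)
  if (scheme == "3:1:1") {
    n_test <- max(1L, round(k / 5))
    n_val <- max(1L, round(k / 5))
    n_train <- k - n_val - n_test
    if (n_train < 1L) stop("k too small for a 3:1:1 split", call. = FALSE)
  } else {
    n_train <- 1L
    n_val <- max(1L, round((k - 1L) / 9))
    n_test <- k - 1L - n_val
    if (n_test < 1L) stop("k too small for a one-train split",
                          call. = FALSE)
  }
  repetitions <- lapply(seq_len(k), function(r) {
    rot <- ((r - 1L + seq_len(k) - 1L) %% k) + 1L
    list(train = rot[seq_len(n_train)],
         val = rot[n_train + seq_len(n_val)],
         test = rot[n_train + n_val + seq_len(n_test)])
  })
  structure(list(k = k, scheme = scheme, seed = seed,
                 fold_of_patient = fold_of_patient,
                 repetitions = repetitions),
            class = "hctnet_split_plan")
}

#' @export
print.hctnet_split_plan <- function(x, ...) {
  cat(sprintf("Patient-level %d-fold split plan (%s scheme, seed %d)\n",
              x$k, x$scheme, x$seed))
  r1 <- x$repetitions[[1L]]
  cat(sprintf("  %d patients; folds per repetition: %d train / %d val / %d test\n",
              length(x$fold_of_patient), length(r1$train), length(r1$val),
              length(r1$test)))
  invisible(x)
}

#' Resolve a split plan to record row indices
#'
#' @param plan A plan from [make_splits()].
#' @param records The data frame the plan was built from.
#' @param repetition Which of the `k` repetitions to resolve.
#' @return List of integer row-index vectors `train`, `val`, `test`.
#' @export
split_records <- function(plan, records, repetition = 1L) {
  folds <- plan$fold_of_patient[as.character(records$patient_id)]
  rep_ <- plan$repetitions[[repetition]]
  list(train = which(folds %in% rep_$train),
       val = which(folds %in% rep_$val),
       test = which(folds %in% rep_$test))
}

# Triangle-filter (bilinear) interpolation weights from n_in to n_out
# samples, center-aligned. When downscaling, the filter support widens with
# the scale factor so the resize is anti-aliased (area-weighted); when
# upscaling it reduces to classic bilinear interpolation. Edge taps clamp.
resize_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  support <- max(1, scale)
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) * scale - 0.5
    js <- floor(center - support):ceiling(center + support)
    w <- pmax(0, 1 - abs(js - center) / support)
    jc <- pmin(pmax(js, 0), n_in - 1L) + 1L
    for (t in seq_along(js)) W[i, jc[t]] <- W[i, jc[t]] + w[t]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Bilinear image resize
#'
#' Separable triangle-filter resize with a center-aligned sampling grid;
#' anti-aliased when downscaling. Constant images stay constant exactly.
#'
#' @param img Numeric matrix (rows x cols).
#' @param out_h,out_w Output size.
#' @return Numeric matrix of size `out_h` x `out_w`.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  A <- resize_weights(nrow(img), out_h)
  B <- resize_weights(ncol(img), out_w)
  A %*% img %*% t(B)
}

#' Preprocess one B-scan for the network
#'
#' Resizes to the target square size with bilinear interpolation and
#' standardizes with the supplied split statistics:
#' `(x - mean) / std`.
#'
#' @param image Numeric matrix (grayscale B-scan).
#' @param mean,std Normalization statistics, computed on the training
#'   split only (see [hctnet_fit()]).
#' @param size Target side length (224 in the full-scale protocol).
#' @return Normalized `size` x `size` matrix.
#' @export
preprocess_image <- function(image, mean = 0, std = 1, size = 224L) {
  if (!is.matrix(image) || nrow(image) < 8L || ncol(image) < 8L) {
    stop("image must be a numeric matrix of at least 8x8", call. = FALSE)
  }
  if (std <= 0) {
    stop(paste("std must be positive; a zero standard deviation suggests",
               "a degenerate (constant) training split"), call. = FALSE)
  }
  (resize_bilinear(image, size, size) - mean) / std
}

#' Assemble matrices into a network input batch
#'
#' @param images List of equally sized matrices, or a rank-3 array
#'   (n, rows, cols).
#' @return Rank-4 array (n, 1, rows, cols).
#' @export
as_image_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    return(array(images, c(d[1L], 1L, d[2L], d[3L])))
  }
  n <- length(images)
  d <- dim(images[[1L]])
  out <- array(0, c(n, 1L, d[1L], d[2L]))
  for (i in seq_len(n)) out[i, 1L, , ] <- images[[i]]
  out
}

#' Step-decay learning-rate schedule
#'
#' `lr0 * gamma^floor(epoch / step)` with a 0-based epoch index, i.e. the
#' rate drops by the factor `gamma` every `step` epochs.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param lr0 Initial learning rate.
#' @param step Epochs between decays.
#' @param gamma Decay factor.
#' @return Learning rate(s).
#' @examples
#' lr_schedule(25)  # 3e-4 * 0.1^2
#' @export
lr_schedule <- function(epoch, lr0 = 3e-4, step = 10L, gamma = 0.1) {
  lr0 * gamma^(epoch %/% step)
}

#' Optimization protocol configuration
#'
#' Defaults follow the training recipe: Adam, mini-batch 32, weight decay
#' 1e-4, learning rate 3e-4 decayed by 0.1 every 10 epochs, early stopping
#' on validation loss with patience 10, epoch cap 50.
#'
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty coupled into the Adam update.
#' @param lr0,lr_step,lr_gamma Step-decay schedule (see [lr_schedule()]).
#' @param patience Early-stopping patience in epochs (validation loss).
#' @param max_epochs Epoch cap.
#' @param seed Integer seed controlling initialization and batch order.
#' @param stop_at_train_acc Optional training-accuracy level at which to
#'   stop early (e.g. for capability checks); `NULL` disables.
#' @return A list of class `"hctnet_train_config"`.
#' @export
train_config <- function(batch_size = 32L, weight_decay = 1e-4,
                         lr0 = 3e-4, lr_step = 10L, lr_gamma = 0.1,
                         patience = 10L, max_epochs = 50L, seed = 1L,
                         stop_at_train_acc = NULL) {
  stopifnot(batch_size >= 1, weight_decay >= 0, lr0 > 0, lr_step >= 1,
            lr_gamma > 0, patience >= 1, max_epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, lr0 = lr0,
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 stop_at_train_acc = stop_at_train_acc),
            class = "hctnet_train_config")
}

tree_zero <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, tree_zero)
}

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  if (!is.null(names(a))) b <- b[names(a)]
  Map(function(x, y) tree_map2(f, x, y), a, b)
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) {
    grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# Forward a label/image set in mini-batches; returns loss, accuracy and
# predicted labels without touching gradients.
eval_forward <- function(params, cfg, x, y, batch_size = 32L) {
  n <- dim(x)[1L]
  preds <- integer(n)
  loss <- 0
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    fw <- model_fwd(params, x[idx, , , , drop = FALSE], cfg)
    probs <- softmax_rows(fw$logits)
    preds[idx] <- apply(probs, 1L, which.max)
    loss <- loss + cross_entropy_loss(probs, one_hot(y[idx],
                                                     cfg$n_classes)) *
      length(idx)
  }
  list(loss = loss / n, accuracy = mean(preds == y), predictions = preds)
}

#' Train an assembled model
#'
#' Runs the optimization protocol over explicit train/validation index
#' sets: Xavier-initialized parameters, Adam with the step-decayed
#' learning-rate schedule and L2 weight decay, early stopping on
#' validation loss with best-checkpoint restoration. A non-finite loss
#' aborts with the offending epoch and batch.
#'
#' @param x Rank-4 input array (n, 1, size, size), already preprocessed.
#' @param y Integer class labels (1-based).
#' @param train_idx,val_idx Row indices of the training and validation
#'   samples.
#' @param config Architecture configuration ([hctnet_config()]).
#' @param tcfg Optimization configuration ([train_config()]).
#' @param verbose Print one line per epoch.
#' @return List with `model` (an `"hctnet_model"` holding the best
#'   parameters), `log` (per-epoch data frame: 0-based `epoch`, `lr`,
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`), and `best_epoch`.
#' @export
train_model <- function(x, y, train_idx, val_idx, config,
                        tcfg = train_config(), verbose = FALSE) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(tcfg$seed)
  params <- init_hctnet_params(config)
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), train_acc = numeric(),
                    val_loss = numeric(), val_acc = numeric())
  if (tcfg$max_epochs == 0L) {
    return(list(model = structure(list(config = config, params = params),
                                  class = "hctnet_model"),
                log = log, best_epoch = NA_integer_))
  }
  if (length(train_idx) == 0L || length(val_idx) == 0L) {
    stop("train and validation sets must be nonempty", call. = FALSE)
  }
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  stale <- 0L
  for (epoch in 0:(tcfg$max_epochs - 1L)) {
    lr <- lr_schedule(epoch, tcfg$lr0, tcfg$lr_step, tcfg$lr_gamma)
    order_ <- sample(train_idx)
    ep_loss <- 0
    ep_hits <- 0L
    nb <- 0L
    for (at in seq(1L, length(order_), by = tcfg$batch_size)) {
      nb <- nb + 1L
      idx <- order_[at:min(at + tcfg$batch_size - 1L, length(order_))]
      xb <- x[idx, , , , drop = FALSE]
      g <- one_hot(y[idx], config$n_classes)
      fw <- model_fwd(params, xb, config)
      probs <- softmax_rows(fw$logits)
      loss <- cross_entropy_loss(probs, g)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                     epoch, nb), call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(apply(probs, 1L, which.max) == y[idx])
      dlogits <- (probs - g) / length(idx)
      grads <- model_bwd(dlogits, fw$cache, params, config)
      st <- adam_step(params, grads, state, lr, tcfg$weight_decay)
      params <- st$params
      state <- st$state
    }
    train_loss <- ep_loss / length(train_idx)
    train_acc <- ep_hits / length(train_idx)
    vl <- eval_forward(params, config, x[val_idx, , , , drop = FALSE],
                       y[val_idx], tcfg$batch_size)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = train_loss,
                                 train_acc = train_acc,
                                 val_loss = vl$loss, val_acc = vl$accuracy))
    if (verbose) {
      message(sprintf(
        "epoch %02d lr %.1e train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, lr, train_loss, train_acc, vl$loss, vl$accuracy))
    }
    if (vl$loss < best$loss) {
      best <- list(loss = vl$loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tcfg$patience) break
    }
    if (!is.null(tcfg$stop_at_train_acc) &&
        train_acc >= tcfg$stop_at_train_acc) break
  }
  list(model = structure(list(config = config, params = best$params),
                         class = "hctnet_model"),
       log = log, best_epoch = best$epoch)
}

#' Fit a hybrid ConvNet-Transformer OCT classifier
#'
#' The main modelling entry point. Takes labeled grayscale B-scans,
#' computes normalization statistics on the training portion only,
#' optionally resizes every scan to the configured input size, and runs
#' the training protocol ([train_model()]). When `patient_id` is supplied
#' and no explicit indices are given, the train/validation split is made
#' at the patient level so no patient leaks across the boundary.
#'
#' @param x Images: rank-3 array (n, rows, cols), rank-4 array
#'   (n, 1, rows, cols), or list of matrices.
#' @param y Class labels (factor, character or integer).
#' @param config Architecture configuration ([hctnet_config()]).
#' @param tcfg Optimization configuration ([train_config()]).
#' @param patient_id Optional per-scan patient identifiers used for the
#'   internal patient-level split.
#' @param train_idx,val_idx Optional explicit sample indices; both must be
#'   given together and override the internal split.
#' @param val_fraction Fraction of patients (or scans, if no `patient_id`)
#'   held out for validation when indices are not supplied.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"hctnet"`: the fitted model, class levels,
#'   normalization statistics, per-epoch log and split bookkeeping.
#'   Supports `print`, `summary`, `predict` and `plot`.
#' @export
hctnet_fit <- function(x, y, config = hctnet_config("reduced"),
                       tcfg = train_config(), patient_id = NULL,
                       train_idx = NULL, val_idx = NULL,
                       val_fraction = 0.2, verbose = FALSE) {
  yf <- as.factor(y)
  classes <- levels(yf)
  if (length(classes) != config$n_classes) {
    config$n_classes <- length(classes)
    config <- validate_config(config)
  }
  yi <- as.integer(yf)
  xb <- if (is.list(x)) as_image_batch(x) else
    if (length(dim(x)) == 3L) as_image_batch(x) else x
  n <- dim(xb)[1L]
  if (dim(xb)[3L] != config$image_size) {
    res <- array(0, c(n, 1L, config$image_size, config$image_size))
    for (i in seq_len(n)) {
      res[i, 1L, , ] <- resize_bilinear(xb[i, 1L, , ], config$image_size)
    }
    xb <- res
  }
  if (is.null(train_idx) != is.null(val_idx)) {
    stop("supply both train_idx and val_idx or neither", call. = FALSE)
  }
  if (is.null(train_idx)) {
    old <- get_rng_state()
    set.seed(tcfg$seed)
    if (!is.null(patient_id)) {
      pats <- unique(as.character(patient_id))
      nv <- max(1L, round(length(pats) * val_fraction))
      val_p <- sample(pats, nv)
      val_idx <- which(as.character(patient_id) %in% val_p)
      train_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- sample(n, max(1L, round(n * val_fraction)))
      train_idx <- setdiff(seq_len(n), val_idx)
    }
    set_rng_state(old)
  }
  mu <- mean(xb[train_idx, , , ])
  sdv <- stats::sd(as.vector(xb[train_idx, , , ]))
  if (sdv <= 0) {
    stop("training split has zero pixel variance; degenerate split",
         call. = FALSE)
  }
  xb <- (xb - mu) / sdv
  fit <- train_model(xb, yi, train_idx, val_idx, config, tcfg,
                     verbose = verbose)
  structure(list(model = fit$model, classes = classes,
                 norm = list(mean = mu, std = sdv),
                 log = fit$log, best_epoch = fit$best_epoch,
                 train_idx = train_idx, val_idx = val_idx,
                 tcfg = tcfg, call = match.call()),
            class = "hctnet")
}

#' Predict classes or probabilities for new B-scans
#'
#' @param object A fitted `"hctnet"` object.
#' @param newdata Images in any format accepted by [hctnet_fit()].
#' @param type `"class"` (factor), `"prob"` (probability matrix) or
#'   `"logits"`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix with one row
#'   per image.
#' @export
predict.hctnet <- function(object, newdata,
                           type = c("class", "prob", "logits"),
                           batch_size = 32L, ...) {
  type <- match.arg(type)
  cfg <- object$model$config
  xb <- if (is.list(newdata)) as_image_batch(newdata) else
    if (length(dim(newdata)) == 3L) as_image_batch(newdata) else newdata
  n <- dim(xb)[1L]
  if (dim(xb)[3L] != cfg$image_size) {
    res <- array(0, c(n, 1L, cfg$image_size, cfg$image_size))
    for (i in seq_len(n)) {
      res[i, 1L, , ] <- resize_bilinear(xb[i, 1L, , ], cfg$image_size)
    }
    xb <- res
  }
  xb <- (xb - object$norm$mean) / object$norm$std
  out <- NULL
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    logits <- model_fwd(object$model$params,
                        xb[idx, , , , drop = FALSE], cfg)$logits
    out <- rbind(out, logits)
  }
  switch(type,
         logits = out,
         prob = {
           p <- softmax_rows(out)
           colnames(p) <- object$classes
           p
         },
         class = factor(object$classes[apply(softmax_rows(out), 1L,
                                             which.max)],
                        levels = object$classes))
}

#' @export
print.hctnet <- function(x, ...) {
  cat("Hybrid ConvNet-Transformer OCT classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  print(x$model)
  if (nrow(x$log)) {
    b <- x$log[x$log$epoch == x$best_epoch, ]
    cat(sprintf("  trained %d epochs; best epoch %d (val loss %.4f, val acc %.3f)\n",
                nrow(x$log), x$best_epoch, b$val_loss, b$val_acc))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @export
summary.hctnet <- function(object, ...) {
  print(object)
  if (nrow(object$log)) {
    cat("\nTraining log (last 5 epochs):\n")
    print(utils::tail(object$log, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.hctnet <- function(x, ...) {
  if (!nrow(x$log)) {
    warning("nothing to plot: model was not trained")
    return(invisible(x))
  }
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", main = "Loss", col = "steelblue")
  graphics::lines(x$log$epoch, x$log$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  plot(x$log$epoch, x$log$train_acc, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "Accuracy",
       col = "steelblue")
  graphics::lines(x$log$epoch, x$log$val_acc, col = "firebrick")
  invisible(x)
}
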