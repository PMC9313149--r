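# Whole-network assembly. An assembled model couples an architecture
# configuration with an initialized parameter tree; the ablation mode
# selects which modules exist:
#   vit_only               - patch tokenization of the raw image + encoder
#                            stack + head (a pure vision transformer),
#   llfe_vit               - RDB stem feeding the transformer branch,
#   llfe_vit_cbranch_concat- both branches, features concatenated into a
#                            width-2D head (no adaptive fusion),
#   full                   - both branches with adaptive re-weighting fusion.

ABLATION_MODES <- c("vit_only", "llfe_vit", "llfe_vit_cbranch_concat", "full")

#' Architecture configuration
#'
#' Collects every architectural hyperparameter in one list. Two presets are
#' provided: `"full"` is the benchmark-scale network (224x224 input, 32-channel
#' stem, P = 7 so the 56x56 stem output yields N = 64 tokens, D = 384,
#' 6 heads, L = 12 encoder blocks); `"reduced"` is a CPU-scale network for
#' testing and simulation studies (64x64 input, 8-channel stem, P = 4,
#' D = 128, 4 heads, L = 4).
#'
#' @param preset `"full"` or `"reduced"`.
#' @param ... Named overrides of individual fields (e.g. `n_classes = 3`,
#'   `ablation_mode = "vit_only"`).
#' @return A list of class `"hctnet_config"`.
#' @export
hctnet_config <- function(preset = c("full", "reduced"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(image_size = 224L, in_channels = 1L, n_classes = 4L,
         stem_channels = 32L, growth = 32L, kernel = 3L,
         lrelu_slope = 0.2, stem_activation = TRUE,
         P = 7L, D = 384L, h = 6L, L = 12L, K_mlp = 4L * 384L,
         ln_eps = 1e-6, vit_patch = 16L, ablation_mode = "full")
  } else {
    list(image_size = 64L, in_channels = 1L, n_classes = 4L,
         stem_channels = 8L, growth = 8L, kernel = 3L,
         lrelu_slope = 0.2, stem_activation = TRUE,
         P = 4L, D = 128L, h = 4L, L = 4L, K_mlp = 4L * 128L,
         ln_eps = 1e-6, vit_patch = 16L, ablation_mode = "full")
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg$preset <- preset
  validate_config(structure(cfg, class = "hctnet_config"))
}

validate_config <- function(cfg) {
  if (!cfg$ablation_mode %in% ABLATION_MODES) {
    stop(sprintf("unknown ablation_mode '%s'; valid modes: %s",
                 cfg$ablation_mode, paste(ABLATION_MODES, collapse = ", ")),
         call. = FALSE)
  }
  if (cfg$D %% cfg$h != 0L) {
    stop(sprintf("token dimension D=%d is not divisible by h=%d heads",
                 cfg$D, cfg$h), call. = FALSE)
  }
  if (cfg$ablation_mode == "vit_only") {
    if (cfg$image_size %% cfg$vit_patch != 0L) {
      stop("image_size must be divisible by vit_patch in vit_only mode",
           call. = FALSE)
    }
  } else {
    if (cfg$image_size %% 4L != 0L) {
      stop("image_size must be divisible by 4 (two stem poolings)",
           call. = FALSE)
    }
    fm <- cfg$image_size %/% 4L
    if (fm %% cfg$P != 0L) {
      stop(sprintf("stem output size %d is not divisible by patch size %d",
                   fm, cfg$P), call. = FALSE)
    }
    if (cfg$ablation_mode != "llfe_vit" && fm %% 8L != 0L) {
      stop(sprintf(paste0("stem output size %d must be divisible by 8 for ",
                          "the convolutional branch"), fm), call. = FALSE)
    }
  }
  cfg
}

#' Read or write an architecture configuration as YAML
#'
#' @param path File path.
#' @return `read_config` returns an `hctnet_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "full"
  raw$preset <- NULL
  do.call(hctnet_config, c(list(preset = preset), raw))
}

#' @rdname read_config
#' @param cfg An `hctnet_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

init_hctnet_params <- function(cfg) {
  mode <- cfg$ablation_mode
  p <- list()
  if (mode == "vit_only") {
    p$t_branch <- t_branch_init(cfg$image_size, cfg$image_size,
                                cfg$in_channels, cfg$vit_patch,
                                cfg$D, cfg$h, cfg$L, cfg$K_mlp)
    p$head <- head_init(cfg$D, cfg$n_classes)
    return(p)
  }
  fm <- cfg$image_size %/% 4L
  p$llfe <- llfe_init(cfg$in_channels, cfg$stem_channels, cfg$growth,
                      cfg$kernel)
  p$t_branch <- t_branch_init(fm, fm, cfg$stem_channels, cfg$P,
                              cfg$D, cfg$h, cfg$L, cfg$K_mlp)
  if (mode %in% c("llfe_vit_cbranch_concat", "full")) {
    p$c_branch <- c_branch_init(cfg$stem_channels, cfg$growth, cfg$D,
                                cfg$kernel)
  }
  if (mode == "full") {
    p$fusion <- fusion_init(cfg$D)
    p$head <- head_init(cfg$D, cfg$n_classes)
  } else if (mode == "llfe_vit_cbranch_concat") {
    p$head <- head_init(2L * cfg$D, cfg$n_classes)
  } else {
    p$head <- head_init(cfg$D, cfg$n_classes)
  }
  p
}

#' Assemble an initialized model
#'
#' Instantiates the module set selected by the configuration's ablation
#' mode and initializes all parameters (Xavier for weight matrices and
#' convolutions; truncated normal for the class token and position table).
#'
#' @param cfg An [hctnet_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `"hctnet_model"` with elements `config` and
#'   `params`.
#' @export
assemble_model <- function(cfg, seed = NULL) {
  cfg <- validate_config(cfg)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  structure(list(config = cfg, params = init_hctnet_params(cfg)),
            class = "hctnet_model")
}

# Flatten a parameter tree into named numeric leaves ("llfe.stem.W", ...).
flatten_params <- function(p, prefix = NULL) {
  if (is.numeric(p)) {
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  nms <- names(p) %||% as.character(seq_along(p))
  out <- list()
  for (i in seq_along(p)) {
    key <- if (is.null(prefix)) nms[i] else paste(prefix, nms[i], sep = ".")
    out <- c(out, flatten_params(p[[i]], key))
  }
  out
}

#' Parameter name-to-shape manifest
#'
#' @param model An `"hctnet_model"` (or a bare parameter tree).
#' @return Data frame with columns `name`, `shape`, `count`.
#' @export
param_manifest <- function(model) {
  p <- if (inherits(model, "hctnet_model")) model$params else model
  fl <- flatten_params(p)
  data.frame(
    name = names(fl),
    shape = vapply(fl, function(x)
      paste(if (is.null(dim(x))) length(x) else dim(x), collapse = "x"),
      character(1)),
    count = vapply(fl, length, numeric(1)),
    row.names = NULL
  )
}

#' @export
print.hctnet_model <- function(x, ...) {
  mf <- param_manifest(x)
  cat(sprintf("Hybrid ConvNet-Transformer model (mode: %s)\n",
              x$config$ablation_mode))
  cat(sprintf("  input %dx%d, D=%d, h=%d heads, L=%d encoder blocks\n",
              x$config$image_size, x$config$image_size, x$config$D,
              x$config$h, x$config$L))
  cat(sprintf("  %d parameter tensors, %s parameters\n",
              nrow(mf), format(sum(mf$count), big.mark = ",")))
  invisible(x)
}

model_fwd <- function(params, x, cfg) {
  mode <- cfg$ablation_mode
  if (mode == "vit_only") {
    tb <- t_branch_fwd(x, params$t_branch, cfg$h, cfg$ln_eps)
    hd <- head_fwd(tb$out, params$head)
    return(list(logits = hd$out,
                cache = list(tb = tb$cache, hd = hd$cache)))
  }
  lf <- llfe_fwd(x, params$llfe, cfg$lrelu_slope, cfg$stem_activation)
  tb <- t_branch_fwd(lf$out, params$t_branch, cfg$h, cfg$ln_eps)
  if (mode == "llfe_vit") {
    hd <- head_fwd(tb$out, params$head)
    return(list(logits = hd$out,
                cache = list(lf = lf$cache, tb = tb$cache, hd = hd$cache)))
  }
  cb <- c_branch_fwd(lf$out, params$c_branch, cfg$lrelu_slope)
  if (mode == "llfe_vit_cbranch_concat") {
    feat <- cbind(tb$out, cb$out)
    hd <- head_fwd(feat, params$head)
    return(list(logits = hd$out,
                cache = list(lf = lf$cache, tb = tb$cache, cb = cb$cache,
                             hd = hd$cache)))
  }
  fu <- fuse_fwd(tb$out, cb$out, params$fusion)
  hd <- head_fwd(fu$out, params$head)
  list(logits = hd$out,
       cache = list(lf = lf$cache, tb = tb$cache, cb = cb$cache,
                    fu = fu$cache, hd = hd$cache))
}

model_bwd <- function(dlogits, cache, params, cfg) {
  mode <- cfg$ablation_mode
  gh <- linear_bwd(dlogits, cache$hd, params$head$W)
  grads <- list(head = list(W = gh$dW, b = gh$db))
  if (mode == "vit_only") {
    gt <- t_branch_bwd(gh$dX, cache$tb, params$t_branch)
    grads$t_branch <- gt$grads
    return(grads)
  }
  if (mode == "llfe_vit") {
    gt <- t_branch_bwd(gh$dX, cache$tb, params$t_branch)
    gl <- llfe_bwd(gt$df, cache$lf, params$llfe)
    grads$t_branch <- gt$grads
    grads$llfe <- gl$grads
    return(grads)
  }
  if (mode == "llfe_vit_cbranch_concat") {
    D <- cfg$D
    dtf <- gh$dX[, seq_len(D), drop = FALSE]
    dcf <- gh$dX[, D + seq_len(D), drop = FALSE]
  } else {
    gf <- fuse_bwd(gh$dX, cache$fu, params$fusion)
    grads$fusion <- gf$grads
    dtf <- gf$dtf
    dcf <- gf$dcf
  }
  gt <- t_branch_bwd(dtf, cache$tb, params$t_branch)
  gc_ <- c_branch_bwd(dcf, cache$cb, params$c_branch)
  gl <- llfe_bwd(gt$df + gc_$df, cache$lf, params$llfe)
  grads$t_branch <- gt$grads
  grads$c_branch <- gc_$grads
  grads$llfe <- gl$grads
  grads
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a serialized parameter archive; a JSON sidecar
#' (`<path>.manifest.json`) records the name-to-shape manifest and the
#' configuration so weights survive refactors and can be audited without
#' deserializing.
#'
#' @param model An `"hctnet_model"` (possibly with training metadata).
#' @param path Checkpoint file path.
#' @return `hctnet_save` returns `path` invisibly; `hctnet_load` returns
#'   the model object.
#' @export
hctnet_save <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config),
                  manifest = param_manifest(model))
  jsonlite::write_json(sidecar, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hctnet_save
#' @export
hctnet_load <- function(path) readRDS(path)

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
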