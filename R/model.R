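# Model construction and the hand-written forward/backward passes.
#
# A model is a list: config (kn_config), params (flat named list of
# trainable arrays), state (batch-norm running mean/var, not trainable),
# classes (ordered vocabulary, set at training time or from a checkpoint).
#
# Parameter naming: stem.conv1/.bn1, stem.conv2/.bn2; stage s block b under
# "s<s>.b<b>." with gc1/gc2 (grouped convs + bn1/bn2), cmp (1x1 compression
# + bn3); transitions "t<s>." (s = 1..3); head.w / head.b.

.kaiming <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build a KidneyNeXt model
#'
#' Instantiates all trainable parameters for a configuration. Convolution
#' weights use Kaiming fan-in initialization; convolution biases and the
#' classification head start at zero (an untrained model therefore outputs
#' exactly uniform class probabilities); batch-norm scale/shift start at
#' 1/0 with running statistics at 0/1. Identical seeds give bitwise
#' identical parameters.
#'
#' @param config a [kn_config()].
#' @param seed integer seed for the initialization RNG.
#' @return an object of class `kn_model`.
#' @examples
#' m <- build_model(kn_config(num_classes = 3), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(config, seed = 1L) {
  validate_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  params <- list()
  state <- list()
  add_conv <- function(name, kh, kw, cin_g, cout) {
    params[[paste0(name, ".w")]] <<- .kaiming(c(kh, kw, cin_g, cout))
    if (config$conv_bias) params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- numeric(c)
    state[[paste0(name, ".mean")]] <<- numeric(c)
    state[[paste0(name, ".var")]] <<- rep(1, c)
  }

  ch <- config$stage_channels
  add_conv("stem.conv1", config$stem_kernel, config$stem_kernel,
           config$in_channels, ch[1L])
  add_bn("stem.bn1", ch[1L])
  add_conv("stem.conv2", config$stem_kernel, config$stem_kernel,
           config$in_channels, ch[1L])
  add_bn("stem.bn2", ch[1L])
  for (s in 1:4) {
    C <- ch[s]
    for (b in seq_len(config$blocks_per_stage[s])) {
      p <- sprintf("s%d.b%d", s, b)
      k <- config$branch_kernel
      add_conv(paste0(p, ".gc1"), k, k, C %/% config$group_count, C)
      add_bn(paste0(p, ".bn1"), C)
      add_conv(paste0(p, ".gc2"), k, k, C %/% config$group_count, C)
      add_bn(paste0(p, ".bn2"), C)
      add_conv(paste0(p, ".cmp"), 1L, 1L, 4L * C, C)
      add_bn(paste0(p, ".bn3"), C)
    }
    if (s < 4L) {
      add_conv(sprintf("t%d", s), 2L, 2L, C, 2L * C)
      add_bn(sprintf("t%d.bn", s), 2L * C)
    }
  }
  params[["head.w"]] <- matrix(0, nrow = config$num_classes, ncol = ch[4L])
  params[["head.b"]] <- numeric(config$num_classes)

  structure(list(config = config, params = params, state = state,
                 classes = NULL), class = "kn_model")
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars: convolution weights and biases,
#' batch-norm scale and shift, head weight and bias. Running batch-norm
#' statistics are not trainable and are excluded. The count is independent
#' of `input_size` and batch size, and changing the class count by one
#' changes it by exactly `D + 1` (D = final stage width).
#'
#' @param model a built [build_model()] model.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.kn_model <- function(x, ...) {
  cat("KidneyNeXt model\n")
  print(x$config)
  cat(sprintf("  trainable parameters: %s (%.1fM)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  if (!is.null(x$classes))
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# ---- forward pieces ---------------------------------------------------------

.unit_cbg_fw <- function(P, st, x, cname, bname, stride, pad, groups,
                         training, keep) {
  z <- conv2d(x, P[[paste0(cname, ".w")]], P[[paste0(cname, ".b")]],
              stride = stride, pad = pad, groups = groups)
  bn <- .bn_fw(z, P[[paste0(bname, ".gamma")]], P[[paste0(bname, ".beta")]],
               st[[paste0(bname, ".mean")]], st[[paste0(bname, ".var")]],
               training, keep)
  if (training) {
    st[[paste0(bname, ".mean")]] <- bn$rmean
    st[[paste0(bname, ".var")]] <- bn$rvar
  }
  list(y = gelu(bn$y),
       cache = if (keep) list(x = x, bn = bn$cache, ybn = bn$y) else NULL)
}

.unit_cbg_bw <- function(dy, cache, P, grads, cname, bname, stride, pad, groups) {
  dz_bn <- dy * gelu_grad(cache$ybn)
  bnb <- .bn_bw(dz_bn, cache$bn, P[[paste0(bname, ".gamma")]])
  grads[[paste0(bname, ".gamma")]] <- bnb$dgamma
  grads[[paste0(bname, ".beta")]] <- bnb$dbeta
  has_b <- !is.null(P[[paste0(cname, ".b")]])
  cb <- .conv2d_bw(cache$x, P[[paste0(cname, ".w")]], bnb$dx,
                   stride, pad, groups, has_b)
  grads[[paste0(cname, ".w")]] <- cb$dw
  if (has_b) grads[[paste0(cname, ".b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

.stem_fw <- function(P, st, x, cfg, training, keep) {
  if (dim(x)[1L] %% cfg$stem_stride != 0L || dim(x)[2L] %% cfg$stem_stride != 0L)
    stop("shape error: spatial size not divisible by stem stride", call. = FALSE)
  b1 <- .unit_cbg_fw(P, st, x, "stem.conv1", "stem.bn1",
                     cfg$stem_stride, 0L, 1L, training, keep)
  b2 <- .unit_cbg_fw(P, st, x, "stem.conv2", "stem.bn2",
                     cfg$stem_stride, 0L, 1L, training, keep)
  list(y = (b1$y + b2$y) / 2,
       cache = if (keep) list(b1 = b1$cache, b2 = b2$cache) else NULL)
}

.stem_bw <- function(dy, cache, P, grads, cfg) {
  r1 <- .unit_cbg_bw(dy / 2, cache$b1, P, grads, "stem.conv1", "stem.bn1",
                     cfg$stem_stride, 0L, 1L)
  r2 <- .unit_cbg_bw(dy / 2, cache$b2, P, r1$grads, "stem.conv2", "stem.bn2",
                     cfg$stem_stride, 0L, 1L)
  list(dx = r1$dx + r2$dx, grads = r2$grads)
}

.block_fw <- function(P, st, x, prefix, cfg, training, keep) {
  C <- dim(x)[3L]
  if (dim(P[[paste0(prefix, ".gc1.w")]])[4L] != C)
    stop(sprintf("shape error: block %s expects %d channels, got %d", prefix,
                 dim(P[[paste0(prefix, ".gc1.w")]])[4L], C), call. = FALSE)
  pad <- (cfg$branch_kernel - 1L) %/% 2L
  pm <- cpp_maxpool_forward(x, 3L, 1L, 1L)
  pa <- cpp_avgpool_forward(x, 3L, 1L, 1L)
  g1 <- .unit_cbg_fw(P, st, x, paste0(prefix, ".gc1"), paste0(prefix, ".bn1"),
                     1L, pad, cfg$group_count, training, keep)
  g2 <- .unit_cbg_fw(P, st, x, paste0(prefix, ".gc2"), paste0(prefix, ".bn2"),
                     1L, pad, cfg$group_count, training, keep)
  d <- dim(x)
  concat <- array(0, c(d[1L], d[2L], 4L * C, d[4L]))
  concat[, , seq_len(C), ] <- pm$y
  concat[, , C + seq_len(C), ] <- pa
  concat[, , 2L * C + seq_len(C), ] <- g1$y
  concat[, , 3L * C + seq_len(C), ] <- g2$y
  cmp <- .unit_cbg_fw(P, st, concat, paste0(prefix, ".cmp"), paste0(prefix, ".bn3"),
                      1L, 0L, 1L, training, keep)
  y <- if (cfg$use_residual) cmp$y + x else cmp$y
  list(y = y,
       cache = if (keep) list(argmax = pm$argmax, g1 = g1$cache, g2 = g2$cache,
                              cmp = cmp$cache, xdim = d, C = C) else NULL)
}

.block_bw <- function(dy, cache, P, grads, prefix, cfg) {
  pad <- (cfg$branch_kernel - 1L) %/% 2L
  C <- cache$C
  rc <- .unit_cbg_bw(dy, cache$cmp, P, grads, paste0(prefix, ".cmp"),
                     paste0(prefix, ".bn3"), 1L, 0L, 1L)
  dcat <- rc$dx
  d_pm <- dcat[, , seq_len(C), , drop = FALSE]
  d_pa <- dcat[, , C + seq_len(C), , drop = FALSE]
  d_g1 <- dcat[, , 2L * C + seq_len(C), , drop = FALSE]
  d_g2 <- dcat[, , 3L * C + seq_len(C), , drop = FALSE]
  dx <- cpp_maxpool_backward(cache$argmax, d_pm, cache$xdim) +
    cpp_avgpool_backward(d_pa, cache$xdim, 3L, 1L, 1L)
  r1 <- .unit_cbg_bw(d_g1, cache$g1, P, rc$grads, paste0(prefix, ".gc1"),
                     paste0(prefix, ".bn1"), 1L, pad, cfg$group_count)
  r2 <- .unit_cbg_bw(d_g2, cache$g2, P, r1$grads, paste0(prefix, ".gc2"),
                     paste0(prefix, ".bn2"), 1L, pad, cfg$group_count)
  dx <- dx + r1$dx + r2$dx
  if (cfg$use_residual) dx <- dx + dy
  list(dx = dx, grads = r2$grads)
}

.trans_fw <- function(P, st, x, prefix, training, keep) {
  d <- dim(x)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop(sprintf("shape error: transition %s requires even spatial size, got %dx%d",
                 prefix, d[1L], d[2L]), call. = FALSE)
  z <- conv2d(x, P[[paste0(prefix, ".w")]], P[[paste0(prefix, ".b")]],
              stride = 2L, pad = 0L, groups = 1L)
  bname <- paste0(prefix, ".bn")
  bn <- .bn_fw(z, P[[paste0(bname, ".gamma")]], P[[paste0(bname, ".beta")]],
               st[[paste0(bname, ".mean")]], st[[paste0(bname, ".var")]],
               training, keep)
  if (training) {
    st[[paste0(bname, ".mean")]] <- bn$rmean
    st[[paste0(bname, ".var")]] <- bn$rvar
  }
  list(y = bn$y, cache = if (keep) list(x = x, bn = bn$cache) else NULL)
}

.trans_bw <- function(dy, cache, P, grads, prefix) {
  bname <- paste0(prefix, ".bn")
  bnb <- .bn_bw(dy, cache$bn, P[[paste0(bname, ".gamma")]])
  grads[[paste0(bname, ".gamma")]] <- bnb$dgamma
  grads[[paste0(bname, ".beta")]] <- bnb$dbeta
  has_b <- !is.null(P[[paste0(prefix, ".b")]])
  cb <- .conv2d_bw(cache$x, P[[paste0(prefix, ".w")]], bnb$dx, 2L, 0L, 1L, has_b)
  grads[[paste0(prefix, ".w")]] <- cb$dw
  if (has_b) grads[[paste0(prefix, ".b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

# Full forward pass. x: (H, W, C, N). Returns logits/probs (K x N), pooled
# (D x N), the (possibly updated) state, and optionally per-layer caches
# plus the final-stage feature map for Grad-CAM.
.model_fw <- function(model, x, training = FALSE, keep = FALSE) {
  cfg <- model$config
  P <- model$params
  d <- dim(x)
  if (d[3L] != cfg$in_channels)
    stop(sprintf("shape error: expected %d input channels, got %d",
                 cfg$in_channels, d[3L]), call. = FALSE)
  if (d[1L] != cfg$input_size || d[2L] != cfg$input_size)
    stop(sprintf("shape error: expected %dx%d input, got %dx%d",
                 cfg$input_size, cfg$input_size, d[1L], d[2L]), call. = FALSE)
  st <- list2env(model$state)
  ca <- list(stages = vector("list", 4L), trans = vector("list", 3L))
  res <- .stem_fw(P, st, x, cfg, training, keep)
  h <- res$y
  ca$stem <- res$cache
  stage_out <- vector("list", 4L)
  for (s in 1:4) {
    ca$stages[[s]] <- vector("list", cfg$blocks_per_stage[s])
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      res <- .block_fw(P, st, h, sprintf("s%d.b%d", s, b), cfg, training, keep)
      h <- res$y
      ca$stages[[s]][[b]] <- res$cache
    }
    if (keep) stage_out[[s]] <- h
    if (s < 4L) {
      res <- .trans_fw(P, st, h, sprintf("t%d", s), training, keep)
      h <- res$y
      ca$trans[[s]] <- res$cache
    }
  }
  f <- .gap_fw(h)
  logits <- P[["head.w"]] %*% f + P[["head.b"]]
  probs <- softmax_cols(logits)
  list(logits = logits, probs = probs, pooled = f, final_dim = dim(h),
       cache = if (keep) ca else NULL,
       stage_out = if (keep) stage_out else NULL,
       state = as.list(st))
}

# Backward pass from a gradient on the logits (K x N). When `tap` is one of
# "stage1".."stage4" the walk stops at that stage's block output and the
# gradient there is returned (used by Grad-CAM); otherwise all parameter
# gradients are returned.
.model_bw <- function(model, fw, dlogits, tap = NULL) {
  cfg <- model$config
  P <- model$params
  grads <- list()
  grads[["head.w"]] <- dlogits %*% t(fw$pooled)
  grads[["head.b"]] <- rowSums(dlogits)
  df <- t(P[["head.w"]]) %*% dlogits
  dh <- .gap_bw(df, fw$final_dim)
  for (s in 4:1) {
    if (s < 4L) {
      r <- .trans_bw(dh, fw$cache$trans[[s]], P, grads, sprintf("t%d", s))
      dh <- r$dx
      grads <- r$grads
    }
    if (!is.null(tap) && tap == sprintf("stage%d", s))
      return(list(grads = grads, dtap = dh))
    for (b in rev(seq_len(cfg$blocks_per_stage[s]))) {
      r <- .block_bw(dh, fw$cache$stages[[s]][[b]], P, grads,
                     sprintf("s%d.b%d", s, b), cfg)
      dh <- r$dx
      grads <- r$grads
    }
  }
  if (!is.null(tap) && tap == "stem") return(list(grads = grads, dtap = dh))
  r <- .stem_bw(dh, fw$cache$stem, P, grads, cfg)
  list(grads = r$grads, dinput = r$dx)
}

# ---- exported single-component forwards (inference mode) --------------------

#' Component forward passes
#'
#' Run individual network components in inference mode (frozen batch-norm
#' statistics), mainly for inspection and verification against independent
#' oracles. `stem_forward()` applies the two parallel patchify convolutions
#' (conv -> BN -> GELU each) and averages them; `block_forward()` runs one
#' four-branch block (max pool, average pool, two grouped convolutions,
#' concatenation to 4C channels, 1x1 compression back to C, optional
#' identity shortcut); `transition_forward()` applies the 2x2 stride-2
#' channel-doubling convolution + BN; `head_forward()` applies global
#' average pooling and the softmax classifier to a feature map.
#'
#' @param model a built model.
#' @param x feature-map array `(H, W, C)` or `(H, W, C, N)`.
#' @param stage,block which stage / block the parameters come from.
#' @param which which transition (1-3).
#' @return `stem/block/transition_forward`: a feature-map array of the same
#'   arity; `head_forward`: a list with `pooled` (D-vector or D x N matrix)
#'   and `probs` (samples x classes matrix).
#' @export
stem_forward <- function(model, x) {
  single <- length(dim(x)) == 3L
  st <- list2env(model$state)
  y <- .stem_fw(model$params, st, .as_batch(x), model$config, FALSE, FALSE)$y
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' @rdname stem_forward
#' @export
block_forward <- function(model, x, stage = 1L, block = 1L) {
  single <- length(dim(x)) == 3L
  st <- list2env(model$state)
  y <- .block_fw(model$params, st, .as_batch(x),
                 sprintf("s%d.b%d", stage, block), model$config, FALSE, FALSE)$y
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' @rdname stem_forward
#' @export
transition_forward <- function(model, x, which = 1L) {
  single <- length(dim(x)) == 3L
  st <- list2env(model$state)
  y <- .trans_fw(model$params, st, .as_batch(x), sprintf("t%d", which),
                 FALSE, FALSE)$y
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' @rdname stem_forward
#' @export
head_forward <- function(model, x) {
  x <- .as_batch(x)
  D <- ncol(model$params[["head.w"]])
  if (dim(x)[3L] != D)
    stop(sprintf("shape error: head expects %d channels, got %d", D, dim(x)[3L]),
         call. = FALSE)
  f <- .gap_fw(x)
  logits <- model$params[["head.w"]] %*% f + model$params[["head.b"]]
  list(pooled = if (ncol(f) == 1L) drop(f) else f,
       probs = t(softmax_cols(logits)))
}

#' Full model forward pass
#'
#' Maps a batch of standardized images to class scores and probabilities.
#' Inference mode uses frozen batch-norm running statistics, so the output
#' is deterministic in the parameters and inputs.
#'
#' @param model a built model.
#' @param images `(H, W, C)` array or `(H, W, C, N)` batch with
#'   `H = W = input_size`.
#' @return list with `logits` and `probs`, both samples x classes matrices
#'   (columns named after the class vocabulary when the model has one).
#' @export
model_forward <- function(model, images) {
  fw <- .model_fw(model, .as_batch(images), training = FALSE, keep = FALSE)
  logits <- t(fw$logits)
  probs <- t(fw$probs)
  if (!is.null(model$classes)) {
    colnames(logits) <- model$classes
    colnames(probs) <- model$classes
  }
  list(logits = logits, probs = probs)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized container holding the full
#' configuration (as a plain key/value list), every named parameter array,
#' the batch-norm running statistics, and the ordered class vocabulary.
#' Loading reproduces identical forward outputs.
#'
#' @param model a model.
#' @param path file path (conventionally `.rds`).
#' @return `load_checkpoint()` returns the model; `save_checkpoint()` the
#'   path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               state = model$state, classes = model$classes,
               format = "kidneynext-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "kidneynext-checkpoint-1"))
    stop("not a kidneynext checkpoint: ", path, call. = FALSE)
  cfg <- obj$config
  cfg$format <- NULL
  config <- do.call(kn_config, cfg)
  structure(list(config = config, params = obj$params, state = obj$state,
                 classes = obj$classes), class = "kn_model")
}
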