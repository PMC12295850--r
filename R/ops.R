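#' @useDynLib kidneynext, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected a (H, W, C) or (H, W, C, N) array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' 2-D (grouped) convolution
#'
#' Direct dense convolution over a `(H, W, C)` feature map or `(H, W, C, N)`
#' batch, with optional zero padding and channel grouping. Weights are
#' `(kh, kw, C/groups, C_out)`; output channels are partitioned into
#' `groups` blocks, each seeing only its own slice of input channels.
#'
#' Exposed mainly so the network's building blocks can be verified against
#' independent direct-summation oracles; the model forward/backward passes
#' use it internally.
#'
#' @param x input array, `(H, W, C)` or `(H, W, C, N)`.
#' @param w weight array `(kh, kw, C/groups, C_out)`.
#' @param b optional bias vector of length `C_out`, or `NULL`.
#' @param stride,pad integer stride and symmetric zero padding.
#' @param groups number of channel groups; must divide both `C` and `C_out`.
#' @return array `(Ho, Wo, C_out[, N])`, same arity as the input.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  single <- length(dim(x)) == 3L
  x <- .as_batch(x)
  d <- dim(x); wd <- dim(w)
  if (wd[3L] * groups != d[3L])
    stop(sprintf("channel mismatch: input has %d channels, weights expect %d groups of %d",
                 d[3L], groups, wd[3L]), call. = FALSE)
  if (wd[4L] %% groups != 0L)
    stop("output channels not divisible by groups", call. = FALSE)
  y <- cpp_conv2d_forward(x, w, if (is.null(b)) numeric(0) else b,
                          as.integer(stride), as.integer(pad), as.integer(groups))
  if (single) dim(y) <- dim(y)[1:3]
  y
}

.conv2d_bw <- function(x, w, dy, stride, pad, groups, has_bias) {
  cpp_conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad),
                      as.integer(groups), has_bias)
}

#' Shape-preserving pooling
#'
#' `max_pool2d()` and `avg_pool2d()` pool `k x k` windows. With the block
#' defaults (`k = 3`, `stride = 1`, `pad = 1`) output shape equals input
#' shape. Average pooling divides by the number of valid (non-padded)
#' elements in each window, so constant maps remain constant at borders;
#' max pooling ignores padding positions.
#'
#' @param x `(H, W, C)` or `(H, W, C, N)` array.
#' @param k,stride,pad window size, stride, symmetric zero padding.
#' @return pooled array of the same arity.
#' @export
max_pool2d <- function(x, k = 3L, stride = 1L, pad = 1L) {
  single <- length(dim(x)) == 3L
  out <- cpp_maxpool_forward(.as_batch(x), as.integer(k), as.integer(stride),
                             as.integer(pad))$y
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' @rdname max_pool2d
#' @export
avg_pool2d <- function(x, k = 3L, stride = 1L, pad = 1L) {
  single <- length(dim(x)) == 3L
  out <- cpp_avgpool_forward(.as_batch(x), as.integer(k), as.integer(stride),
                             as.integer(pad))
  if (single) dim(out) <- dim(out)[1:3]
  out
}

# Exact Gaussian-error-linear unit and its derivative.
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Per-channel sums over (H, W, N) for a (H, W, C, N) array.
.chan_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, nrow = d[1L] * d[2L]))    # length C*N
  rowSums(matrix(cs, nrow = d[3L]))
}

# Broadcast a per-channel vector across (H, W, C, N) via recycling.
.chan_bc <- function(v, d) rep(v, each = d[1L] * d[2L])

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# Batch normalization. In training mode normalizes with biased batch
# statistics and updates running statistics (exponential average, unbiased
# variance); in inference mode uses the stored running statistics.
.bn_fw <- function(x, gamma, beta, rmean, rvar, training, keep = FALSE) {
  d <- dim(x)
  if (training) {
    m <- d[1L] * d[2L] * d[4L]
    mu <- .chan_sum(x) / m
    v <- pmax(.chan_sum(x * x) / m - mu^2, 0)
    invstd <- 1 / sqrt(v + .bn_eps)
    xhat <- (x - .chan_bc(mu, d)) * .chan_bc(invstd, d)
    ub <- if (m > 1L) v * m / (m - 1L) else v
    rmean <- (1 - .bn_momentum) * rmean + .bn_momentum * mu
    rvar <- (1 - .bn_momentum) * rvar + .bn_momentum * ub
  } else {
    invstd <- 1 / sqrt(rvar + .bn_eps)
    xhat <- (x - .chan_bc(rmean, d)) * .chan_bc(invstd, d)
  }
  y <- .chan_bc(gamma, d) * xhat + .chan_bc(beta, d)
  dim(y) <- d
  cache <- if (keep) list(xhat = xhat, invstd = invstd, training = training) else NULL
  list(y = y, rmean = rmean, rvar = rvar, cache = cache)
}

.bn_bw <- function(dy, cache, gamma) {
  d <- dim(dy)
  xhat <- cache$xhat
  dgamma <- .chan_sum(dy * xhat)
  dbeta <- .chan_sum(dy)
  ginv <- .chan_bc(gamma * cache$invstd, d)
  if (cache$training) {
    m <- d[1L] * d[2L] * d[4L]
    dx <- ginv * (dy - .chan_bc(dbeta / m, d) - xhat * .chan_bc(dgamma / m, d))
  } else {
    dx <- ginv * dy
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Global average pooling: (H, W, C, N) -> C x N matrix.
.gap_fw <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, nrow = d[1L] * d[2L])) / (d[1L] * d[2L]),
         nrow = d[3L], ncol = d[4L])
}

.gap_bw <- function(df, d) {
  dx <- rep(as.numeric(df), each = d[1L] * d[2L]) / (d[1L] * d[2L])
  dim(dx) <- d
  dx
}

# Numerically stable column-wise softmax of a K x N score matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Bilinear image resize
#'
#' Resizes a 2-D matrix (one image channel) with bilinear interpolation
#' using half-pixel-centre source coordinates, clamped at the borders.
#'
#' @param img numeric matrix.
#' @param out_h,out_w target size in pixels.
#' @return `out_h x out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(h) || h == 0L || w == 0L || out_h < 1L || out_w < 1L)
    stop("zero-area image cannot be resized", call. = FALSE)
  if (h == out_h && w == out_w) return(img)
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  y0 <- floor(sy); y1 <- pmin(y0 + 1, h - 1); wy <- sy - y0
  x0 <- floor(sx); x1 <- pmin(x0 + 1, w - 1); wx <- sx - x0
  rows <- img[y0 + 1, , drop = FALSE] * (1 - wy) + img[y1 + 1, , drop = FALSE] * wy
  rows[, x0 + 1, drop = FALSE] * rep(1 - wx, each = out_h) +
    rows[, x1 + 1, drop = FALSE] * rep(wx, each = out_h)
}

# Round half away from zero at d decimals (display convention of the
# metric tables: 99.955 -> 99.96).
round_half_up <- function(x, d = 2L) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5) / p
}
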