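# Grad-CAM saliency: channel weights are the spatial mean of the gradient
# of the pre-softmax class score with respect to a tapped convolutional
# feature map; the rectified weighted channel sum is min-max normalized
# and bilinearly upsampled to the input size.

#' Grad-CAM saliency map
#'
#' Computes a class-specific relevance map for one image. The gradient of
#' the target class's pre-softmax score (not the probability) is
#' backpropagated to the tapped stage output; each channel is weighted by
#' its spatially averaged gradient, the weighted sum is rectified,
#' min-max normalized to `[0, 1]` (an all-zero map, e.g. under zero
#' gradients, stays all-zero) and bilinearly upsampled to the image size.
#'
#' @param model a built model (typically trained).
#' @param image `(H, W, 3)` standardized image array, `H = W = input_size`.
#' @param target_class class name or index; default is the predicted
#'   class.
#' @param layer tapped feature map: one of `"stage1".."stage4"` (stage
#'   block outputs; default the final stage's pre-pooling map).
#' @return object of class `saliency_map`: list with `values`
#'   (input-size square matrix in `[0, 1]`), `raw_size`, `target_class`,
#'   `layer`.
#' @export
gradcam <- function(model, image, target_class = NULL, layer = "stage4") {
  if (!layer %in% c("stage1", "stage2", "stage3", "stage4"))
    stop("unknown layer '", layer, "': expected stage1..stage4", call. = FALSE)
  x <- .as_batch(image)
  fw <- .model_fw(model, x, training = FALSE, keep = TRUE)
  K <- model$config$num_classes
  if (is.null(target_class)) {
    ti <- which.max(fw$probs[, 1L])
  } else if (is.character(target_class)) {
    if (is.null(model$classes) || !target_class %in% model$classes)
      stop("unknown class: ", target_class, call. = FALSE)
    ti <- match(target_class, model$classes)
  } else {
    ti <- as.integer(target_class)
    if (ti < 1L || ti > K) stop("unknown class index: ", ti, call. = FALSE)
  }
  dlogits <- matrix(0, K, 1L)
  dlogits[ti, 1L] <- 1
  dtap <- .model_bw(model, fw, dlogits, tap = layer)$dtap
  s <- as.integer(sub("stage", "", layer))
  feat <- fw$stage_out[[s]]
  alpha <- apply(dtap[, , , 1L, drop = FALSE], 3L, mean)
  d <- dim(feat)
  cam <- matrix(0, d[1L], d[2L])
  for (c in seq_len(d[3L])) cam <- cam + alpha[c] * feat[, , c, 1L]
  cam <- pmax(cam, 0)
  if (max(cam) > 0) {
    rng <- max(cam) - min(cam)
    cam <- if (rng > 0) (cam - min(cam)) / rng else cam / max(cam)
  }
  up <- bilinear_resize(cam, dim(x)[1L], dim(x)[2L])
  up <- pmin(pmax(up, 0), 1)
  structure(list(values = up, raw_size = d[1:2],
                 target_class = if (!is.null(model$classes)) model$classes[ti] else ti,
                 layer = layer),
            class = "saliency_map")
}

#' Mask-based localization score
#'
#' Mean saliency inside a ground-truth lesion mask versus outside; used to
#' quantify whether a saliency map concentrates on the lesion.
#'
#' @param map a [gradcam()] `saliency_map`.
#' @param mask logical matrix of the same size.
#' @return named vector `inside`, `outside`.
#' @export
saliency_localization <- function(map, mask) {
  v <- map$values
  if (!all(dim(v) == dim(mask)))
    stop("shape error: mask does not match the saliency map", call. = FALSE)
  c(inside = mean(v[mask]), outside = mean(v[!mask]))
}

#' Overlay a saliency map on an image
#'
#' Alpha-blends a heat-colored (blue-cyan-yellow-red) saliency map onto
#' the grayscale rendering of the image. Opacity 0 returns the original
#' image; an all-zero map renders the coldest colormap value everywhere.
#'
#' @param image `(H, W, 3)` array or `(H, W)` matrix in `[0, 1]`.
#' @param map a [gradcam()] `saliency_map` (or plain matrix in `[0, 1]`).
#' @param opacity blend weight of the heat map in `[0, 1]`.
#' @param path optional PNG output path.
#' @return `(H, W, 3)` RGB array, invisibly when written to `path`.
#' @export
cam_overlay <- function(image, map, opacity = 0.5, path = NULL) {
  v <- if (inherits(map, "saliency_map")) map$values else map
  gray <- if (length(dim(image)) == 3L) {
    (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  } else image
  if (!all(dim(v) == dim(gray)))
    stop("shape error: saliency map does not match the image", call. = FALSE)
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "yellow", "red"))
  cols <- ramp(as.numeric(v)) / 255
  h <- nrow(gray); w <- ncol(gray)
  out <- array(0, c(h, w, 3L))
  for (c in 1:3)
    out[, , c] <- (1 - opacity) * gray + opacity * matrix(cols[, c], h, w)
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
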