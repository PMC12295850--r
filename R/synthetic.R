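# Seeded CT-like phantom generator. Phantoms emulate the layout of an
# axial abdominal slice exported as a grayscale screenshot: dark air
# background, a brighter elliptical body, two kidney ellipses, and a
# class-dependent lesion inside one kidney. They exist so that every other
# module (loading, splitting, training, metrics, saliency) is exercisable
# without any external download; they make no claim to radiological realism.

#' Supported phantom classes
#' @export
phantom_classes <- c("normal", "benign", "malignant", "cyst", "stone")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Pixel mask of a rotated ellipse on an s x s grid (centre cx, cy and
# semi-axes a, b in pixel units, theta in radians).
.ellipse_mask <- function(s, cx, cy, a, b, theta = 0) {
  xg <- matrix(rep(seq_len(s), each = s), nrow = s)   # column coordinate
  yg <- matrix(rep(seq_len(s), times = s), nrow = s)  # row coordinate
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Irregular star-shaped lesion: a circle whose radius is modulated by a
# random low-order harmonic perturbation (used for malignant masses).
.blob_mask <- function(s, cx, cy, r, irregularity) {
  amp <- irregularity * stats::runif(3, 0.5, 1)
  ph <- stats::runif(3, 0, 2 * pi)
  xg <- matrix(rep(seq_len(s), each = s), nrow = s)
  yg <- matrix(rep(seq_len(s), times = s), nrow = s)
  ang <- atan2(yg - cy, xg - cx)
  rad <- r * (1 + amp[1] * cos(2 * ang + ph[1]) + amp[2] * cos(3 * ang + ph[2]) +
                amp[3] * cos(5 * ang + ph[3]))
  sqrt((xg - cx)^2 + (yg - cy)^2) <= rad
}

#' Generate one CT-like phantom
#'
#' Draws a seeded grayscale phantom: dark background (~0.05), elliptical
#' body (~0.32), two kidney ellipses (~0.55), and a class-conditional
#' lesion inside one randomly chosen kidney. Lesion appearance by class:
#' `benign` - well-circumscribed, smooth, hyperintense (~+0.30 over
#' kidney); `malignant` - larger, irregular star-shaped boundary with
#' heterogeneous internal texture; `cyst` - round, hypointense (~-0.33);
#' `stone` - small, strongly hyperdense focus (~+0.40); `normal` - none.
#' Gaussian noise is added and the image clipped to `[0, 1]`. A logical
#' lesion mask is returned alongside.
#'
#' @param class one of [phantom_classes].
#' @param side image side length in pixels.
#' @param seed integer seed; identical specs give identical phantoms.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @return list with `image` (side x side matrix in `[0, 1]`), `mask`
#'   (logical matrix, lesion pixels), and `params` (drawn geometry).
#' @export
generate_phantom <- function(class, side = 224L, seed = 1L, noise_sd = 0.02) {
  class <- match.arg(class, phantom_classes)
  s <- as.integer(side)
  .with_seed(seed, {
    img <- matrix(0.05, s, s)
    body <- .ellipse_mask(s, s / 2 + stats::runif(1, -0.02, 0.02) * s,
                          s / 2 + stats::runif(1, -0.02, 0.02) * s,
                          0.42 * s, 0.34 * s)
    img[body] <- 0.32 + stats::runif(1, -0.03, 0.03)
    kid_int <- 0.55 + stats::runif(2, -0.03, 0.03)
    kx <- c(0.32, 0.68) * s + stats::runif(2, -0.02, 0.02) * s
    ky <- rep(0.52 * s, 2) + stats::runif(2, -0.03, 0.03) * s
    ka <- stats::runif(2, 0.100, 0.120) * s   # semi-minor (horizontal)
    kb <- stats::runif(2, 0.16, 0.19) * s     # semi-major (vertical)
    kth <- stats::runif(2, -0.25, 0.25)
    kmask <- vector("list", 2)
    for (i in 1:2) {
      kmask[[i]] <- .ellipse_mask(s, kx[i], ky[i], ka[i], kb[i], kth[i])
      img[kmask[[i]]] <- kid_int[i]
    }
    mask <- matrix(FALSE, s, s)
    if (class != "normal") {
      k <- sample(1:2, 1)
      r <- switch(class,
                  benign = stats::runif(1, 0.045, 0.058) * s,
                  malignant = stats::runif(1, 0.075, 0.095) * s,
                  cyst = stats::runif(1, 0.045, 0.060) * s,
                  stone = stats::runif(1, 0.018, 0.028) * s)
      if (r >= min(ka[k], kb[k]))
        stop("generation error: lesion radius exceeds the kidney ellipse",
             call. = FALSE)
      # keep the lesion centre well inside the kidney
      off <- (min(ka[k], kb[k]) - r) * 0.5
      cx <- kx[k] + stats::runif(1, -off, off)
      cy <- ky[k] + stats::runif(1, -off, off)
      mask <- switch(class,
                     malignant = .blob_mask(s, cx, cy, r, 0.25),
                     .ellipse_mask(s, cx, cy, r, r)) & kmask[[k]]
      les_int <- switch(class,
                        benign = 0.90 + stats::runif(1, -0.02, 0.02),
                        malignant = 0.70 + stats::runif(1, -0.02, 0.02),
                        cyst = 0.22 + stats::runif(1, -0.02, 0.02),
                        stone = 0.95 + stats::runif(1, -0.02, 0.02))
      img[mask] <- les_int
      if (class == "malignant")  # heterogeneous internal texture
        img[mask] <- img[mask] + stats::rnorm(sum(mask), 0, 0.18)
    }
    img <- img + stats::rnorm(s * s, 0, noise_sd)
    list(image = pmin(pmax(img, 0), 1), mask = mask,
         params = list(class = class, side = s, seed = seed,
                       noise_sd = noise_sd))
  })
}

#' Generate a balanced phantom dataset
#'
#' Generates `n_per_class` seeded phantoms for each requested class (each
#' phantom's seed is derived deterministically from the base seed) and
#' returns them as a standardized [image_set()] with grayscale replicated
#' to RGB. When `output` is given, the class-foldered PNG tree is written
#' (readable unchanged by [load_image_folder()]), lesion masks go to
#' `<output>/masks/`, and a generation manifest CSV is written.
#'
#' @param n_per_class phantoms per class (scalar or one count per class).
#' @param classes subset of [phantom_classes].
#' @param side image side length in pixels.
#' @param seed base seed.
#' @param noise_sd additive noise level.
#' @param output optional output directory.
#' @return an [image_set()]; masks are attached as the `masks` attribute
#'   (list of logical matrices, record order).
#' @export
generate_dataset <- function(n_per_class, classes = c("benign", "malignant", "normal"),
                             side = 224L, seed = 1L, noise_sd = 0.02,
                             output = NULL) {
  unknown <- setdiff(classes, phantom_classes)
  if (length(unknown))
    stop("unknown class name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(all(n_per_class >= 1))
  n_per_class <- rep(as.integer(n_per_class), length.out = length(classes))
  ord <- order(classes)
  classes <- classes[ord]
  n_per_class <- n_per_class[ord]
  images <- list(); labels <- character(0); sources <- character(0)
  masks <- list()
  manifest <- list()
  if (!is.null(output)) {
    dir.create(file.path(output, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (cl in classes) dir.create(file.path(output, cl), showWarnings = FALSE)
  }
  k <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (i in seq_len(n_per_class[ci])) {
      k <- k + 1L
      # distinct, reproducible per-image seed, kept within 32-bit range
      iseed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      ph <- generate_phantom(cl, side = side, seed = iseed, noise_sd = noise_sd)
      arr <- array(ph$image, c(side, side, 1L))
      arr <- array(arr[, , c(1L, 1L, 1L)], c(side, side, 3L))
      tag <- sprintf("%s_%04d", cl, i)
      if (!is.null(output)) {
        fp <- file.path(output, cl, paste0(tag, ".png"))
        png::writePNG(ph$image, fp)
        png::writePNG(ph$mask * 1, file.path(output, "masks", paste0(tag, ".png")))
        src <- fp
      } else {
        src <- paste0("synthetic:", tag)
      }
      images[[k]] <- arr
      labels[k] <- cl
      sources[k] <- src
      masks[[k]] <- ph$mask
      manifest[[k]] <- data.frame(file = src, class = cl, seed = iseed,
                                  noise_sd = noise_sd, stringsAsFactors = FALSE)
    }
  }
  set <- image_set(images, labels, classes = classes, sources = sources)
  attr(set, "masks") <- masks
  if (!is.null(output)) {
    utils::write.csv(do.call(rbind, manifest),
                     file.path(output, "manifest.csv"), row.names = FALSE)
  }
  set
}
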