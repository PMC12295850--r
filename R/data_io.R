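# Class-foldered image datasets, preprocessing, and the stratified
# 80/20 (+30% validation) partitioning used throughout.

#' Labeled image set
#'
#' Ordered collection of (image, label) records with a fixed, ordered class
#' vocabulary. Images are stored as standardized `(H, W, 3)` arrays with
#' values in `[0, 1]`.
#'
#' @param images list of `(H, W, 3)` numeric arrays.
#' @param labels character vector of class labels, one per image.
#' @param classes ordered class vocabulary; defaults to the sorted unique
#'   labels.
#' @param sources character vector of source identifiers (paths or
#'   synthetic tags).
#' @return an object of class `image_set`.
#' @export
image_set <- function(images, labels, classes = sort(unique(labels)),
                      sources = paste0("record_", seq_along(images))) {
  labels <- as.character(labels)
  if (length(images) != length(labels))
    stop("images and labels differ in length", call. = FALSE)
  if (!all(labels %in% classes))
    stop("dataset error: labels outside the class vocabulary: ",
         paste(setdiff(labels, classes), collapse = ", "), call. = FALSE)
  structure(list(images = images, labels = labels, classes = classes,
                 sources = sources), class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image set: %d records, %d classes\n", length(x), length(x$classes)))
  print(table(factor(x$labels, levels = x$classes)))
  invisible(x)
}

#' Subset an image set by record index
#' @param set an [image_set()].
#' @param idx integer indices.
#' @return an `image_set` with the same class vocabulary.
#' @export
set_subset <- function(set, idx) {
  image_set(set$images[idx], set$labels[idx], classes = set$classes,
            sources = set$sources[idx])
}

#' Standardize a raw image to the network input contract
#'
#' Converts any decodable raster to the `(input_size, input_size, 3)`
#' contract: grayscale is replicated to three channels, an alpha channel is
#' dropped, intensities are scaled to `[0, 1]` (integer-coded images are
#' divided by their maximum representable value), and each channel is
#' bilinearly resized. No augmentation of any kind is applied.
#'
#' @param img numeric matrix `(H, W)` or array `(H, W, C)` with C in 1-4.
#' @param input_size target side length in pixels.
#' @return `(input_size, input_size, 3)` array in `[0, 1]`.
#' @export
preprocess_image <- function(img, input_size = 224L) {
  d <- dim(img)
  if (is.null(d) || d[1L] == 0L || d[2L] == 0L)
    stop("preprocessing error: zero-area image", call. = FALSE)
  if (length(d) == 2L) dim(img) <- c(d, 1L)
  nc <- dim(img)[3L]
  if (nc == 2L) img <- img[, , 1L, drop = FALSE]          # gray + alpha
  if (nc == 4L) img <- img[, , 1:3, drop = FALSE]         # drop alpha
  mx <- max(img)
  if (mx > 1) img <- img / (if (mx <= 255) 255 else 65535)
  nc <- dim(img)[3L]
  out <- array(0, c(input_size, input_size, 3L))
  if (nc == 1L) {
    r <- bilinear_resize(img[, , 1L], input_size, input_size)
    out[, , 1L] <- r; out[, , 2L] <- r; out[, , 3L] <- r
  } else {
    for (c in 1:3) out[, , c] <- bilinear_resize(img[, , c], input_size, input_size)
  }
  pmin(pmax(out, 0), 1)
}

#' Load a class-foldered image dataset
#'
#' Reads a directory tree with one subdirectory per class holding PNG
#' images (the layout written by [generate_dataset()] and used by public
#' CT-slice collections). The class vocabulary is the sorted subdirectory
#' names unless an explicit order is supplied. Unreadable files are skipped
#' with a warning; per-class counts are reported via `message()`.
#'
#' @param root dataset root directory.
#' @param expected_classes optional explicit class vocabulary/order.
#' @param input_size side length images are standardized to.
#' @return an [image_set()].
#' @export
load_image_folder <- function(root, expected_classes = NULL, input_size = 224L) {
  if (!dir.exists(root))
    stop("dataset error: directory not found: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  dirs <- setdiff(dirs, "masks")
  if (!is.null(expected_classes)) {
    missing <- setdiff(expected_classes, dirs)
    if (length(missing))
      stop("dataset error: missing class folders: ",
           paste(missing, collapse = ", "), call. = FALSE)
    classes <- expected_classes
  } else {
    classes <- sort(dirs)
  }
  if (!length(classes)) stop("dataset error: no class folders under ", root,
                             call. = FALSE)
  images <- list(); labels <- character(0); sources <- character(0)
  skipped <- 0L
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files))
      stop("dataset error: class folder is empty: ", cl, call. = FALSE)
    for (f in files) {
      raw <- tryCatch(png::readPNG(f), error = function(e) NULL)
      if (is.null(raw)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- preprocess_image(raw, input_size)
      labels <- c(labels, cl)
      sources <- c(sources, f)
    }
  }
  counts <- table(factor(labels, levels = classes))
  message("loaded ", length(images), " images (",
          paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
          if (skipped) sprintf("; %d skipped", skipped) else "", ")")
  image_set(images, labels, classes = classes, sources = sources)
}

#' Per-class split arithmetic
#'
#' The partitioning rule applied independently to each class of size `n`:
#' `n_train = round(train_fraction * n)` with half rounded up, the rest is
#' test; validation then reserves `round(val_fraction * n_train)` records
#' (half up) out of the training share. Applied to the published class
#' inventories this reproduces the printed train/test counts exactly.
#'
#' @param n class size.
#' @param train_fraction training share (default 0.8).
#' @param val_fraction share of the training records reserved for
#'   validation (default 0.3).
#' @return named integer vector `train80` (training share before validation
#'   removal), `val`, `train` (after removal), `test`.
#' @examples
#' split_counts(1919)  # train80 = 1535, test = 384
#' @export
split_counts <- function(n, train_fraction = 0.8, val_fraction = 0.3) {
  n <- as.integer(n)
  n_tr <- as.integer(round_half_up(train_fraction * n, 0))
  n_va <- as.integer(round_half_up(val_fraction * n_tr, 0))
  c(train80 = n_tr, val = n_va, train = n_tr - n_va, test = n - n_tr)
}

#' Stratified train/validation/test split
#'
#' Splits an image set per class with a seeded shuffle: 80% of each class
#' to the training share and 20% to test, then 30% of the per-class
#' training share is reserved for validation (all rounded half-up). The
#' three parts partition the input exactly; different seeds permute
#' membership but never counts.
#'
#' @param set an [image_set()].
#' @param train_fraction,val_fraction split fractions in (0, 1).
#' @param seed shuffle seed.
#' @return list with `train`, `val`, `test` image sets and `manifest`, a
#'   data frame (source, class, partition) enabling exact re-loading.
#' @export
stratified_split <- function(set, train_fraction = 0.8, val_fraction = 0.3,
                             seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            val_fraction >= 0, val_fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  part <- character(length(set))
  for (cl in set$classes) {
    idx <- which(set$labels == cl)
    n <- length(idx)
    if (n < 2L)
      stop("split error: class '", cl, "' has fewer than 2 records", call. = FALSE)
    cs <- split_counts(n, train_fraction, val_fraction)
    if (cs["train80"] < 1L || cs["test"] < 1L)
      stop("split error: class '", cl, "' too small for a nonempty partition",
           call. = FALSE)
    idx <- sample(idx)
    part[idx[seq_len(cs["val"])]] <- "val"
    part[idx[cs["val"] + seq_len(cs["train"])]] <- "train"
    part[idx[cs["train80"] + seq_len(cs["test"])]] <- "test"
  }
  manifest <- data.frame(source = set$sources, class = set$labels,
                         partition = part, stringsAsFactors = FALSE)
  list(train = set_subset(set, which(part == "train")),
       val = set_subset(set, which(part == "val")),
       test = set_subset(set, which(part == "test")),
       manifest = manifest)
}

#' Write a split manifest CSV
#' @param split result of [stratified_split()].
#' @param path output CSV path.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.csv(split$manifest, path, row.names = FALSE)
  invisible(path)
}
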