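#' Network configuration
#'
#' Structural description of a KidneyNeXt network: a patchify stem (two
#' parallel convolutions whose kernel equals their stride, averaged), four
#' stages of shape-preserving multi-branch blocks with strided transition
#' layers between stages 1-3, and a global-average-pooling softmax head.
#' The default configuration is the reference network: stages of
#' 96/192/384/768 channels, one block per stage, 6-group 3x3 grouped
#' convolutions, 224x224 RGB input.
#'
#' @param input_size input side length in pixels. Must be divisible by
#'   `stem_stride * 8` so that the three transitions halve cleanly
#'   (224 -> 56 -> 28 -> 14 -> 7).
#' @param in_channels input channels (3 for RGB).
#' @param stage_channels integer vector of 4 stage widths.
#' @param blocks_per_stage integer vector of 4 block counts.
#' @param group_count groups of the grouped-convolution branches; must
#'   divide every stage width.
#' @param branch_kernel spatial kernel of the grouped convolutions.
#' @param stem_kernel,stem_stride stem kernel and stride (equal by default:
#'   non-overlapping patchify).
#' @param num_classes number of classes K (>= 2).
#' @param use_residual add an identity shortcut around each block.
#' @param conv_bias give convolutions a bias term.
#' @return an object of class `kn_config`.
#' @examples
#' cfg <- kn_config(num_classes = 3)
#' shape_trace(cfg)
#' @export
kn_config <- function(input_size = 224L, in_channels = 3L,
                      stage_channels = c(96L, 192L, 384L, 768L),
                      blocks_per_stage = c(1L, 1L, 1L, 1L),
                      group_count = 6L, branch_kernel = 3L,
                      stem_kernel = 4L, stem_stride = 4L,
                      num_classes, use_residual = TRUE, conv_bias = TRUE) {
  cfg <- list(input_size = as.integer(input_size),
              in_channels = as.integer(in_channels),
              stage_channels = as.integer(stage_channels),
              blocks_per_stage = as.integer(blocks_per_stage),
              group_count = as.integer(group_count),
              branch_kernel = as.integer(branch_kernel),
              stem_kernel = as.integer(stem_kernel),
              stem_stride = as.integer(stem_stride),
              num_classes = as.integer(num_classes),
              use_residual = isTRUE(use_residual),
              conv_bias = isTRUE(conv_bias))
  class(cfg) <- "kn_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$stage_channels) != 4L || length(cfg$blocks_per_stage) != 4L)
    stop("configuration error: expected 4 stage channel counts and 4 block counts",
         call. = FALSE)
  if (cfg$num_classes < 2L)
    stop("configuration error: num_classes must be at least 2", call. = FALSE)
  bad <- which(cfg$stage_channels %% cfg$group_count != 0L)
  if (length(bad))
    stop(sprintf("configuration error: stage %d channels (%d) not divisible by group_count (%d)",
                 bad[1L], cfg$stage_channels[bad[1L]], cfg$group_count),
         call. = FALSE)
  if (any(cfg$blocks_per_stage < 1L))
    stop("configuration error: blocks_per_stage entries must be >= 1", call. = FALSE)
  if (cfg$input_size %% cfg$stem_stride != 0L)
    stop("configuration error: input_size not divisible by stem_stride", call. = FALSE)
  side <- cfg$input_size %/% cfg$stem_stride
  for (s in 1:3) {
    if (side %% 2L != 0L)
      stop(sprintf("configuration error: spatial size %d entering transition %d is odd; input_size must be divisible by stem_stride * 8",
                   side, s), call. = FALSE)
    side <- side %/% 2L
  }
  invisible(cfg)
}

#' Symbolic per-stage shape trace
#'
#' Computes the output shape of every stage of the network without
#' instantiating parameters: stem output, each stage's composed
#' (blocks + transition) output, the pooled feature vector and the class
#' scores. With the reference configuration this reproduces the standard
#' stage table 224 -> 56x56x96 -> 28x28x192 -> 14x14x384 -> 7x7x768 ->
#' 1x1x768 -> K.
#'
#' @param config a [kn_config()].
#' @return data frame with columns `stage`, `height`, `width`, `channels`.
#' @export
shape_trace <- function(config) {
  validate_config(config)
  side <- config$input_size %/% config$stem_stride
  ch <- config$stage_channels
  rows <- list(c("stem", side, side, ch[1L]))
  for (s in 1:3) {
    side <- side %/% 2L
    rows[[s + 1L]] <- c(sprintf("stage%d", s), side, side, ch[s + 1L])
  }
  rows[[5L]] <- c("stage4_gap", 1L, 1L, ch[4L])
  rows[[6L]] <- c("head", 1L, 1L, config$num_classes)
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- c("stage", "height", "width", "channels")
  out$height <- as.integer(out$height)
  out$width <- as.integer(out$width)
  out$channels <- as.integer(out$channels)
  out
}

#' @export
print.kn_config <- function(x, ...) {
  cat("KidneyNeXt configuration\n")
  cat(sprintf("  input: %dx%dx%d, classes: %d\n", x$input_size, x$input_size,
              x$in_channels, x$num_classes))
  cat(sprintf("  stages: %s (blocks %s), groups: %d, branch kernel: %d\n",
              paste(x$stage_channels, collapse = "/"),
              paste(x$blocks_per_stage, collapse = "/"),
              x$group_count, x$branch_kernel))
  cat(sprintf("  stem: %dx%d stride %d, residual: %s, conv bias: %s\n",
              x$stem_kernel, x$stem_kernel, x$stem_stride,
              x$use_residual, x$conv_bias))
  invisible(x)
}
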