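# Fine-tuning protocol: SGD with momentum, constant learning rate,
# per-epoch reshuffling, L2 penalty on convolution/head weights,
# cross-entropy loss, no early stopping and no checkpoint restore.

#' Training protocols
#'
#' `finetune_protocol()` describes one supervised training run;
#' `default_finetune_protocol()` returns the reference fine-tuning recipe:
#' SGD with momentum 0.9 over 30 epochs, initial learning rate 0.01 held
#' constant, batch size 128, L2 coefficient 1e-4, reshuffling at the start
#' of every epoch. `pretrain_protocol()` records the large-scale
#' pre-training stage (AdamW, 90 epochs, learning rate 1e-3, weight decay
#' 1e-4) as configuration only: pre-trained parameters enter through
#' [load_checkpoint()], the run itself is out of scope at desk scale.
#'
#' @param epochs number of epochs (>= 1).
#' @param lr positive initial learning rate (held constant).
#' @param batch_size minibatch size.
#' @param momentum momentum coefficient.
#' @param l2 L2 regularization coefficient, applied to convolution and
#'   head weights only (not biases or batch-norm scale/shift).
#' @param shuffle reshuffle the training records at each epoch start.
#' @param lr_decay,lr_steps optional schedule hook: at the start of each
#'   epoch listed in `lr_steps` the learning rate is multiplied by
#'   `lr_decay`. The default (`lr_steps = NULL`) keeps the rate constant
#'   for the whole run, which is the reference recipe.
#' @return a list of class `finetune_protocol` / `pretrain_protocol`.
#' @export
finetune_protocol <- function(epochs = 30L, lr = 0.01, batch_size = 128L,
                              momentum = 0.9, l2 = 1e-4, shuffle = TRUE,
                              lr_decay = 1, lr_steps = NULL) {
  stopifnot(epochs >= 1, lr >= 0, batch_size >= 1, momentum >= 0, l2 >= 0,
            lr_decay > 0)
  structure(list(optimizer = "sgdm", epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 l2 = l2, shuffle = isTRUE(shuffle), loss = "cross-entropy",
                 lr_decay = lr_decay, lr_steps = as.integer(lr_steps)),
            class = "finetune_protocol")
}

#' @rdname finetune_protocol
#' @export
default_finetune_protocol <- function() finetune_protocol()

#' @rdname finetune_protocol
#' @export
pretrain_protocol <- function() {
  structure(list(optimizer = "adamw", epochs = 90L, lr = 1e-3,
                 weight_decay = 1e-4, executed_here = FALSE),
            class = "pretrain_protocol")
}

# Stack image-set records into a (H, W, C, N) batch array.
.batch_array <- function(set, idx) {
  d <- dim(set$images[[idx[1L]]])
  x <- array(0, c(d, length(idx)))
  for (j in seq_along(idx)) x[, , , j] <- set$images[[idx[j]]]
  x
}

.is_weight <- function(name) {
  grepl("\\.w$", name) && !grepl("\\.(gamma|beta)$", name)
}

#' Train a model
#'
#' Runs the supervised fine-tuning loop: for exactly `protocol$epochs`
#' epochs the training records are (optionally) reshuffled with a seeded
#' RNG, cross-entropy gradients are backpropagated per minibatch, and
#' parameters follow SGD-with-momentum updates with the L2 penalty added
#' to convolution and head weight gradients. The final-epoch parameters
#' are returned as-is: no early stopping and no best-checkpoint restore.
#' Validation loss/accuracy are evaluated once per epoch.
#'
#' @param model a built [build_model()] model; its class count must equal
#'   the number of classes in `train_set`.
#' @param train_set,val_set training and (optional) validation
#'   [image_set()]s with matching vocabularies.
#' @param protocol a [finetune_protocol()].
#' @param seed seed driving shuffling.
#' @return list with `model` (trained) and `history`, a data frame with
#'   one row per iteration (iteration, epoch, train_loss, train_acc) and
#'   per-epoch validation columns (val_loss, val_acc; NA within epochs).
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        protocol = default_finetune_protocol(), seed = 1L) {
  K <- model$config$num_classes
  if (length(train_set$classes) != K)
    stop(sprintf("model has %d classes but training set has %d", K,
                 length(train_set$classes)), call. = FALSE)
  if (!all(train_set$labels %in% train_set$classes))
    stop("label outside the class vocabulary", call. = FALSE)
  model$classes <- train_set$classes
  n <- length(train_set)
  bs <- protocol$batch_size
  if (bs > n) {
    warning(sprintf("batch size %d exceeds training set size %d; using one batch of %d",
                    bs, n, n), call. = FALSE)
    bs <- n
  }
  y_idx <- match(train_set$labels, train_set$classes)
  vel <- lapply(model$params, function(p) p * 0)
  weight_flag <- vapply(names(model$params), .is_weight, logical(1))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  hist <- list()
  iter <- 0L
  lr <- protocol$lr
  for (epoch in seq_len(protocol$epochs)) {
    if (epoch %in% protocol$lr_steps) lr <- lr * protocol$lr_decay
    ord <- if (protocol$shuffle) sample.int(n) else seq_len(n)
    starts <- seq(1L, n, by = bs)
    for (si in seq_along(starts)) {
      idx <- ord[starts[si]:min(starts[si] + bs - 1L, n)]
      x <- .batch_array(train_set, idx)
      yi <- y_idx[idx]
      fw <- .model_fw(model, x, training = TRUE, keep = TRUE)
      model$state <- fw$state
      nb <- length(idx)
      p_true <- fw$probs[cbind(yi, seq_len(nb))]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      acc <- mean(apply(fw$probs, 2L, which.max) == yi)
      dlogits <- fw$probs
      dlogits[cbind(yi, seq_len(nb))] <- dlogits[cbind(yi, seq_len(nb))] - 1
      dlogits <- dlogits / nb
      grads <- .model_bw(model, fw, dlogits)$grads
      if (lr > 0) {
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          if (weight_flag[[nm]] && protocol$l2 > 0)
            g <- g + protocol$l2 * model$params[[nm]]
          vel[[nm]] <- protocol$momentum * vel[[nm]] + g
          model$params[[nm]] <- model$params[[nm]] - lr * vel[[nm]]
        }
      }
      iter <- iter + 1L
      hist[[iter]] <- data.frame(iteration = iter, epoch = epoch,
                                 train_loss = loss, train_acc = acc,
                                 val_loss = NA_real_, val_acc = NA_real_)
    }
    if (!is.null(val_set) && length(val_set) > 0L) {
      ev <- .evaluate_set(model, val_set)
      hist[[iter]]$val_loss <- ev$loss
      hist[[iter]]$val_acc <- ev$acc
    }
  }
  list(model = model, history = do.call(rbind, hist))
}

.evaluate_set <- function(model, set, batch_size = 64L) {
  n <- length(set)
  yi <- match(set$labels, set$classes)
  loss_sum <- 0; correct <- 0L
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    fw <- .model_fw(model, .batch_array(set, idx), training = FALSE)
    p_true <- fw$probs[cbind(yi[idx], seq_along(idx))]
    loss_sum <- loss_sum - sum(log(pmax(p_true, 1e-12)))
    correct <- correct + sum(apply(fw$probs, 2L, which.max) == yi[idx])
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' Predict class probabilities for an image set
#'
#' Deterministic inference (frozen batch-norm statistics). The predicted
#' class is the probability argmax; ties break to the lowest class index
#' (alphabetical order under the default vocabulary).
#'
#' @param model a trained model with a class vocabulary.
#' @param set an [image_set()].
#' @param batch_size inference batch size.
#' @return data frame with columns `source`, `true`, `predicted`, and one
#'   `p_<class>` probability column per class.
#' @export
kn_predict <- function(model, set, batch_size = 64L) {
  if (is.null(model$classes))
    stop("model has no class vocabulary; train it or load a checkpoint",
         call. = FALSE)
  n <- length(set)
  probs <- matrix(0, n, length(model$classes))
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    fw <- .model_fw(model, .batch_array(set, idx), training = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  pred <- model$classes[apply(probs, 1L, which.max)]
  out <- data.frame(source = set$sources, true = set$labels, predicted = pred,
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p_", model$classes)
  cbind(out, as.data.frame(probs))
}

#' @export
predict.kn_model <- function(object, newdata, ...) kn_predict(object, newdata, ...)

#' Extract deep features
#'
#' Taps the trained network for downstream classical classifiers:
#' `tap = "pooled"` returns the D-dimensional global-average-pooled
#' feature vector feeding the fully connected layer (D = final stage
#' width, 768 in the reference configuration); `tap = "logits"` returns
#' the K pre-softmax class scores.
#'
#' @param model a built model.
#' @param set an [image_set()].
#' @param tap `"pooled"` or `"logits"`.
#' @param batch_size inference batch size.
#' @return data frame: `label` column plus `f1..fD` (or `logit_<class>`)
#'   feature columns, one row per record.
#' @export
extract_features <- function(model, set, tap = c("pooled", "logits"),
                             batch_size = 64L) {
  tap <- match.arg(tap)
  n <- length(set)
  D <- if (tap == "pooled") length(model$params[["head.b"]]) else 0L
  feats <- NULL
  for (st in seq(1L, n, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, n)
    fw <- .model_fw(model, .batch_array(set, idx), training = FALSE)
    m <- t(if (tap == "pooled") fw$pooled else fw$logits)
    feats <- rbind(feats, m)
  }
  colnames(feats) <- if (tap == "pooled") paste0("f", seq_len(ncol(feats)))
  else paste0("logit_", if (!is.null(model$classes)) model$classes
              else seq_len(ncol(feats)))
  cbind(data.frame(label = set$labels, stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Write a training history CSV
#' @param history history data frame from [train_model()].
#' @param path output path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
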