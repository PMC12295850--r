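# Shared fixtures. Expensive objects (the trained phantom classifier) are
# built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

# A small configuration used for structural tests: 32px input, stage
# widths 4/8/16/32, 2 groups.
tiny_cfg <- function(num_classes = 3L, input_size = 32L,
                     stage_channels = c(4L, 8L, 16L, 32L), group_count = 2L,
                     ...) {
  kn_config(input_size = input_size, stage_channels = stage_channels,
            group_count = group_count, num_classes = num_classes, ...)
}

tiny_model <- function(seed = 1L, ...) build_model(tiny_cfg(...), seed = seed)

# Phantom-classification experiment: 200 phantoms per class at 96px,
# stratified 80/20 split with 30% validation, tiny network
# (8/16/32/64 channels, 2 groups) trained 18 epochs with SGD momentum.
phantom_experiment <- function() {
  if (!is.null(.fixtures$experiment)) return(.fixtures$experiment)
  ds <- generate_dataset(200, classes = c("benign", "malignant", "normal"),
                         side = 96, seed = 11)
  sp <- stratified_split(ds, seed = 12)
  cfg <- kn_config(input_size = 96, stage_channels = c(8L, 16L, 32L, 64L),
                   group_count = 2L, num_classes = 3L)
  model <- build_model(cfg, seed = 13)
  proto <- finetune_protocol(epochs = 18, lr = 0.003, batch_size = 16,
                             lr_decay = 0.25, lr_steps = c(12L, 16L))
  tr <- train_model(model, sp$train, sp$val, proto, seed = 14)
  preds <- kn_predict(tr$model, sp$test)
  .fixtures$experiment <- list(model = tr$model, history = tr$history,
                               split = sp, predictions = preds,
                               test_accuracy = mean(preds$true == preds$predicted))
  .fixtures$experiment
}

# Single-channel phantom replicated to the RGB contract.
phantom_rgb <- function(ph) {
  s <- nrow(ph$image)
  array(rep(ph$image, 3), c(s, s, 3))
}

# Direct-summation convolution oracle: plain nested loops, independent of
# the package kernels.
oracle_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cg <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) / stride + 1
  Wo <- (W + 2 * pad - kw) / stride + 1
  gCout <- Cout / groups
  y <- array(0, c(Ho, Wo, Cout))
  for (oc in seq_len(Cout)) {
    g <- (oc - 1) %/% gCout
    for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[oc]
      for (icl in seq_len(cg)) for (ky in seq_len(kh)) for (kx in seq_len(kw)) {
        ih <- (oh - 1) * stride - pad + ky
        iw <- (ow - 1) * stride - pad + kx
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[ih, iw, g * cg + icl] * w[ky, kx, icl, oc]
      }
      y[oh, ow, oc] <- acc
    }
  }
  y
}

# Exhaustive sliding-window pooling oracle (k = 3, stride 1, pad 1);
# average pooling is over the valid window elements only.
oracle_pool <- function(x, type = c("max", "avg")) {
  type <- match.arg(type)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, dim(x))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- x[max(1, i - 1):min(H, i + 1), max(1, j - 1):min(W, j + 1), c]
    y[i, j, c] <- if (type == "max") max(win) else mean(win)
  }
  y
}

# Inference-mode batch norm + GELU at freshly initialized parameters
# (gamma 1, beta 0, running mean 0, running var 1).
init_bn_gelu <- function(z) {
  u <- z / sqrt(1 + 1e-5)
  u * pnorm(u)
}

# O(n^2) concordant-pair AUC oracle with half credit for ties.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Closed-form trainable-parameter count: dual patchify stem (conv + BN
# each), per-stage four-branch blocks (two grouped convs + BN, 1x1
# compression + BN), 2x2 transitions (conv + BN) after stages 1-3, and
# the fully connected head.
oracle_param_count <- function(ch, groups, K, cin = 3, stem_k = 4, kb = 3,
                               blocks = c(1, 1, 1, 1), bias = 1) {
  stem <- 2 * (stem_k^2 * cin * ch[1] + bias * ch[1] + 2 * ch[1])
  blk <- sum(blocks * (2 * (kb^2 * ch^2 / groups + bias * ch + 2 * ch) +
                         (4 * ch^2 + bias * ch + 2 * ch)))
  trans <- sum(8 * ch[1:3]^2 + bias * 2 * ch[1:3] + 2 * 2 * ch[1:3])
  stem + blk + trans + ch[4] * K + K
}

# One-vs-rest counts printed for the three evaluation tables, plus
# confusion matrices consistent with them (used for overall accuracy).
published_tables <- function() {
  collected <- data.frame(
    class = c("benign", "control", "malignant"),
    TP = c(384L, 225L, 229L), TN = c(456L, 613L, 609L),
    FP = c(0L, 0L, 2L), FN = c(0L, 2L, 0L))
  collected_cm <- confusion_matrix(
    rep(c("benign", "control", "control", "malignant"), c(384, 225, 2, 229)),
    rep(c("benign", "control", "malignant", "malignant"), c(384, 225, 2, 229)),
    collected$class)
  kaggle <- data.frame(
    class = c("cyst", "normal", "stone", "tumor"),
    TP = c(1331L, 1828L, 501L, 818L), TN = c(3147L, 2652L, 3978L, 3661L),
    FP = c(1L, 0L, 0L, 1L), FN = c(1L, 0L, 1L, 0L))
  kaggle_cm <- matrix(c(1331, 0, 0, 1,
                        0, 1828, 0, 0,
                        1, 0, 501, 0,
                        0, 0, 0, 818), 4, byrow = TRUE,
                      dimnames = list(kaggle$class, kaggle$class))
  kauh <- data.frame(
    class = c("benign", "cyst", "malignant", "normal"),
    TP = c(530L, 265L, 307L, 448L), TN = c(1020L, 1286L, 1246L, 1106L),
    FP = c(2L, 2L, 0L, 0L), FN = c(2L, 1L, 1L, 0L))
  kauh_cm <- matrix(c(530, 2, 0, 0,
                      1, 265, 0, 0,
                      1, 0, 307, 0,
                      0, 0, 0, 448), 4, byrow = TRUE,
                    dimnames = list(kauh$class, kauh$class))
  list(collected = list(counts = collected, cm = collected_cm),
       kaggle = list(counts = kaggle, cm = kaggle_cm),
       kauh = list(counts = kauh, cm = kauh_cm))
}

rhu <- function(x, d = 2) kidneynext:::round_half_up(x, d)
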