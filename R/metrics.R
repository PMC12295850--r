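# Confusion-matrix based evaluation: one-vs-rest counts, per-class and
# macro/overall metrics (percentages, displayed half-up at 2 decimals with
# full precision retained), and one-vs-rest ROC/AUC.

#' Confusion matrix
#'
#' K x K integer count table in a fixed class order: rows are true
#' classes, columns predicted classes.
#'
#' @param true,predicted equal-length label vectors; every label must be
#'   in `classes`.
#' @param classes ordered class vocabulary fixing row/column order.
#' @return integer matrix with dimnames, class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, classes = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted))
    stop("true and predicted labels differ in length", call. = FALSE)
  unknown <- setdiff(unique(c(true, predicted)), classes)
  if (length(unknown))
    stop("labels outside the class vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- table(factor(true, levels = classes), factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' One-vs-rest counts
#'
#' For each class c taken as positive against all others: TP is the
#' diagonal cell, FN the rest of row c, FP the rest of column c, and TN
#' the remainder, so TP + TN + FP + FN equals the total for every class.
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with columns class, TP, TN, FP, FN.
#' @export
one_vs_rest_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  data.frame(class = rownames(cm), TP = as.integer(tp), TN = as.integer(total - tp - fn - fp),
             FP = as.integer(fp), FN = as.integer(fn), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-class metrics from one-vs-rest counts
#'
#' Precision `100*TP/(TP+FP)`, recall `100*TP/(TP+FN)`, F1 (harmonic mean
#' of the two), and per-class one-vs-rest accuracy `100*(TP+TN)/total`.
#' All values are percentages at full precision. A zero denominator yields
#' 0 with the `degenerate` flag set for that row.
#'
#' @param counts data frame from [one_vs_rest_counts()] (or any frame with
#'   columns class, TP, TN, FP, FN).
#' @return the input with columns precision, recall, f1, accuracy,
#'   degenerate appended.
#' @export
class_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- 100 * safe(counts$TP, counts$TP + counts$FP)
  rec <- 100 * safe(counts$TP, counts$TP + counts$FN)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- 100 * safe(counts$TP + counts$TN, total)
  degenerate <- (counts$TP + counts$FP == 0) | (counts$TP + counts$FN == 0)
  cbind(counts, data.frame(precision = prec, recall = rec, f1 = f1,
                           accuracy = acc, degenerate = degenerate))
}

#' Macro and overall metrics
#'
#' Macro precision/recall/F1 are unweighted means over classes (rows
#' flagged degenerate are excluded from the mean); overall accuracy is
#' `100 * trace / total` of the confusion matrix. Values are stored at
#' full precision; the print method displays them half-up at 2 decimals,
#' mirroring the published table layout.
#'
#' @param rows per-class metric rows from [class_metrics()].
#' @param cm the confusion matrix the rows derive from.
#' @return object of class `metrics_report`: list with `per_class`,
#'   `macro` (named vector precision/recall/f1), `overall_accuracy`,
#'   `total`, `confusion`.
#' @export
macro_and_overall <- function(rows, cm) {
  ok <- !rows$degenerate
  macro <- c(precision = mean(rows$precision[ok]),
             recall = mean(rows$recall[ok]),
             f1 = mean(rows$f1[ok]))
  structure(list(per_class = rows, macro = macro,
                 overall_accuracy = 100 * sum(diag(cm)) / sum(cm),
                 total = sum(cm), confusion = cm),
            class = "metrics_report")
}

#' One-call evaluation
#'
#' Composes [confusion_matrix()], [one_vs_rest_counts()],
#' [class_metrics()] and [macro_and_overall()].
#'
#' @inheritParams confusion_matrix
#' @return a `metrics_report`.
#' @export
metrics_report <- function(true, predicted, classes = sort(unique(c(true, predicted)))) {
  cm <- confusion_matrix(true, predicted, classes)
  macro_and_overall(class_metrics(one_vs_rest_counts(cm)), cm)
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  show <- data.frame(Class = df$class, TP = df$TP, TN = df$TN, FP = df$FP,
                     FN = df$FN,
                     Precision = round_half_up(df$precision),
                     Recall = round_half_up(df$recall),
                     F1 = round_half_up(df$f1),
                     Accuracy = round_half_up(df$accuracy))
  show <- rbind(show, data.frame(Class = "Overall", TP = NA, TN = NA, FP = NA,
                                 FN = NA,
                                 Precision = round_half_up(x$macro["precision"]),
                                 Recall = round_half_up(x$macro["recall"]),
                                 F1 = round_half_up(x$macro["f1"]),
                                 Accuracy = round_half_up(x$overall_accuracy)))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON (`<path>.json`) and as a CSV mirroring the
#' published table layout (TP, TN, FP, FN, precision, recall, F1,
#' accuracy, plus an Overall row), together with a labeled confusion
#' matrix CSV.
#'
#' @param report a `metrics_report`.
#' @param path output path stem (without extension).
#' @return the path stem, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  df <- report$per_class
  overall <- data.frame(class = "Overall", TP = NA, TN = NA, FP = NA, FN = NA,
                        precision = report$macro["precision"],
                        recall = report$macro["recall"],
                        f1 = report$macro["f1"],
                        accuracy = report$overall_accuracy, degenerate = NA)
  utils::write.csv(rbind(df, overall), paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(per_class = df,
                            macro = as.list(report$macro),
                            overall_accuracy = report$overall_accuracy,
                            total = report$total),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  cmout <- cbind(data.frame(true = rownames(report$confusion)),
                 as.data.frame(unclass(report$confusion)))
  utils::write.csv(cmout, paste0(path, "_confusion.csv"), row.names = FALSE)
  invisible(path)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores for one class taken as
#' positive (equal scores collapse into one threshold step) and computes
#' the trapezoid-rule area under the resulting (FPR, TPR) curve. The curve
#' starts at (0, 0) and ends at (1, 1). With only one true label value the
#' AUC is undefined: NA with the `degenerate` flag set.
#'
#' @param scores numeric score (e.g. predicted probability) for the
#'   positive class, one per sample.
#' @param true true labels.
#' @param positive which label is the positive class.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`, `degenerate`.
#' @export
roc_curve_ovr <- function(scores, true, positive) {
  pos <- true == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("only one true label value present; AUC undefined", call. = FALSE)
    return(list(fpr = c(0, 1), tpr = c(0, 1), thresholds = numeric(0),
                auc = NA_real_, degenerate = TRUE))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)   # last index of each tied score
  tpr <- c(0, cumsum(p)[keep] / n_pos)
  fpr <- c(0, cumsum(!p)[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = unique(s), auc = auc,
       degenerate = FALSE)
}
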