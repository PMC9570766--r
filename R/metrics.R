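# Confusion-matrix accumulation and segmentation evaluation metrics:
# per-class precision / recall / F1 / IoU, overall accuracy, mIoU and
# frequency-weighted IoU, all derived from one K x K pixel-count matrix.

#' Create an empty confusion matrix
#'
#' Rows index the true class, columns the predicted class.
#'
#' @param n_classes number of classes `K` (default 3: background, bark
#'   beetle, aspen leaf miner).
#' @param class_names optional character vector of length `K`.
#' @return a `confusion_matrix` object (integer `K x K` matrix).
#' @export
confusion_matrix <- function(n_classes = 3L,
                             class_names = default_class_names(n_classes)) {
  cm <- matrix(0, n_classes, n_classes,
               dimnames = list(true = class_names, pred = class_names))
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

default_class_names <- function(K) {
  if (K == 3L) c("BG", "BB", "ALM") else paste0("class", seq_len(K) - 1L)
}

#' Accumulate pixel counts into a confusion matrix
#'
#' Accumulation is associative: adding two tiles one after another equals
#' adding their concatenation, so tile-wise evaluation and whole-scene
#' evaluation agree exactly.
#'
#' @param cm a [confusion_matrix()].
#' @param pred integer array of predicted labels `0..K-1`.
#' @param truth integer array of true labels `0..K-1`; pixels whose truth
#'   (or prediction) equals `ignore` are skipped.
#' @param ignore label value excluded from evaluation.
#' @return the updated `confusion_matrix`.
#' @export
cm_accumulate <- function(cm, pred, truth, ignore = 255L) {
  K <- nrow(cm)
  p <- as.vector(pred)
  t <- as.vector(truth)
  if (length(p) != length(t)) stop("pred and truth differ in length")
  keep <- !is.na(t) & !is.na(p) & t != ignore & p != ignore
  p <- p[keep]; t <- t[keep]
  if (any(p < 0 | p >= K) || any(t < 0 | t >= K))
    stop("labels outside 0..", K - 1L, " (and not `ignore`) found")
  counts <- tabulate(t * K + p + 1L, nbins = K * K)
  add <- matrix(counts, K, K, byrow = TRUE)
  out <- unclass(cm) + add
  class(out) <- class(cm)
  dimnames(out) <- dimnames(cm)
  out
}

#' Evaluation metrics from a confusion matrix
#'
#' Treats each class one-vs-rest: with `TP`, `FP`, `FN` read off the
#' matrix, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic
#' mean of the two, and IoU `TP/(TP+FN+FP)`. Globally: accuracy is the
#' trace over the total, mIoU the unweighted class mean of IoU, and FWIoU
#' the sum over classes of `(TP+FN)/total * IoU`, i.e. IoU weighted by
#' true-class pixel frequency.
#'
#' Classes with an empty denominator get metric value 0 and are flagged in
#' the `undefined` column.
#'
#' @param cm a [confusion_matrix()] with at least one counted pixel.
#' @return a `metrics_report`: list with `per_class` (data.frame with
#'   precision, recall, f1, iou), `accuracy`, `miou`, `fwiou`, `total`.
#' @export
compute_report <- function(cm) {
  cmm <- unclass(cm)
  total <- sum(cmm)
  if (total <= 0) stop("empty confusion matrix")
  K <- nrow(cmm)
  tp <- diag(cmm)
  fn <- rowSums(cmm) - tp
  fp <- colSums(cmm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  iou <- safe_div(tp, tp + fn + fp)
  undefined <- (tp + fp) == 0 | (tp + fn) == 0
  per_class <- data.frame(
    class = rownames(cmm) %||% as.character(seq_len(K) - 1L),
    precision = precision, recall = recall, f1 = f1, iou = iou,
    undefined = undefined, row.names = NULL)
  freq <- (tp + fn) / total
  rep <- list(per_class = per_class,
              accuracy = sum(tp) / total,
              miou = mean(iou),
              fwiou = sum(freq * iou),
              total = total)
  class(rep) <- "metrics_report"
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", x$total, "pixels\n")
  pc <- x$per_class
  pc[, 2:5] <- round(pc[, 2:5] * 100, 2)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy %.2f%%  mIoU %.2f%%  FWIoU %.2f%%\n",
              100 * x$accuracy, 100 * x$miou, 100 * x$fwiou))
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per class (precision/recall/F1/IoU in percent) with the global
#' accuracy, mIoU and FWIoU repeated on each row, mirroring the usual
#' model-comparison table layout.
#'
#' @param report a [compute_report()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  pc <- report$per_class
  df <- data.frame(
    category = pc$class,
    precision_pct = round(100 * pc$precision, 2),
    recall_pct = round(100 * pc$recall, 2),
    f1_pct = round(100 * pc$f1, 2),
    iou_pct = round(100 * pc$iou, 2),
    miou_pct = round(100 * report$miou, 2),
    fwiou_pct = round(100 * report$fwiou, 2),
    accuracy_pct = round(100 * report$accuracy, 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a metrics report to JSON
#'
#' @inheritParams write_metrics_csv
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(per_class = report$per_class,
         accuracy = report$accuracy, miou = report$miou,
         fwiou = report$fwiou, total = report$total),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
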