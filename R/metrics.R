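#' Numerically stable softmax
#'
#' Applies the softmax over the class axis: the last dimension of an
#' array, the columns of a matrix, or the elements of a vector. Stabilized
#' by max-subtraction so large logits do not overflow.
#'
#' @param z Finite logits: vector (one observation), matrix
#'   (observations x classes), or (H, W, K) array.
#' @return Probabilities of the same shape, non-negative, summing to 1
#'   over the class axis.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("softmax requires finite logits")
  if (is.vector(z)) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  d <- dim(z)
  zm <- if (length(d) == 2L) z else matrix(z, ncol = d[length(d)])
  e <- exp(zm - apply(zm, 1, max))
  p <- e / rowSums(e)
  if (length(d) > 2L) dim(p) <- d
  p
}

#' Class-balanced cross-entropy loss
#'
#' Mean over observations of `-beta[c] * log(p[o, c])` at each
#' observation's true class `c`: the weighted multiclass cross-entropy
#' used to counter the heavy background/foreground pixel imbalance. With
#' uniform weights `beta = 1/M` it equals the plain cross-entropy scaled
#' by `1/M`.
#'
#' @param labels Integer true classes in `0..K-1` (vector or array).
#' @param probs Predicted probabilities: (observations x K) matrix or
#'   (H, W, K) array, rows summing to 1.
#' @param beta Per-class weights, non-negative; see
#'   [compute_class_weights()].
#' @return Non-negative scalar loss.
#' @export
balanced_cross_entropy <- function(labels, probs, beta) {
  d <- dim(probs)
  pm <- if (is.matrix(probs)) probs else matrix(probs, ncol = d[length(d)])
  if (any(is.na(pm))) stop("NaN probabilities")
  lab <- as.integer(labels) + 1L
  stopifnot(length(lab) == nrow(pm), all(lab >= 1L), all(lab <= ncol(pm)),
            length(beta) == ncol(pm), all(beta >= 0))
  p_true <- pmin(pmax(pm[cbind(seq_len(nrow(pm)), lab)], 1e-12), 1)
  mean(-beta[lab] * log(p_true))
}

#' Inverse-frequency class weights
#'
#' Computes per-class weights proportional to the inverse pixel frequency
#' across a set of label masks, normalized to sum to 1. A class absent
#' from all masks is treated as having one pixel, with a warning.
#'
#' @param masks List of integer label rasters (values `0..n_classes-1`),
#'   or a single raster.
#' @param n_classes Number of classes.
#' @return Numeric weight vector of length `n_classes` summing to 1.
#' @export
compute_class_weights <- function(masks, n_classes = 3L) {
  if (!is.list(masks)) masks <- list(masks)
  counts <- numeric(n_classes)
  for (m in masks) {
    counts <- counts + tabulate(as.integer(m) + 1L, nbins = n_classes)
  }
  if (any(counts == 0)) {
    warning("class(es) ", paste(which(counts == 0) - 1L, collapse = ", "),
            " absent from masks; treating count as 1 pixel")
    counts[counts == 0] <- 1
  }
  w <- (1 / counts) / sum(1 / counts)
  w
}

confusion_counts <- function(truth, pred, positive_class = 2L) {
  t_pos <- truth == positive_class
  p_pos <- pred == positive_class
  list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
       FN = sum(t_pos & !p_pos), TN = sum(!t_pos & !p_pos))
}

#' Segmentation evaluation metrics
#'
#' Overall accuracy across all classes plus precision, recall and IOU
#' (Jaccard, `TP / (TP + FP + FN)`) for the designated positive (root)
#' class, and, when class probabilities are supplied, the one-vs-rest AUC
#' of the positive-class probability.
#'
#' @param truth,pred Integer label rasters of equal shape.
#' @param probs Optional probability array (H, W, K) from prediction;
#'   when `NULL` the AUC is omitted (`NA`).
#' @param positive_class Class evaluated as foreground (default root = 2).
#' @return Named list: `accuracy`, `precision`, `recall`, `iou`, `auc`.
#'   When the positive class is empty in both truth and prediction, IOU is
#'   defined as 1 and precision/recall are `NA` with a warning.
#' @export
segmentation_metrics <- function(truth, pred, probs = NULL,
                                 positive_class = 2L) {
  stopifnot(all(dim(truth) == dim(pred)))
  cc <- confusion_counts(truth, pred, positive_class)
  accuracy <- mean(truth == pred)
  if (cc$TP + cc$FP + cc$FN == 0) {
    warning("positive class empty in both truth and prediction; ",
            "IOU defined as 1, precision/recall undefined")
    precision <- NA_real_
    recall <- NA_real_
    iou <- 1
  } else {
    precision <- if (cc$TP + cc$FP > 0) cc$TP / (cc$TP + cc$FP) else NA_real_
    recall <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
    iou <- cc$TP / (cc$TP + cc$FP + cc$FN)
  }
  auc <- NA_real_
  if (!is.null(probs)) {
    resp <- as.integer(truth == positive_class)
    sc <- as.numeric(probs[, , positive_class + 1L])
    if (length(unique(resp)) == 2L) {
      auc <- as.numeric(pROC::auc(pROC::roc(resp, sc, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
    }
  }
  list(accuracy = accuracy, precision = precision, recall = recall,
       iou = iou, auc = auc, counts = cc)
}
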