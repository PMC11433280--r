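# Classification metrics (accuracy / sensitivity / specificity / AUC) and
# the set-cardinality segmentation overlap metrics (Dice, Jaccard, pixel
# accuracy, recall, specificity).

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from scores at a threshold
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold; a score `>= threshold` predicts 1.
#' @return a [confusion_counts()].
#' @export
count_confusion <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  confusion_counts(tp = sum(pred == 1 & labels == 1),
                   fp = sum(pred == 1 & labels == 0),
                   tn = sum(pred == 0 & labels == 0),
                   fn = sum(pred == 0 & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`.
#'
#' @param counts a [confusion_counts()].
#' @return a list with `acc`, `sen`, `spe`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("accuracy undefined: no evaluated items")
  if (tp + fn == 0) stop("sensitivity undefined: no positive items (TP + FN = 0)")
  if (tn + fp == 0) stop("specificity undefined: no negative items (TN + FP = 0)")
  list(acc = (tp + tn) / total, sen = tp / (tp + fn), spe = tn / (tn + fp))
}

#' Area under the ROC curve
#'
#' Rank (Mann--Whitney) formulation: the probability that a random positive
#' scores above a random negative, with ties counted half. Invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores predicted probabilities or arbitrary real scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binarize a probability map
#'
#' @param P probability map (any shape).
#' @param threshold decision threshold in `(0, 1)`; a pixel with
#'   `P >= threshold` becomes foreground.
#' @return a 0/1 array of the same shape.
#' @export
binarize <- function(P, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- (P >= threshold) * 1
  dim(out) <- dim(P)
  out
}

seg_metrics_single <- function(S, GT) {
  I <- length(GT)
  nS <- sum(S)
  nG <- sum(GT)
  inter <- sum(S * GT)
  uni <- nS + nG - inter
  if (nG == 0) stop("recall undefined: ground-truth mask is empty (|GT| = 0)")
  if (nG == I) stop("specificity undefined: ground-truth mask covers the whole image")
  di <- if (nS + nG == 0) 1 else 2 * inter / (nS + nG)
  ja <- if (uni == 0) 1 else inter / uni
  list(di = di,
       ja = ja,
       acc = (I - uni + inter) / I,
       recall = inter / nG,
       spe = (I - uni) / (I - nG))
}

#' Segmentation overlap metrics
#'
#' Set-cardinality formulations over a predicted mask `S` and ground truth
#' `GT` with `I` total pixels: Dice `2|S∩GT|/(|S|+|GT|)`, Jaccard
#' `|S∩GT|/|S∪GT|`, pixel accuracy `(I - |S∪GT| + |S∩GT|)/I`, recall
#' `|S∩GT|/|GT|` and specificity `(I - |S∪GT|)/(I - |GT|)`. When both masks
#' are empty, Dice and Jaccard are defined as 1. For a batch
#' (`[H, W, N]` or `[H, W, 1, N]`), per-image metrics and their unweighted
#' mean are returned.
#'
#' @param S predicted binary mask (use [binarize()] on a probability map).
#' @param GT ground-truth binary mask, same shape.
#' @return for a single image, a list with `di`, `ja`, `acc`, `recall`,
#'   `spe`; for a batch, a list with `per_image` (data.frame) and `mean`.
#' @export
segmentation_metrics <- function(S, GT) {
  if (!identical(dim(as.array(S)), dim(as.array(GT))))
    stop("mask shapes differ")
  if (!all(S %in% c(0, 1)) || !all(GT %in% c(0, 1)))
    stop("masks must be binary")
  ss <- as_image_list(S)
  gs <- as_image_list(GT)
  if (length(ss) == 1) return(seg_metrics_single(ss[[1]], gs[[1]]))
  per <- do.call(rbind, lapply(seq_along(ss), function(i)
    as.data.frame(seg_metrics_single(ss[[i]], gs[[i]]))))
  list(per_image = per, mean = as.list(colMeans(per)))
}

#' Write a metric report as JSON
#'
#' Serialises a metric report (or any named list of numbers) with the fixed
#' key names used throughout the package (`di`, `ja`, `acc`, `recall`,
#' `spe`, `auc`, `sen`).
#'
#' @param report named list (nested lists allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
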