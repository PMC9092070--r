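#' Per-class confusion tally of a predicted vs true label map
#'
#' Builds one-vs-rest pixel counts per class: `TP_c` (pred = c and truth = c),
#' `FP_c` (pred = c, truth != c), `FN_c` (pred != c, truth = c) and
#' `TN_c = N - TP - FP - FN`. All four segmentation metrics derive from this
#' tally.
#'
#' @param pred,truth integer label matrices of identical shape with values in
#'   the 6-class schema (or `0:(n_classes-1)`).
#' @param n_classes number of categories `k` (default 6).
#' @return a `confusion_tally`: data.frame with one row per class
#'   (`class`, `id`, `TP`, `FP`, `FN`, `TN`) plus attributes `N` and `k`.
#' @export
confusion_tally <- function(pred, truth, n_classes = n_label_classes()) {
  if (!all(dim(pred) == dim(truth))) {
    stopf("pred and truth shapes differ: %s vs %s",
          paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  }
  ids <- 0:(n_classes - 1L)
  bad <- setdiff(unique(c(as.integer(pred), as.integer(truth))), ids)
  if (length(bad) > 0) stopf("label map contains invalid id %d", bad[1])
  N <- length(truth)
  m <- table(factor(as.integer(pred), levels = ids),
             factor(as.integer(truth), levels = ids))
  TP <- diag(m)
  FP <- rowSums(m) - TP
  FN <- colSums(m) - TP
  tally <- data.frame(
    class = if (n_classes == n_label_classes()) label_names() else paste0("class", ids),
    id = ids, TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
    TN = as.integer(N - TP - FP - FN), row.names = NULL
  )
  attr(tally, "N") <- N
  attr(tally, "k") <- n_classes
  class(tally) <- c("confusion_tally", "data.frame")
  tally
}

#' Pixel accuracy (PA)
#'
#' Global fraction of correctly labeled pixels, `(TP + TN) / (TP + FP + FN + TN)`
#' in the one-vs-rest convention — identical for every class, and equal to
#' `sum(TP_c) / N`.
#'
#' @param tally a [confusion_tally()].
#' @return PA in `[0, 1]`.
#' @export
pixel_accuracy <- function(tally) {
  N <- attr(tally, "N")
  if (is.null(N) || N == 0) stopf("empty tally")
  sum(tally$TP) / N
}

#' Mean pixel accuracy (MPA)
#'
#' Mean over categories of the per-class accuracy `TP_c / (TP_c + FN_c)`
#' (per-class recall). For `k = 2` this equals the binary form
#' `(1/k) (TP/(FN+TP) + TN/(FP+TN))`. Classes absent from the truth are
#' excluded from the mean (and reported in the `excluded` attribute) rather
#' than counted as zero.
#'
#' @param tally a [confusion_tally()].
#' @return MPA in `[0, 1]`, with attribute `excluded` naming skipped classes.
#' @export
mean_pixel_accuracy <- function(tally) {
  present <- (tally$TP + tally$FN) > 0
  if (!any(present)) stopf("no class present in truth")
  rec <- tally$TP[present] / (tally$TP[present] + tally$FN[present])
  out <- mean(rec)
  attr(out, "excluded") <- tally$class[!present]
  out
}

#' Intersection over union for one class
#'
#' `IOU_c = TP_c / (TP_c + FP_c + FN_c)`: intersection of prediction and truth
#' over their union for class `class_id`. Undefined (`NA`) when the class
#' appears in neither prediction nor truth.
#'
#' @param tally a [confusion_tally()].
#' @param class_id integer class id.
#' @return IoU in `[0, 1]`, or `NA` when undefined.
#' @export
iou <- function(tally, class_id) {
  i <- match(class_id, tally$id)
  if (is.na(i)) stopf("invalid class id %s", class_id)
  denom <- tally$TP[i] + tally$FP[i] + tally$FN[i]
  if (denom == 0) return(NA_real_)
  tally$TP[i] / denom
}

#' Mean intersection over union (MIOU)
#'
#' Mean of the per-class IoU over classes for which it is defined. For
#' `k = 2` this equals the binary form
#' `(1/k) (TP/(TP+FP+FN) + TN/(TN+FN+FP))`.
#'
#' @param tally a [confusion_tally()].
#' @return MIOU in `[0, 1]`.
#' @export
mean_iou <- function(tally) {
  ious <- vapply(tally$id, function(id) iou(tally, id), numeric(1))
  if (all(is.na(ious))) stopf("no class with a defined IoU")
  mean(ious, na.rm = TRUE)
}

#' Full metrics report for a prediction
#'
#' Convenience wrapper producing the global PA, MPA and MIOU plus the
#' per-class accuracy (recall), one-vs-rest accuracy and IoU table, mirroring
#' a per-class PA/IOU results panel.
#'
#' @param pred,truth label matrices (see [confusion_tally()]).
#' @param n_classes number of categories.
#' @return list with `PA`, `MPA`, `MIOU` and `per_class` data.frame.
#' @export
metrics_report <- function(pred, truth, n_classes = n_label_classes()) {
  tally <- confusion_tally(pred, truth, n_classes)
  N <- attr(tally, "N")
  per <- data.frame(
    class = tally$class,
    id = tally$id,
    recall = ifelse(tally$TP + tally$FN > 0, tally$TP / (tally$TP + tally$FN), NA),
    accuracy_ovr = (tally$TP + tally$TN) / N,
    IOU = vapply(tally$id, function(id) iou(tally, id), numeric(1))
  )
  list(PA = pixel_accuracy(tally),
       MPA = as.numeric(mean_pixel_accuracy(tally)),
       MIOU = mean_iou(tally),
       per_class = per)
}
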