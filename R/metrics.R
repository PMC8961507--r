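# Pixel-level segmentation metrics: confusion counts and the four
# benchmark metrics (accuracy, precision, specificity, mean IoU).

#' Pixel confusion counts between two binary masks
#'
#' Foreground is 1. Inputs must already be binary; threshold probability
#' maps first.
#'
#' @param pred,truth Binary arrays of equal shape.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(pred, truth) {
  if (length(pred) != length(truth) ||
      (!is.null(dim(pred)) && !is.null(dim(truth)) &&
       !identical(dim(pred), dim(truth))))
    argumentError("pred and truth must have identical shapes")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    argumentError("masks must be strictly binary; threshold first")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  new("ConfusionCounts", tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Add confusion counts
#'
#' Pixel pooling across images: micro-averaged evaluation is the report of
#' the summed counts.
#' @param e1,e2 \linkS4class{ConfusionCounts}.
#' @export
setMethod("+", signature("ConfusionCounts", "ConfusionCounts"),
  function(e1, e2)
    new("ConfusionCounts", tp = e1@tp + e2@tp, fp = e1@fp + e2@fp,
        tn = e1@tn + e2@tn, fn = e1@fn + e2@fn))

safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' The four benchmark metrics from confusion counts
#'
#' \itemize{
#'   \item accuracy = (tp + tn) / total
#'   \item precision = tp / (tp + fp)
#'   \item specificity = tn / (tn + fp)
#'   \item mIoU = mean of foreground IoU tp / (tp + fp + fn) and background
#'     IoU tn / (tn + fn + fp)
#' }
#' all expressed as percentages. A metric with a zero denominator is
#' undefined: reported as NA and listed in the report's \code{undefined}
#' slot, never silently zeroed.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return A \linkS4class{MetricReport}.
#' @examples
#' metricReport(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
metricReport <- function(counts) {
  if (!is(counts, "ConfusionCounts"))
    argumentError("counts must be a ConfusionCounts")
  total <- counts@tp + counts@fp + counts@tn + counts@fn
  if (total == 0) argumentError("empty confusion counts")
  acc <- (counts@tp + counts@tn) / total
  prec <- safeRatio(counts@tp, counts@tp + counts@fp)
  spec <- safeRatio(counts@tn, counts@tn + counts@fp)
  iouFg <- safeRatio(counts@tp, counts@tp + counts@fp + counts@fn)
  iouBg <- safeRatio(counts@tn, counts@tn + counts@fn + counts@fp)
  miou <- if (is.na(iouFg) || is.na(iouBg)) NA_real_ else (iouFg + iouBg) / 2
  vals <- c(accuracy = acc, precision = prec, specificity = spec, miou = miou)
  new("MetricReport",
      accuracy = 100 * vals[["accuracy"]],
      precision = 100 * vals[["precision"]],
      specificity = 100 * vals[["specificity"]],
      miou = 100 * vals[["miou"]],
      undefined = names(vals)[is.na(vals)])
}

#' Metric report as a one-row data frame
#'
#' @param report A \linkS4class{MetricReport}.
#' @return data.frame with the four metric columns in benchmark-table order.
#' @export
reportRow <- function(report) {
  data.frame(accuracy = report@accuracy, precision = report@precision,
             specificity = report@specificity, miou = report@miou)
}

#' Evaluate a model over a dataset
#'
#' Predicts every image, thresholds the probability maps, and reports
#' either the micro-averaged metrics (confusion counts pooled over all
#' pixels of all images, the default) or the macro mean of per-image
#' metrics.
#'
#' @param model An \linkS4class{EUNetModel}, or a function
#'   \code{image -> probability map} (useful for oracles and external
#'   predictors).
#' @param pairs List of sample pairs \code{list(image, mask, id)}.
#' @param threshold Binarization threshold in (0, 1).
#' @param average \code{"micro"} or \code{"macro"}.
#' @param pad Padding policy passed to [predictModel()].
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateDataset <- function(model, pairs, threshold = 0.5,
                            average = c("micro", "macro"), pad = "error") {
  average <- match.arg(average)
  if (length(pairs) == 0L) argumentError("empty dataset")
  if (threshold <= 0 || threshold >= 1)
    argumentError("threshold must lie in (0, 1)")
  predictFun <- if (is.function(model)) model
                else function(im) predictModel(model, im, pad = pad)
  counts <- NULL
  macro <- matrix(NA_real_, length(pairs), 4)
  for (i in seq_along(pairs)) {
    pm <- predictFun(pairs[[i]]$image)
    bm <- 1 * (pm > threshold)
    cc <- confusionCounts(bm, pairs[[i]]$mask)
    counts <- if (is.null(counts)) cc else counts + cc
    if (average == "macro") {
      r <- metricReport(cc)
      macro[i, ] <- c(r@accuracy, r@precision, r@specificity, r@miou)
    }
  }
  if (average == "micro") return(metricReport(counts))
  m <- colMeans(macro)
  new("MetricReport", accuracy = m[1], precision = m[2], specificity = m[3],
      miou = m[4],
      undefined = c("accuracy", "precision", "specificity",
                    "miou")[apply(macro, 2, anyNA)])
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp=%.0f fp=%.0f tn=%.0f fn=%.0f (total %.0f)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

setMethod("show", "MetricReport", function(object) {
  fmt <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f", x)
  cat(sprintf(
    "MetricReport: accuracy %s | precision %s | specificity %s | mIoU %s\n",
    fmt(object@accuracy), fmt(object@precision), fmt(object@specificity),
    fmt(object@miou)))
})
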