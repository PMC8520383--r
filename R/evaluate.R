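# Pixel-level evaluation of a predicted vessel mask against a manual
# annotation, restricted to the field of view.

#' Confusion counts within the field of view
#'
#' TP = vessel pixels correctly segmented, FP = background pixels marked as
#' vessel, TN = background correctly left out, FN = vessel pixels missed.
#' Only in-FOV pixels are counted.
#'
#' @param pred predicted logical vessel mask.
#' @param truth ground-truth logical vessel mask.
#' @param fov logical FOV mask (default whole frame).
#' @return a `confusion_counts` list with integer fields `tp, fp, tn, fn`.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  check_mask(pred, "pred"); check_mask(truth, "truth")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pred), ncol(pred))
  check_mask(fov, "fov")
  check_same_shape(pred, truth, "pred vs truth")
  check_same_shape(pred, fov, "pred vs FOV")
  p <- pred[fov]; t <- truth[fov]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' \itemize{
#'   \item ACC = (TP + TN) / (TP + TN + FP + FN): fraction of in-FOV pixels
#'     classified correctly.
#'   \item TPR = TP / (TP + FN): recall on vessel pixels.
#'   \item FPR = FP / (FP + TN): fraction of background marked as vessel.
#'   \item precision = TP / (TP + FP); F = harmonic mean of precision and TPR.
#' }
#' Larger ACC and TPR and smaller FPR mean a better segmentation. A ratio
#' whose denominator is zero is reported as `NA`, not 0.
#'
#' @param cc a [confusion_counts()] object, or a list with fields
#'   `tp, fp, tn, fn`.
#' @return a `segmentation_metrics` list with fields
#'   `acc, tpr, fpr, precision, f_measure`.
#' @export
segmentation_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  if (any(c(tp, fp, tn, fn) < 0)) stopf("confusion counts must be non-negative")
  n <- tp + fp + tn + fn
  if (n == 0) stopf("all confusion counts are zero")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rat(tp, tp + fn)
  prec <- rat(tp, tp + fp)
  f <- if (!is.na(tpr) && !is.na(prec) && (tpr + prec) > 0)
    2 * prec * tpr / (prec + tpr) else NA_real_
  structure(list(acc = (tp + tn) / n, tpr = tpr, fpr = rat(fp, fp + tn),
                 precision = prec, f_measure = f),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  TPR %.4f  FPR %.4f  precision %.4f  F %.4f\n",
              x$acc, x$tpr, x$fpr, x$precision, x$f_measure))
  invisible(x)
}

#' TPR at a matched false-positive rate
#'
#' Chooses the threshold at which the fused map marks exactly the given
#' fraction of true background pixels as vessel, then measures the recall on
#' vessel pixels at that threshold. Comparing two detectors at matched FPR
#' removes the choice of operating point from the comparison.
#'
#' @param fused numeric fused response matrix.
#' @param truth logical ground-truth vessel mask.
#' @param fov logical FOV mask (default whole frame).
#' @param fpr target false-positive rate in (0, 1).
#' @param on optional logical mask restricting which truth pixels recall is
#'   measured on (e.g. thin-vessel pixels only); default all truth pixels.
#' @return recall (TPR) at the matched operating point.
#' @export
tpr_at_fpr <- function(fused, truth, fov = NULL, fpr = 0.05, on = NULL) {
  check_image(fused, "fused map"); check_mask(truth, "truth")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(fused), ncol(fused))
  bg <- fused[fov & !truth]
  t0 <- stats::quantile(bg, probs = 1 - fpr, names = FALSE, type = 7)
  target <- if (is.null(on)) truth else truth & on
  v <- fused[fov & target]
  if (!length(v)) stopf("no truth pixels to measure recall on")
  mean(v >= t0)
}

#' Sweep thresholds and tabulate the ROC-style trade-off
#'
#' @param fused numeric fused response matrix.
#' @param truth logical ground-truth vessel mask.
#' @param fov logical FOV mask (default whole frame).
#' @param quantiles vessel-fraction values q to sweep (default 0.02 to 0.30).
#' @return data.frame with columns `q, threshold, acc, tpr, fpr, precision,
#'   f_measure`.
#' @export
threshold_sweep <- function(fused, truth, fov = NULL,
                            quantiles = seq(0.02, 0.30, by = 0.02)) {
  if (is.null(fov)) fov <- matrix(TRUE, nrow(fused), ncol(fused))
  rows <- lapply(quantiles, function(q) {
    mask <- threshold_map(fused, fov, method = "quantile", value = q)
    m <- segmentation_metrics(confusion_counts(mask, truth, fov))
    data.frame(q = q, threshold = attr(mask, "threshold"), acc = m$acc,
               tpr = m$tpr, fpr = m$fpr, precision = m$precision,
               f_measure = m$f_measure)
  })
  do.call(rbind, rows)
}
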