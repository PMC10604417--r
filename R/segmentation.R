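#' Otsu threshold over a 256-bin histogram, optionally inside a mask
#'
#' Finds the grey-level cut `t` maximising the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the 256-bin histogram of the
#' in-mask pixels; binarization labels pixels with value `> t` as
#' foreground. Ties in the maximum are broken toward the smallest
#' threshold. A constant in-mask image has no two classes to separate and
#' is flagged degenerate instead of guessing.
#'
#' @param image 2D numeric matrix with values in 0..255.
#' @param within_mask optional `{0, 1}` matrix; only pixels where the mask
#'   is 1 enter the histogram.
#' @return list with `threshold` (integer in 0..254, or `NA` when
#'   degenerate) and `degenerate` (logical).
#' @export
otsu_threshold <- function(image, within_mask = NULL) {
  stopifnot(is.matrix(image))
  px <- if (is.null(within_mask)) as.numeric(image) else {
    stopifnot(identical(dim(image), dim(within_mask)))
    as.numeric(image[within_mask == 1])
  }
  px <- as.integer(pmin(255, pmax(0, round(px))))
  if (length(px) == 0 || length(unique(px)) < 2) {
    warning("degenerate Otsu input: constant or empty region")
    return(list(threshold = NA_integer_, degenerate = TRUE))
  }
  h <- tabulate(px + 1L, nbins = 256L)
  n <- sum(h)
  w0 <- cumsum(h)[1:255]            # pixels with value <= t, t = 0..254
  s0 <- cumsum(h * (0:255))[1:255]
  w1 <- n - w0
  total <- sum(h * (0:255))
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (s0[valid] / w0[valid] - (total - s0[valid]) / w1[valid])^2
  list(threshold = which.max(bcv) - 1L, degenerate = FALSE)
}

#' Mask-assisted Otsu segmentation of a slice
#'
#' Refines a predicted grain mask by thresholding the masked original
#' image: pixels outside the prediction are zeroed, Otsu's threshold is
#' computed over the histogram of that masked image (the zeroed background
#' included), and only in-mask pixels brighter than the threshold are
#' kept. Including the zeros anchors the dark class, so an accurate mask -
#' whose interior is pure grain tissue - is passed through intact, while
#' false-positive blobs whose underlying intensities fall below the
#' threshold are removed. The output foreground is always a subset of the
#' predicted foreground. When the masked image is constant (an all-ones
#' prediction over a flat slice) there is nothing to separate and the
#' predicted mask is returned unchanged, with a warning.
#'
#' @param original 2D intensity matrix (0..255).
#' @param predicted `{0, 1}` mask of the same dimensions.
#' @return `{0, 1}` mask.
#' @export
assisted_segment <- function(original, predicted) {
  stopifnot(identical(dim(original), dim(predicted)))
  if (!all(predicted %in% c(0, 1)))
    stop("predicted mask must be binary {0,1}")
  if (sum(predicted) == 0) return(predicted * 0)
  masked <- original
  masked[predicted == 0] <- 0
  ot <- otsu_threshold(masked)
  if (ot$degenerate) return(predicted)
  ((original > ot$threshold) & (predicted == 1)) + 0
}

#' Segmentation quality metrics for binary masks
#'
#' Pixel-count confusion metrics for a predicted vs reference mask:
#' precision TP/(TP+FP), recall TP/(TP+FN), per-class intersection over
#' union TP/(TP+FP+FN), the class means mIoU and mPA taken over the
#' k + 1 = 2 categories (grain foreground and background), and overall
#' pixel accuracy (TP+TN)/total. A class absent from both masks is scored
#' 1 (vacuously correct) in the per-class means.
#'
#' @param pred,truth `{0, 1}` matrices or 3D arrays of equal dimensions.
#' @return list of class `seg_metrics` with fields `precision`, `recall`,
#'   `iou` (foreground), `iou_background`, `miou`, `mpa`,
#'   `pixel_accuracy`, and the raw counts `tp`, `fp`, `fn`, `tn`.
#' @export
seg_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dimensions differ")
  p <- as.numeric(pred); t <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be binary {0,1}")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  rat <- function(num, den) if (den == 0) 1 else num / den
  iou_fg <- rat(tp, tp + fp + fn)
  iou_bg <- rat(tn, tn + fp + fn)
  pa_fg <- rat(tp, tp + fn)   # per-class pixel accuracy
  pa_bg <- rat(tn, tn + fp)
  structure(list(precision = rat(tp, tp + fp), recall = rat(tp, tp + fn),
                 iou = iou_fg, iou_background = iou_bg,
                 miou = (iou_fg + iou_bg) / 2, mpa = (pa_fg + pa_bg) / 2,
                 pixel_accuracy = rat(tp + tn, tp + fp + fn + tn),
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf(paste0("segmentation metrics: precision %.4f  recall %.4f  ",
                     "IoU %.4f  mIoU %.4f  mPA %.4f  pixel acc %.4f\n"),
              x$precision, x$recall, x$iou, x$miou, x$mpa,
              x$pixel_accuracy))
  invisible(x)
}
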