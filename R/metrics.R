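# Pixel-level detection scoring against labelled ground truth.

#' Confusion counts within an evaluation ROI
#'
#' Counts are restricted to the ROI; prediction and truth outside it are
#' ignored. The four counts partition the ROI exactly.
#'
#' @param pred logical predicted vein mask.
#' @param truth logical ground-truth vein mask.
#' @param roi logical evaluation region (defaults to the whole image).
#' @return Object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `total`.
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  vm_assert(is_binary_matrix(pred) && is_binary_matrix(truth),
            "veinmap_format_error", "pred and truth must be binary matrices")
  if (!identical(dim(pred), dim(truth))) {
    vm_stop("veinmap_format_error", "pred and truth shapes differ")
  }
  pred <- as_logical_mask(pred); truth <- as_logical_mask(truth)
  if (is.null(roi)) {
    roi <- matrix(TRUE, nrow(pred), ncol(pred))
  } else {
    if (!identical(dim(roi), dim(pred))) {
      vm_stop("veinmap_format_error", "roi shape differs from masks")
    }
    roi <- as_logical_mask(roi)
  }
  p <- pred[roi]; t <- truth[roi]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 total = sum(roi)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (ROI %d px)\n",
              x$tp, x$fp, x$tn, x$fn, x$total))
  invisible(x)
}

#' True-positive vein detection rate (percent)
#'
#' The proportion of the pixels identified as vein that are correct:
#' `100 * tp / (tp + fp)`. Undefined (an error) when nothing was identified
#' as vein.
#'
#' @param c a [confusion_counts()].
#' @return percentage in `[0, 100]`.
#' @export
tp_rate <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fp == 0L) {
    vm_stop("veinmap_degenerate_error",
            "no pixels identified as vein: TP rate undefined")
  }
  100 * c$tp / (c$tp + c$fp)
}

#' Detection accuracy and total error rate (percent)
#'
#' `accuracy = 100 (tp + tn) / total`; the total error rate is its exact
#' complement `100 (fp + fn) / total`, computed as `100 - accuracy` so the
#' partition identity `accuracy + error_rate == 100` holds exactly in
#' floating point.
#'
#' @param c a [confusion_counts()] with a non-empty ROI.
#' @return percentage in `[0, 100]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  vm_assert(c$total > 0L, "veinmap_degenerate_error", "empty evaluation ROI")
  100 * (c$tp + c$tn) / c$total
}

#' @rdname accuracy
#' @export
error_rate <- function(c) {
  100 - accuracy(c)
}

#' Per-axis absolute position errors between matched 3-D point sets
#'
#' Axes follow the TOF camera frame: x transverse, y longitudinal, z along
#' the optical axis, all in mm.
#'
#' @param estimated,truth matched `n x 3` point matrices (mm).
#' @return data.frame with one row per axis and columns `axis`, `min`,
#'   `max`, `mean` of the absolute errors.
#' @export
position_errors <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!identical(dim(estimated), dim(truth)) || ncol(estimated) != 3L) {
    vm_stop("veinmap_format_error",
            "estimated and truth must be matched n x 3 matrices")
  }
  e <- abs(estimated - truth)
  data.frame(axis = c("x", "y", "z"),
             min = apply(e, 2L, min),
             max = apply(e, 2L, max),
             mean = colMeans(e),
             row.names = NULL)
}
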