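#' Detect subcutaneous veins in a SWIR image
#'
#' Runs the full feature-extraction chain: Otsu foreground segmentation,
#' construction of the two edge-discarding ROI masks (background dilated by
#' 10 px and 15 px square elements), contrast enhancement (CLAHE + 1%
#' percentile adjustment) and vein extraction — each performed independently
#' under the narrow and the wide mask — followed by a logical AND of the two
#' binary results, which removes false detections caused by segmentation
#' edges.
#'
#' @param img a [swir_image()].
#' @param method `"maxcurv"` (maximum-curvature ridge extraction) or
#'   `"kmeans"` (3-cluster intensity clustering).
#' @param config a [pipeline_config()]; relevant knobs: `mask$widths`,
#'   `clahe`, `adjust$saturation`, `maxcurv$sigma`, `kmeans$*`,
#'   `preprocess$invert`.
#' @param seed RNG seed for the k-means initialization (overrides
#'   `config$kmeans$seed` when given).
#' @return Object of class `vein_detection`: `mask` (logical, subset of both
#'   ROI masks), `method`, `roi` (the [build_masks()] result), `threshold`,
#'   and `per_mask` (the two pre-AND detections).
#' @export
detect_veins <- function(img, method = c("kmeans", "maxcurv"),
                         config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(img, "swir_image"))
  method <- match.arg(method)
  seed <- if (is.null(seed)) config$kmeans$seed else seed
  seg <- segment_foreground(img, invert = config$preprocess$invert)
  roi <- build_masks(seg$foreground, widths = config$mask$widths,
                     threshold = seg$threshold)
  extract_one <- function(mask) {
    enh <- enhance_contrast(img, mask,
                            tiles = config$clahe$tiles,
                            clip = config$clahe$clip,
                            saturation = config$adjust$saturation,
                            bins = config$clahe$bins)
    if (method == "maxcurv") {
      plane <- accumulate_plane(enh, mask, sigma = config$maxcurv$sigma)
      connect_and_binarize(plane) & mask
    } else {
      model <- kmeans_segment(enh, mask, K = config$kmeans$K, seed = seed,
                              tol = config$kmeans$tol,
                              max_iter = config$kmeans$max_iter)
      select_vein_cluster(model)
    }
  }
  det_narrow <- extract_one(roi$mask_narrow)
  det_wide <- extract_one(roi$mask_wide)
  structure(list(mask = det_narrow & det_wide,
                 method = method,
                 roi = roi,
                 threshold = seg$threshold,
                 per_mask = list(narrow = det_narrow, wide = det_wide)),
            class = "vein_detection")
}

#' @export
print.vein_detection <- function(x, ...) {
  cat(sprintf("<vein_detection> method = %s, %d vein px (%.2f%% of ROI)\n",
              x$method, sum(x$mask),
              100 * sum(x$mask) / max(1L, sum(x$roi$mask_wide))))
  invisible(x)
}
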