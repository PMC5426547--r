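#' Otsu's global threshold
#'
#' Selects the intensity level that minimizes the weighted intra-class
#' variance of the pixels at or below the level versus those above it,
#' searching every candidate level of the image histogram. Foreground is
#' defined as pixels strictly above the returned level: under active NIR
#' illumination the tissue reflects brightly while the table and unlit
#' background stay dark.
#'
#' @param img a [swir_image()] (or a plain numeric matrix, in which case
#'   `bins` levels over its range are assumed to be `0..bins-1`).
#' @param bins number of histogram levels; defaults to the full A/D range
#'   `2^bit_depth`.
#' @return the threshold level (intensity units).
#' @export
otsu_threshold <- function(img, bins = NULL) {
  if (inherits(img, "swir_image")) {
    v <- as.vector(img$pixels)
    if (is.null(bins)) bins <- 2L^img$bit_depth
  } else {
    v <- as.vector(img)
    if (is.null(bins)) bins <- 256L
  }
  if (length(unique(v)) < 2L) {
    vm_stop("veinmap_degenerate_error",
            "constant image: Otsu threshold undefined (degenerate histogram)")
  }
  # histogram over integer levels 0..bins-1 (values clamped/binned)
  lv <- pmin.int(pmax.int(floor(v), 0), bins - 1L)
  h <- tabulate(lv + 1L, nbins = bins)
  levels <- 0:(bins - 1L)
  n <- length(v)
  # cumulative moments of the "at or below t" class for every candidate t
  w0 <- cumsum(h)
  s0 <- cumsum(h * levels)
  q0 <- cumsum(h * levels^2)
  w1 <- n - w0
  s1 <- s0[bins] - s0
  q1 <- q0[bins] - q0
  var0 <- ifelse(w0 > 0, q0 / w0 - (s0 / w0)^2, 0)
  var1 <- ifelse(w1 > 0, q1 / w1 - (s1 / w1)^2, 0)
  intra <- (w0 * var0 + w1 * var1) / n
  # only thresholds that split the data into two non-empty classes
  ok <- w0 > 0 & w1 > 0
  intra[!ok] <- Inf
  levels[which.min(intra)]   # ties: smallest level (which.min convention)
}

#' Foreground segmentation of a SWIR image
#'
#' Binarizes at a threshold (Otsu's by default) and keeps the single largest
#' connected component, dropping bright speckle outside the arm.
#'
#' @param img a [swir_image()].
#' @param threshold intensity level; pixels strictly above it are foreground.
#'   `NULL` runs [otsu_threshold()].
#' @param invert set `TRUE` if the subject is darker than the background.
#' @param largest_component keep only the largest connected foreground blob.
#' @return list with `foreground` (logical matrix) and `threshold`.
#' @export
segment_foreground <- function(img, threshold = NULL, invert = FALSE,
                               largest_component = TRUE) {
  stopifnot(inherits(img, "swir_image"))
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  fg <- if (invert) img$pixels < threshold else img$pixels > threshold
  if (largest_component && any(fg)) {
    lab <- EBImage::bwlabel(fg * 1L)
    sizes <- tabulate(lab[lab > 0])
    fg <- lab == which.max(sizes)
  }
  list(foreground = fg, threshold = threshold)
}

#' Dual edge-discarding region-of-interest masks
#'
#' The background region is dilated twice, with square structuring elements
#' of two widths (10 and 15 px by default), and each mask is the complement
#' of the dilated background: pixels near the background/foreground edge —
#' where segmentation transitions produce spurious detections — are excluded.
#' A `w x w` square element is anchored at offsets
#' `-(w %/% 2) .. (w - 1) %/% 2` in each axis (centered; for even widths the
#' extra reach goes toward the top-left). The wider element removes more
#' pixels, so the masks nest: `mask_wide` is a subset of `mask_narrow`, which
#' is a subset of the foreground.
#'
#' @param foreground logical (or 0/1) matrix from [segment_foreground()].
#' @param widths two structuring-element widths in pixels, narrow first.
#' @param threshold threshold the foreground was computed at (metadata).
#' @return Object of class `roi_masks` with `foreground`, `mask_narrow`,
#'   `mask_wide`, `widths`, `threshold`.
#' @export
build_masks <- function(foreground, widths = c(10L, 15L), threshold = NA_real_) {
  vm_assert(is_binary_matrix(foreground), "veinmap_format_error",
            "foreground must be a binary matrix")
  vm_assert(length(widths) == 2L && all(widths >= 1),
            "veinmap_format_error", "widths must be two values >= 1")
  widths <- as.integer(sort(widths))
  fg <- as_logical_mask(foreground)
  dilate_bg <- function(w) {
    if (w == 1L) return(fg)           # identity structuring element
    bg <- (!fg) * 1L
    d <- EBImage::dilate(bg, matrix(1L, w, w))
    fg & !(d > 0)
  }
  structure(list(foreground = fg,
                 mask_narrow = dilate_bg(widths[1L]),
                 mask_wide = dilate_bg(widths[2L]),
                 widths = widths, threshold = threshold),
            class = "roi_masks")
}

#' Contrast enhancement: CLAHE plus percentile intensity adjustment
#'
#' Contrast-limited adaptive histogram equalization compensates non-uniform
#' illumination across the masked region; the result is then linearly
#' remapped so that the 1st and 99th percentiles (by default) of the masked
#' pixels reach the extremes of the output range `[0, 2^bit_depth - 1]`,
#' saturating 1% of the data at each end. Pixels outside the mask are zeroed.
#'
#' CLAHE operates tile-wise, so background pixels inside a tile would skew
#' its histogram; they are filled with the masked mean before equalization.
#' The image is edge-padded to a multiple of the tile grid and cropped back.
#' A constant masked region has no contrast to equalize and passes through
#' unchanged (the percentile map is degenerate).
#'
#' @param img a [swir_image()].
#' @param mask logical ROI matrix (non-empty).
#' @param tiles tile grid `c(nx, ny)`.
#' @param clip clip limit as a fraction of the tile histogram mass.
#' @param saturation fraction saturated at each intensity extreme.
#' @param bins histogram bins used by CLAHE.
#' @return an enhanced [swir_image()] (continuous intensities in
#'   `[0, 2^bit_depth - 1]`).
#' @export
enhance_contrast <- function(img, mask, tiles = c(8L, 8L), clip = 0.01,
                             saturation = 0.01, bins = 256L) {
  stopifnot(inherits(img, "swir_image"))
  vm_assert(is_binary_matrix(mask) && identical(dim(mask), dim(img$pixels)),
            "veinmap_format_error", "mask must be binary and match the image")
  mask <- as_logical_mask(mask)
  vm_assert(any(mask), "veinmap_degenerate_error", "mask is empty")
  maxv <- 2^img$bit_depth - 1
  mv <- img$pixels[mask]
  if (diff(range(mv)) < .Machine$double.eps * maxv) {
    out <- img$pixels
    out[!mask] <- 0
    return(swir_image(out, img$bit_depth))
  }
  x <- img$pixels / maxv
  x[!mask] <- 0   # equalize the masked image; the zero mass stays at the
                  # bottom bins and is never clustered or scanned
  # pad to a multiple of the tile grid (EBImage requirement), then crop
  nx <- as.integer(tiles[1L]); ny <- as.integer(tiles[2L])
  nr <- nrow(x); nc <- ncol(x)
  pr <- (ny - nr %% ny) %% ny
  pc <- (nx - nc %% nx) %% nx
  xp <- x
  if (pr > 0) xp <- rbind(xp, xp[rep(nr, pr), , drop = FALSE])
  if (pc > 0) xp <- cbind(xp, xp[, rep(ncol(xp), pc), drop = FALSE])
  # EBImage images are indexed (x, y): transpose so tiles follow our rows/cols
  eq <- EBImage::clahe(t(xp), nx = nx, ny = ny, bins = bins,
                       limit = clip * bins)
  eq <- t(as.matrix(eq))[seq_len(nr), seq_len(nc), drop = FALSE]
  # percentile adjustment on masked pixels only
  q <- stats::quantile(eq[mask], c(saturation, 1 - saturation),
                       names = FALSE, type = 7)
  if (q[2L] - q[1L] < .Machine$double.eps) {
    out <- eq * maxv
  } else {
    out <- (eq - q[1L]) / (q[2L] - q[1L]) * maxv
    out <- pmin.int(pmax.int(out, 0), maxv)
  }
  out[!mask] <- 0
  swir_image(matrix(out, nr, nc), img$bit_depth)
}
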