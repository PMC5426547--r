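# Base-graphics display methods for the pipeline's raster products.

raster_plot <- function(m, col = grDevices::gray.colors(256, 0, 1), ...) {
  # matrix row 1 = top image row; image() draws x right / y up
  graphics::image(x = seq_len(ncol(m)) - 1, y = seq_len(nrow(m)) - 1,
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = col, asp = 1, xlab = "x (px)", ylab = "y (px)",
                  useRaster = TRUE, ...)
}

#' @export
plot.swir_image <- function(x, ...) {
  raster_plot(x$pixels, main = sprintf("SWIR image (%d-bit)", x$bit_depth), ...)
  invisible(x)
}

#' Display a vein detection over its SWIR ROI
#' @param x a [detect_veins()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.vein_detection <- function(x, ...) {
  base <- x$roi$foreground * 0.4 + x$roi$mask_wide * 0.2
  base[x$mask] <- 1
  raster_plot(base, col = c(grDevices::gray.colors(200, 0, 0.7),
                            grDevices::colorRampPalette(c("red", "red"))(56)),
              main = sprintf("vein detection (%s)", x$method), ...)
  invisible(x)
}

#' Display the registered depth of a SWIR-D product
#' @param x a [register_tof_to_swir()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.swir_d <- function(x, ...) {
  d <- x$depth_reg
  d[!x$valid] <- NA
  raster_plot(d, col = grDevices::hcl.colors(256, "viridis"),
              main = "SWIR-D registered depth (mm)", ...)
  invisible(x)
}
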