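# Online fusion of TOF range data into the SWIR frame.

#' Register a TOF frame into the SWIR pixel grid (SWIR-D)
#'
#' Every valid TOF pixel is distortion-corrected, mapped into the SWIR grid
#' by the fitted linear map, and splatted onto its nearest SWIR pixel (when
#' several samples land on one pixel the one closest to the pixel center
#' wins). Because the SWIR grid is roughly 3.6x denser than the TOF grid the
#' splat leaves gaps; these are filled from the nearest splatted sample
#' within `fill_radius` SWIR pixels (chamfer-propagated 8-neighbour
#' distance). Filling copies the sample's depth and its full 3-D point, so
#' every registered coordinate is a genuine surface sample. Pixels farther
#' than `fill_radius` from any sample stay invalid.
#'
#' @param tof a [tof_frame()].
#' @param map a [linear_map2d()] from undistorted TOF pixel coordinates to
#'   SWIR pixel coordinates.
#' @param swir a [swir_image()] defining the target grid.
#' @param fill_radius gap-fill radius in SWIR pixels.
#' @return Object of class `swir_d`: `swir`, `depth_reg` (mm, `NA` where
#'   invalid), `xyz_reg` (`rows x cols x 3` mm), `valid`, `map`,
#'   `fill_radius`.
#' @export
register_tof_to_swir <- function(tof, map, swir, fill_radius = 4) {
  stopifnot(inherits(tof, "tof_frame"), inherits(map, "linear_map2d"),
            inherits(swir, "swir_image"))
  nr <- swir$height; nc <- swir$width
  src <- matrix(0L, nr, nc)
  dist <- matrix(Inf, nr, nc)
  vidx <- which(tof$valid)
  if (length(vidx) > 0L) {
    nrt <- nrow(tof$depth)
    # 0-based pixel-center coordinates of the valid TOF pixels
    tr <- (vidx - 1L) %% nrt
    tc <- (vidx - 1L) %/% nrt
    p_und <- denormalize_point(
      undistort_point(normalize_pixel(cbind(tc, tr), tof$intrinsics),
                      tof$intrinsics), tof$intrinsics)
    q <- apply_linear_map(map, p_und)
    qc <- round(q[, 1L]); qr <- round(q[, 2L])
    inside <- qc >= 0 & qc < nc & qr >= 0 & qr < nr
    if (any(inside)) {
      d2 <- (q[inside, 1L] - qc[inside])^2 + (q[inside, 2L] - qr[inside])^2
      cell <- qr[inside] + 1L + qc[inside] * nr
      keep <- order(d2, decreasing = TRUE)   # last write = closest to center
      src[cell[keep]] <- which(inside)[keep]
      dist[cell[keep]] <- 0
    }
  }
  # chamfer propagation of the nearest splatted sample
  offs <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
                c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))
  for (it in seq_len(ceiling(fill_radius))) {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      cd <- shift_mat(dist, offs[k, 1L], offs[k, 2L], fill = Inf) + offs[k, 3L]
      cs <- shift_mat(src, offs[k, 1L], offs[k, 2L], fill = 0L)
      upd <- cs > 0L & cd < dist
      if (any(upd)) {
        dist[upd] <- cd[upd]
        src[upd] <- cs[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  valid <- src > 0L & dist <= fill_radius
  src[!valid] <- 0L
  depth_vals <- tof$depth[vidx]
  x_vals <- tof$xyz[, , 1L][vidx]
  y_vals <- tof$xyz[, , 2L][vidx]
  z_vals <- tof$xyz[, , 3L][vidx]
  depth_reg <- matrix(NA_real_, nr, nc)
  xyz_reg <- array(NA_real_, c(nr, nc, 3L))
  sel <- which(valid)
  si <- src[sel]
  depth_reg[sel] <- depth_vals[si]
  xyz_reg[sel] <- x_vals[si]
  xyz_reg[sel + nr * nc] <- y_vals[si]
  xyz_reg[sel + 2L * nr * nc] <- z_vals[si]
  structure(list(swir = swir, depth_reg = depth_reg, xyz_reg = xyz_reg,
                 valid = valid, map = map, fill_radius = fill_radius),
            class = "swir_d")
}

#' @export
print.swir_d <- function(x, ...) {
  cat(sprintf("<swir_d> %d x %d px, %.1f%% with registered depth\n",
              ncol(x$valid), nrow(x$valid), 100 * mean(x$valid)))
  invisible(x)
}

#' Map detected veins to labelled 3-D points
#'
#' Emits one 3-D point (TOF camera frame, mm) for every vein-mask pixel that
#' carries a valid registered depth.
#'
#' @param det a [detect_veins()] result (or a plain logical vein mask on the
#'   SWIR grid).
#' @param fused a [register_tof_to_swir()] result on the same grid.
#' @return `n x 3` matrix of points (columns x, y, z in mm) with an integer
#'   `label` attribute (all 1, the vein class).
#' @export
map_veins_3d <- function(det, fused) {
  stopifnot(inherits(fused, "swir_d"))
  mask <- if (inherits(det, "vein_detection")) det$mask else as_logical_mask(det)
  vm_assert(identical(dim(mask), dim(fused$valid)),
            "veinmap_format_error", "vein mask and SWIR-D shapes differ")
  sel <- which(mask & fused$valid)
  nrnc <- length(fused$valid)
  pts <- cbind(x = fused$xyz_reg[sel],
               y = fused$xyz_reg[sel + nrnc],
               z = fused$xyz_reg[sel + 2L * nrnc])
  attr(pts, "label") <- rep.int(1L, nrow(pts))
  pts
}
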