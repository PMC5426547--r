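#' SWIR intensity image
#'
#' Container for a single-channel short-wave infrared reflectance image.
#' Pixels are stored as a numeric `rows x cols` matrix of A/D counts in
#' `[0, 2^bit_depth - 1]`. The package-wide raster convention is: row 1 of the
#' matrix is the top image row, column 1 the left column, and geometric pixel
#' coordinates are 0-based with pixel centers at integer positions, `x` along
#' columns and `y` along rows (so pixel `(x, y)` lives at `pixels[y + 1, x + 1]`).
#'
#' @param pixels numeric matrix of intensities (counts).
#' @param bit_depth integer A/D bit depth; intensities must fit in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `swir_image` with fields `pixels`, `bit_depth`,
#'   `width`, `height`.
#' @export
swir_image <- function(pixels, bit_depth = 14L) {
  vm_assert(is.matrix(pixels) && is.numeric(pixels),
            "veinmap_format_error", "pixels must be a numeric matrix")
  vm_assert(nrow(pixels) > 0 && ncol(pixels) > 0,
            "veinmap_format_error", "image must be non-empty")
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxv, na.rm = TRUE)) {
    vm_stop("veinmap_range_error",
            sprintf("intensities outside [0, %d] for bit depth %d", maxv, bit_depth))
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         width = ncol(pixels), height = nrow(pixels)),
    class = "swir_image"
  )
}

#' @export
print.swir_image <- function(x, ...) {
  cat(sprintf("<swir_image> %d x %d px, %d-bit, intensity range [%g, %g]\n",
              x$width, x$height, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-channel SWIR image from TIFF or PNG
#'
#' Intensities are preserved bit-exactly. Multi-channel input is rejected;
#' values exceeding the stated bit depth raise a range error.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param bit_depth A/D bit depth of the sensor (counts assumed stored in a
#'   16-bit container).
#' @return A [swir_image()].
#' @export
read_swir <- function(path, bit_depth = 14L) {
  vm_assert(file.exists(path), "veinmap_io_error",
            sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    # readPNG scales to [0,1] over the container range; PNG containers
    # are 8 or 16 bit, both exactly invertible here.
    a <- round(a * 65535)
    if (max(a) < 256 && bit_depth <= 8) a <- round(a / 257)
  } else {
    vm_stop("veinmap_format_error", sprintf("unsupported image format: .%s", ext))
  }
  if (length(dim(a)) != 2L) {
    vm_stop("veinmap_format_error",
            sprintf("expected single-channel image, got %d channels: %s",
                    dim(a)[3], path))
  }
  swir_image(matrix(as.numeric(a), nrow(a), ncol(a)), bit_depth = bit_depth)
}

#' Write a SWIR image as 16-bit grayscale TIFF
#'
#' @param img a [swir_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swir <- function(img, path) {
  stopifnot(inherits(img, "swir_image"))
  tiff::writeTIFF(round(img$pixels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  vm_assert(is_binary_matrix(mask), "veinmap_format_error", "mask must be binary")
  png::writePNG(as_logical_mask(mask) * 1.0, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#' @param path PNG path; any nonzero pixel is foreground.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}

#' Time-of-flight range frame
#'
#' Bundles the co-registered per-pixel amplitude, depth and camera-frame XYZ
#' rasters from a TOF camera. XYZ is back-projected along the
#' distortion-corrected pixel ray: the pixel is normalized with the TOF
#' intrinsics, undistorted, and the normalized ray scaled by depth, so the
#' z component equals depth wherever valid. A pixel is valid when its depth
#' is positive and its amplitude reaches `amplitude_floor` (a screen against
#' flying pixels and low-signal noise; 0 disables it).
#'
#' @param depth numeric matrix of radial-corrected depth along the optical
#'   axis (mm).
#' @param amplitude numeric matrix of signal amplitude (counts), same shape.
#' @param intrinsics a [camera_intrinsics()] for the TOF camera.
#' @param amplitude_floor minimum amplitude for a pixel to count as valid.
#' @return Object of class `tof_frame` with fields `amplitude`, `depth`,
#'   `xyz` (array `rows x cols x 3`, mm) and `valid` (logical matrix).
#' @export
tof_frame <- function(depth, amplitude, intrinsics, amplitude_floor = 0) {
  vm_assert(is.matrix(depth) && is.matrix(amplitude),
            "veinmap_format_error", "depth and amplitude must be matrices")
  if (!identical(dim(depth), dim(amplitude))) {
    vm_stop("veinmap_format_error", "depth and amplitude shapes differ")
  }
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  nr <- nrow(depth); nc <- ncol(depth)
  valid <- is.finite(depth) & depth > 0 & amplitude >= amplitude_floor
  # pixel-center coordinates (0-based): x along columns, y along rows
  px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  py <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  np <- undistort_point(normalize_pixel(cbind(as.vector(px), as.vector(py)),
                                        intrinsics), intrinsics)
  xyz <- array(NA_real_, c(nr, nc, 3L))
  d <- as.vector(depth)
  xyz[, , 1L] <- matrix(np[, 1L] * d, nr, nc)
  xyz[, , 2L] <- matrix(np[, 2L] * d, nr, nc)
  xyz[, , 3L] <- depth
  structure(list(amplitude = amplitude, depth = depth, xyz = xyz,
                 valid = valid, intrinsics = intrinsics),
            class = "tof_frame")
}

#' @export
print.tof_frame <- function(x, ...) {
  cat(sprintf("<tof_frame> %d x %d px, %d valid (%.1f%%), depth %g-%g mm\n",
              ncol(x$depth), nrow(x$depth), sum(x$valid),
              100 * mean(x$valid),
              suppressWarnings(min(x$depth[x$valid])),
              suppressWarnings(max(x$depth[x$valid]))))
  invisible(x)
}

# Read a float raster from 32-bit float TIFF or whitespace-delimited text.
read_raster <- function(path) {
  vm_assert(file.exists(path), "veinmap_io_error",
            sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    if (length(dim(a)) != 2L) {
      vm_stop("veinmap_format_error", "expected single-channel raster")
    }
    matrix(as.numeric(a), nrow(a), ncol(a))
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
}

#' Write a float raster as whitespace-delimited text
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_text <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TOF frame from depth and amplitude rasters
#'
#' Rasters may be 32-bit float TIFF or whitespace-delimited text; both must
#' share one shape. XYZ is back-projected with the supplied intrinsics (see
#' [tof_frame()] for the ray convention).
#'
#' @param depth_path,amplitude_path raster file paths (depth in mm).
#' @param intrinsics a [camera_intrinsics()].
#' @param amplitude_floor validity screen, see [tof_frame()].
#' @return A [tof_frame()].
#' @export
read_tof <- function(depth_path, amplitude_path, intrinsics, amplitude_floor = 0) {
  depth <- read_raster(depth_path)
  amplitude <- read_raster(amplitude_path)
  if (!identical(dim(depth), dim(amplitude))) {
    vm_stop("veinmap_format_error", "depth and amplitude shapes differ")
  }
  tof_frame(depth, amplitude, intrinsics, amplitude_floor)
}

#' Write labelled 3D points as ascii PLY
#'
#' One vertex per point with float `x`, `y`, `z` (mm) and, when labels are
#' given, an integer scalar property `label`.
#'
#' @param points numeric matrix `n x 3` (columns x, y, z, mm).
#' @param path output path.
#' @param labels optional integer vector of length `n`.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(points, path, labels = NULL) {
  if (is.null(points) || length(points) == 0L) {
    points <- matrix(numeric(0), 0L, 3L)
  }
  points <- as.matrix(points)
  vm_assert(ncol(points) == 3L, "veinmap_format_error", "points must be n x 3")
  vm_assert(all(is.finite(points)), "veinmap_range_error",
            "point coordinates must be finite")
  n <- nrow(points)
  if (!is.null(labels)) {
    vm_assert(length(labels) == n, "veinmap_format_error",
              "labels length must match point count")
  }
  hdr <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (!is.null(labels)) "property int label",
    "end_header"
  )
  body <- if (n > 0L) {
    coords <- apply(points, 1L, function(p)
      paste(format(p, digits = 9, trim = TRUE, scientific = FALSE), collapse = " "))
    if (is.null(labels)) coords else paste(coords, as.integer(labels))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ascii PLY point cloud written by [write_pointcloud()]
#' @param path PLY path.
#' @return list with `points` (`n x 3` matrix) and `labels` (integer vector
#'   or `NULL`).
#' @export
read_pointcloud <- function(path) {
  lines <- readLines(path)
  vm_assert(identical(lines[1L], "ply"), "veinmap_format_error", "not a PLY file")
  end <- match("end_header", lines)
  vm_assert(!is.na(end), "veinmap_format_error", "PLY header not terminated")
  vline <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  n <- as.integer(sub("^element vertex ", "", vline[1L]))
  has_label <- any(grepl("^property int label", lines[seq_len(end)]))
  if (n == 0L) {
    return(list(points = matrix(numeric(0), 0L, 3L),
                labels = if (has_label) integer(0) else NULL))
  }
  body <- do.call(rbind, lapply(lines[(end + 1L):(end + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  list(points = body[, 1:3, drop = FALSE],
       labels = if (has_label) as.integer(body[, 4L]) else NULL)
}

#' Read / write control-point pairs
#'
#' CSV with header `x1,y1,x2,y2`: `(x1, y1)` in the TOF pixel frame (F1),
#' `(x2, y2)` in the SWIR pixel frame (F2), 0-based pixel coordinates.
#'
#' @param path CSV path.
#' @return `read_control_points`: object of class `control_point_pairs` — a
#'   list with `x1` (`n x 2`), `x2` (`n x 2`) and `n`.
#' @export
read_control_points <- function(path) {
  d <- utils::read.csv(path)
  vm_assert(all(c("x1", "y1", "x2", "y2") %in% names(d)),
            "veinmap_format_error", "control point CSV needs header x1,y1,x2,y2")
  control_point_pairs(as.matrix(d[, c("x1", "y1")]), as.matrix(d[, c("x2", "y2")]))
}

#' @rdname read_control_points
#' @param pairs a `control_point_pairs` object.
#' @export
write_control_points <- function(pairs, path) {
  stopifnot(inherits(pairs, "control_point_pairs"))
  d <- data.frame(x1 = pairs$x1[, 1L], y1 = pairs$x1[, 2L],
                  x2 = pairs$x2[, 1L], y2 = pairs$x2[, 2L])
  utils::write.csv(format(d, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Control-point correspondences between the TOF and SWIR frames
#' @param x1 `n x 2` matrix of points in the TOF pixel frame (F1).
#' @param x2 `n x 2` matrix of matching points in the SWIR pixel frame (F2).
#' @return Object of class `control_point_pairs`.
#' @export
control_point_pairs <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  vm_assert(ncol(x1) == 2L && ncol(x2) == 2L && nrow(x1) == nrow(x2),
            "veinmap_format_error", "x1 and x2 must be matching n x 2 matrices")
  vm_assert(all(is.finite(x1)) && all(is.finite(x2)),
            "veinmap_range_error", "control points must be finite")
  structure(list(x1 = unname(x1), x2 = unname(x2), n = nrow(x1)),
            class = "control_point_pairs")
}

#' Read / write camera intrinsics as JSON
#'
#' JSON keys: `fx`, `fy`, `cx`, `cy`, `k1`, `k2`, `k3`.
#' @param path JSON path.
#' @return `read_intrinsics`: a [camera_intrinsics()].
#' @export
read_intrinsics <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(fx = j$fx, fy = j$fy, cx = j$cx, cy = j$cy,
                    k1 = j$k1 %||% 0, k2 = j$k2 %||% 0, k3 = j$k3 %||% 0)
}

#' @rdname read_intrinsics
#' @param intr a [camera_intrinsics()].
#' @export
write_intrinsics <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  jsonlite::write_json(unclass(intr), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a fitted TOF-to-SWIR transform as JSON
#'
#' JSON keys: `R` (2x2, row-major), `T` (length 2), `epsilon`, `inliers`,
#' `seed`.
#' @param path JSON path.
#' @return `read_transform`: a [linear_map2d()].
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- if (is.matrix(j$R)) j$R else do.call(rbind, j$R)   # rows as written
  linear_map2d(R, as.numeric(j$T),
               epsilon = j$epsilon %||% NA_real_,
               inliers = j$inliers %||% NA_integer_,
               seed = j$seed %||% NA_integer_)
}

#' @rdname read_transform
#' @param map a [linear_map2d()].
#' @export
write_transform <- function(map, path) {
  stopifnot(inherits(map, "linear_map2d"))
  jsonlite::write_json(
    list(R = lapply(seq_len(2L), function(i) map$R[i, ]),
         T = map$T, epsilon = map$epsilon, inliers = map$inliers,
         seed = map$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
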