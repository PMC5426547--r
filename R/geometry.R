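#' Camera intrinsics with radial distortion
#'
#' Pinhole model with a three-coefficient radial (Brown) distortion. A pixel
#' `(col, row)` maps to the normalized imaging coordinate
#' `x = (col - cx)/fx`, `y = (row - cy)/fy`; the lens then distorts it as
#' `x_d = x (1 + k1 r^2 + k2 r^4 + k3 r^6)` (likewise `y_d`) with
#' `r^2 = x^2 + y^2`.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in 0-based pixel coordinates.
#' @param k1,k2,k3 radial distortion coefficients (dimensionless).
#' @return Object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0) {
  vm_assert(is.finite(fx) && is.finite(fy) && fx > 0 && fy > 0,
            "veinmap_range_error", "focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3),
            class = "camera_intrinsics")
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  as.matrix(p)
}

#' Pixel to normalized imaging coordinates (and back)
#'
#' `normalize_pixel` translates to the optical center and divides by the
#' focal length in pixels; `denormalize_point` is its exact inverse.
#'
#' @param p point(s): length-2 vector or `n x 2` matrix, `(x = col, y = row)`.
#' @param intr a [camera_intrinsics()].
#' @return points in the same shape as the input.
#' @export
normalize_pixel <- function(p, intr) {
  m <- as_point_matrix(p)
  out <- cbind((m[, 1L] - intr$cx) / intr$fx, (m[, 2L] - intr$cy) / intr$fy)
  if (is.null(dim(p))) out[1L, ] else out
}

#' @rdname normalize_pixel
#' @export
denormalize_point <- function(p, intr) {
  m <- as_point_matrix(p)
  out <- cbind(m[, 1L] * intr$fx + intr$cx, m[, 2L] * intr$fy + intr$cy)
  if (is.null(dim(p))) out[1L, ] else out
}

#' Apply radial lens distortion to normalized points
#'
#' @inheritParams normalize_pixel
#' @return distorted normalized points, same shape as input.
#' @export
distort_point <- function(p, intr) {
  m <- as_point_matrix(p)
  r2 <- m[, 1L]^2 + m[, 2L]^2
  f <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  out <- m * f
  if (is.null(dim(p))) out[1L, ] else out
}

#' Invert radial lens distortion
#'
#' Fixed-point iteration `x <- x_d / (1 + k1 r^2 + k2 r^4 + k3 r^6)` with
#' `r` evaluated at the current estimate, started from the distorted point.
#' Converges for the moderate coefficient magnitudes of real lenses.
#'
#' @param p distorted normalized point(s): length-2 vector or `n x 2` matrix.
#' @param intr a [camera_intrinsics()].
#' @param tol convergence tolerance on the per-iteration step (normalized
#'   units).
#' @param max_iter iteration cap; exceeding it raises a convergence error.
#' @return undistorted normalized points, same shape as input.
#' @export
undistort_point <- function(p, intr, tol = 1e-12, max_iter = 50L) {
  m <- as_point_matrix(p)
  if (intr$k1 == 0 && intr$k2 == 0 && intr$k3 == 0) {
    return(if (is.null(dim(p))) m[1L, ] else m)
  }
  cur <- m
  for (it in seq_len(max_iter)) {
    r2 <- cur[, 1L]^2 + cur[, 2L]^2
    f <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
    nxt <- m / f
    step <- max(abs(nxt - cur))
    cur <- nxt
    if (step < tol) {
      return(if (is.null(dim(p))) cur[1L, ] else cur)
    }
  }
  vm_stop("veinmap_convergence_error",
          sprintf("undistortion did not converge in %d iterations", max_iter))
}

#' Undistort the TOF side of control-point pairs
#'
#' Control points are typically picked on the raw (distorted) TOF amplitude
#' image; this maps the F1 side to distortion-corrected pixel coordinates so
#' the linear-map fit sees an undistorted frame.
#'
#' @param pairs a [control_point_pairs()].
#' @param intr TOF [camera_intrinsics()].
#' @return a new `control_point_pairs` with corrected `x1`.
#' @export
undistort_pairs <- function(pairs, intr) {
  stopifnot(inherits(pairs, "control_point_pairs"))
  x1 <- denormalize_point(
    undistort_point(normalize_pixel(pairs$x1, intr), intr), intr)
  control_point_pairs(x1, pairs$x2)
}

#' 2D linear map between pixel grids
#'
#' The TOF-to-SWIR transform `X2 = R X1 + T`, with `R` a general invertible
#' 2x2 matrix and `T` a 2-vector in SWIR pixels. `R` is not constrained to a
#' pure rotation: the two cameras have different pixel pitches and fields of
#' view, so the map must carry scale (and possibly shear).
#'
#' @param R 2x2 numeric matrix.
#' @param T length-2 numeric vector (SWIR pixels).
#' @param epsilon inlier threshold used when fitted by RANSAC (SWIR pixels).
#' @param inliers inlier count `f0` from the fit.
#' @param seed RNG seed used by the fit.
#' @return Object of class `linear_map2d`.
#' @export
linear_map2d <- function(R, T, epsilon = NA_real_, inliers = NA_integer_,
                         seed = NA_integer_) {
  R <- matrix(as.numeric(R), 2L, 2L)
  T <- as.numeric(T)
  vm_assert(length(T) == 2L, "veinmap_format_error", "T must have length 2")
  vm_assert(all(is.finite(R)) && all(is.finite(T)),
            "veinmap_range_error", "transform must be finite")
  vm_assert(abs(det(R)) > .Machine$double.eps,
            "veinmap_degenerate_error", "R must be invertible")
  structure(list(R = R, T = T, epsilon = epsilon,
                 inliers = inliers, seed = seed),
            class = "linear_map2d")
}

#' @export
print.linear_map2d <- function(x, ...) {
  cat("<linear_map2d> X2 = R X1 + T\n")
  cat(sprintf("  R = [% .6f % .6f; % .6f % .6f]\n",
              x$R[1, 1], x$R[1, 2], x$R[2, 1], x$R[2, 2]))
  cat(sprintf("  T = (% .3f, % .3f) px", x$T[1], x$T[2]))
  if (!is.na(x$inliers)) cat(sprintf("  [%d inliers, eps = %g px]", x$inliers, x$epsilon))
  cat("\n")
  invisible(x)
}

#' Apply a 2D linear map to points
#' @param map a [linear_map2d()].
#' @param p length-2 vector or `n x 2` matrix of points.
#' @return mapped points, same shape as input.
#' @export
apply_linear_map <- function(map, p) {
  m <- as_point_matrix(p)
  out <- m %*% t(map$R)
  out[, 1L] <- out[, 1L] + map$T[1L]
  out[, 2L] <- out[, 2L] + map$T[2L]
  if (is.null(dim(p))) out[1L, ] else out
}

#' Least-squares fit of the TOF-to-SWIR linear map
#'
#' Solves `min sum_i || R x1_i + T - x2_i ||^2` over the six parameters of
#' `(R, T)`. The problem separates per output coordinate into two ordinary
#' linear least-squares fits on the design `[x, y, 1]`.
#'
#' @param pairs a [control_point_pairs()] with at least 3 non-collinear F1
#'   points.
#' @return a [linear_map2d()].
#' @export
estimate_linear_map <- function(pairs) {
  stopifnot(inherits(pairs, "control_point_pairs"))
  vm_assert(pairs$n >= 3L, "veinmap_degenerate_error",
            "at least 3 control-point pairs required")
  X <- cbind(pairs$x1, 1)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    vm_stop("veinmap_degenerate_error",
            "control points are collinear or duplicated (rank-deficient fit)")
  }
  beta <- qr.coef(qr_x, pairs$x2)   # 3 x 2: rows = coefficients for x, y, 1
  linear_map2d(R = t(beta[1:2, , drop = FALSE]), T = beta[3L, ])
}

#' Count inlier correspondences under a transform
#'
#' A pair is an inlier when the Euclidean residual
#' `e = || R x1 + T - x2 ||` is strictly below `epsilon`.
#'
#' @param pairs a [control_point_pairs()].
#' @param map a [linear_map2d()].
#' @param epsilon inlier threshold in SWIR pixels; defaults to the
#'   threshold stored in `map`.
#' @return integer inlier count `f0`.
#' @export
count_inliers <- function(pairs, map, epsilon = map$epsilon) {
  vm_assert(is.finite(epsilon) && epsilon > 0,
            "veinmap_range_error", "epsilon must be a positive number")
  sum(inlier_flags(pairs, map, epsilon))
}

inlier_flags <- function(pairs, map, epsilon) {
  pred <- apply_linear_map(map, pairs$x1)
  e <- sqrt(rowSums((pred - pairs$x2)^2))
  e < epsilon
}

#' RANSAC estimation of the TOF-to-SWIR map
#'
#' Repeatedly samples 3 pairs, fits the exactly-determined map, and scores it
#' by its inlier count `f0`; the transform with the largest `f0` wins (ties:
#' first found). The winner is refit by least squares on its inlier set and
#' the inliers recounted under the refit. The whole procedure is seeded and
#' deterministic.
#'
#' @param pairs a [control_point_pairs()], `n >= 3`.
#' @param epsilon inlier threshold in SWIR pixels.
#' @param iterations number of random minimal samples.
#' @param seed RNG seed.
#' @return a [linear_map2d()] carrying `epsilon`, `inliers` (`f0`) and `seed`.
#' @export
ransac_register <- function(pairs, epsilon = 2, iterations = 2000L, seed = 1L) {
  stopifnot(inherits(pairs, "control_point_pairs"))
  vm_assert(pairs$n >= 3L, "veinmap_degenerate_error",
            "at least 3 control-point pairs required")
  vm_assert(is.finite(epsilon) && epsilon > 0,
            "veinmap_range_error", "epsilon must be a positive number")
  best <- NULL
  best_f0 <- -1L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(pairs$n, 3L)
      sub <- control_point_pairs(pairs$x1[idx, , drop = FALSE],
                                 pairs$x2[idx, , drop = FALSE])
      cand <- tryCatch(estimate_linear_map(sub), veinmap_error = function(e) NULL)
      if (is.null(cand)) next     # degenerate (collinear) sample
      f0 <- count_inliers(pairs, cand, epsilon)
      if (f0 > best_f0) {
        best_f0 <- f0
        best <- cand
      }
    }
  })
  if (is.null(best) || best_f0 < 3L) {
    vm_stop("veinmap_degenerate_error",
            "RANSAC found no transform with at least 3 inliers")
  }
  keep <- inlier_flags(pairs, best, epsilon)
  refit <- estimate_linear_map(
    control_point_pairs(pairs$x1[keep, , drop = FALSE],
                        pairs$x2[keep, , drop = FALSE]))
  f0 <- count_inliers(pairs, refit, epsilon)
  linear_map2d(refit$R, refit$T, epsilon = epsilon, inliers = f0,
               seed = as.integer(seed))
}
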