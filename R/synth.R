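# Seeded synthetic phantom generator.
#
# Emulates the imaging physics of the two-camera rig well enough to exercise
# every pipeline stage without hardware: a bright arm-shaped foreground on a
# dark table (tissue reflects the active NIR illumination, the table does
# not), dome-shaped limb shading (the arm's curvature turns cross-sectional
# profiles concave-down away from veins), a smooth multiplicative tissue
# texture (subsurface scattering in the SWIR band low-pass filters all skin
# detail), a mild asymmetric lighting ramp, dark curvilinear veins whose
# cross-section is a Gaussian intensity dent (blood absorbs NIR strongly),
# additive sensor noise and A/D quantization; plus a smooth surface viewed
# by a low-resolution, radially distorted depth camera related to the SWIR
# frame by a planted 2-D linear map.

#' Phantom scene specification
#'
#' All parameters of a synthetic scene, including the planted TOF-to-SWIR
#' map and the ground-truth geometry. A fixed seed yields byte-identical
#' outputs.
#'
#' @param width,height SWIR raster size in pixels (camera-native 636 x 508).
#' @param bit_depth SWIR A/D bit depth.
#' @param background_level,foreground_level table / lit-tissue reflectance as
#'   fractions of full scale.
#' @param illumination_gradient peak-to-center amplitude of the
#'   multiplicative linear illumination ramp (fraction; orientation is drawn
#'   from the seed). The LED arrays flank the camera, so the residual
#'   asymmetry across the arm is small.
#' @param limb_shading fractional intensity drop from the limb center to its
#'   silhouette edge (the arm is a cylinder-like diffuse reflector under
#'   near-coaxial illumination).
#' @param texture_amp,texture_scale amplitude (fraction of local signal) and
#'   correlation length (px) of the smooth multiplicative tissue texture
#'   field.
#' @param n_veins number of planted veins.
#' @param vein_width full visible vein width in pixels (the Gaussian dent
#'   has standard deviation `vein_width / 5`, so the labelled width spans the
#'   visibly darkened region, about 5 sd of the dent);
#'   must be at least 2.
#' @param vein_darkening fractional intensity drop at the vein centerline,
#'   in (0, 1).
#' @param vein_curvature lateral waviness of the vein paths as a fraction of
#'   the foreground half-height.
#' @param noise_sigma additive Gaussian noise, fraction of full scale.
#' @param surface `"bump"` (arm-like smooth bulge on a tilted plane) or
#'   `"plane"`.
#' @param surface_z0 plane depth at the optical axis (mm).
#' @param surface_slope plane gradient `c(dz/dX, dz/dY)` (mm per mm).
#' @param bump_height,bump_sigma bulge height and lateral scale (mm).
#' @param tof_width,tof_height TOF raster size (camera-native 176 x 144).
#' @param tof_intrinsics TOF [camera_intrinsics()] including `k1..k3`.
#' @param map planted [linear_map2d()] from undistorted TOF pixel
#'   coordinates to SWIR pixel coordinates; the default scales by 3.5,
#'   rotates by 2 degrees and centers the TOF frame on the SWIR frame
#'   (matching the ~3.6x resolution ratio of the real rig).
#' @param n_pairs number of control-point pairs to emit.
#' @param pair_jitter_sd Gaussian jitter on the SWIR side of each pair (px).
#' @param pair_outlier_frac fraction of pairs replaced by gross outliers
#'   (displaced by 10-60 px, i.e. well beyond any sensible inlier
#'   threshold); exactly `ceiling(frac * n_pairs)` pairs are contaminated.
#' @param seed RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 636L, height = 508L, bit_depth = 14L,
                         background_level = 0.04, foreground_level = 0.55,
                         illumination_gradient = 0.05,
                         limb_shading = 0.10,
                         texture_amp = 0.012, texture_scale = 30,
                         n_veins = 3L, vein_width = 8, vein_darkening = 0.25,
                         vein_curvature = 0.15, noise_sigma = 0.001,
                         surface = c("bump", "plane"),
                         surface_z0 = 400, surface_slope = c(0.05, -0.03),
                         bump_height = 25, bump_sigma = 45,
                         tof_width = 176L, tof_height = 144L,
                         tof_intrinsics = camera_intrinsics(
                           fx = 222, fy = 222, cx = 87.5, cy = 71.5,
                           k1 = -0.1, k2 = 0.01, k3 = 0),
                         map = NULL,
                         n_pairs = 100L, pair_jitter_sd = 0,
                         pair_outlier_frac = 0, seed = 1L) {
  surface <- match.arg(surface)
  vm_assert(vein_darkening >= 0 && vein_darkening < 1,
            "veinmap_spec_error", "vein_darkening must be in [0, 1)")
  vm_assert(vein_width >= 2, "veinmap_spec_error", "vein_width must be >= 2 px")
  vm_assert(vein_width <= 0.2 * min(width, height),
            "veinmap_spec_error", "vein width exceeds the foreground scale")
  if (is.null(map)) {
    s <- 3.5; th <- 2 * pi / 180
    R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    c_tof <- c((tof_width - 1) / 2, (tof_height - 1) / 2)
    c_swir <- c((width - 1) / 2, (height - 1) / 2)
    map <- linear_map2d(R, c_swir - as.vector(R %*% c_tof))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 foreground_level = foreground_level,
                 illumination_gradient = illumination_gradient,
                 limb_shading = limb_shading,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 n_veins = as.integer(n_veins), vein_width = vein_width,
                 vein_darkening = vein_darkening,
                 vein_curvature = vein_curvature, noise_sigma = noise_sigma,
                 surface = surface, surface_z0 = surface_z0,
                 surface_slope = surface_slope, bump_height = bump_height,
                 bump_sigma = bump_sigma,
                 tof_width = as.integer(tof_width),
                 tof_height = as.integer(tof_height),
                 tof_intrinsics = tof_intrinsics, map = map,
                 n_pairs = as.integer(n_pairs),
                 pair_jitter_sd = pair_jitter_sd,
                 pair_outlier_frac = pair_outlier_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Arm-shaped foreground: a superellipse covering most of the frame.
phantom_foreground <- function(spec) {
  W <- spec$width; H <- spec$height
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  a <- 0.42 * W; b <- 0.36 * H
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), times = W), H, W)
  list(mask = (abs((x - cx) / a)^3 + abs((y - cy) / b)^3) <= 1,
       a = a, b = b, cx = cx, cy = cy)
}

#' Generate a synthetic SWIR phantom
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom`: `image` (a [swir_image()]), `truth`
#'   (logical vein mask: pixels within half a vein width of a planted
#'   centerline, inside the foreground), `foreground` (logical),
#'   `centerline` (logical), `centerline_dist` (px) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    W <- spec$width; H <- spec$height
    maxv <- 2^spec$bit_depth - 1
    fgm <- phantom_foreground(spec)
    fg <- fgm$mask
    # vein centerlines: smooth wavy paths spanning the arm lengthwise
    cl <- matrix(FALSE, H, W)
    if (spec$n_veins > 0L) {
      half_span <- 0.95 * fgm$a
      n_s <- ceiling(2 * half_span / 0.4)
      s <- seq(0, 1, length.out = n_s)
      for (i in seq_len(spec$n_veins)) {
        y0 <- fgm$cy + stats::runif(1, -0.55, 0.55) * fgm$b
        f1 <- stats::runif(1, 0.4, 0.9); p1 <- stats::runif(1, 0, 2 * pi)
        f2 <- stats::runif(1, 1.3, 2.2); p2 <- stats::runif(1, 0, 2 * pi)
        xs <- fgm$cx + (s - 0.5) * 2 * half_span
        ys <- y0 + spec$vein_curvature * fgm$b *
          (0.7 * sin(2 * pi * f1 * s + p1) + 0.3 * sin(2 * pi * f2 * s + p2))
        xi <- round(xs); yi <- round(ys)
        ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
        cl[yi[ok] + 1L + xi[ok] * H] <- TRUE
      }
    }
    cl_dist <- if (any(cl)) {
      as.matrix(EBImage::distmap((!cl) * 1))
    } else {
      matrix(Inf, H, W)
    }
    base <- ifelse(fg, spec$foreground_level, spec$background_level) * maxv
    sigma_c <- spec$vein_width / 5
    dent <- 1 - spec$vein_darkening * exp(-cl_dist^2 / (2 * sigma_c^2))
    img <- base
    img[fg] <- base[fg] * dent[fg]
    # limb shading: dome-shaped falloff toward the silhouette edge, applied
    # to the tissue only (the table is flat)
    if (spec$limb_shading > 0) {
      x <- matrix(rep(0:(W - 1), each = H), H, W)
      y <- matrix(rep(0:(H - 1), times = W), H, W)
      rho2 <- ((x - fgm$cx) / fgm$a)^2 + ((y - fgm$cy) / fgm$b)^2
      shade <- 1 - spec$limb_shading * pmin(rho2, 1)
      img[fg] <- img[fg] * shade[fg]
    }
    # smooth multiplicative tissue texture (unit-variance Gaussian random
    # field, low-pass filtered to the subsurface-scattering scale)
    if (spec$texture_amp > 0) {
      z <- matrix(stats::rnorm(H * W), H, W)
      r <- min(2L * ceiling(3 * spec$texture_scale) + 1L,
               2L * ((min(H, W) - 1L) %/% 2L) + 1L)   # odd, fits the raster
      z <- as.matrix(EBImage::gblur(z, sigma = spec$texture_scale, radius = r))
      z <- z / stats::sd(z)
      img[fg] <- img[fg] * (1 + spec$texture_amp * z[fg])
    }
    # residual asymmetric lighting ramp with seeded orientation
    phi <- stats::runif(1, 0, 2 * pi)
    xn <- matrix(rep(seq(0, 1, length.out = W), each = H), H, W)
    yn <- matrix(rep(seq(0, 1, length.out = H), times = W), H, W)
    img <- img * (1 + 2 * spec$illumination_gradient *
                    ((xn - 0.5) * cos(phi) + (yn - 0.5) * sin(phi)))
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma * maxv)
    }
    img <- round(pmin.int(pmax.int(img, 0), maxv))
    structure(list(image = swir_image(matrix(img, H, W), spec$bit_depth),
                   truth = (cl_dist <= spec$vein_width / 2) & fg,
                   foreground = fg,
                   centerline = cl,
                   centerline_dist = cl_dist,
                   spec = spec),
              class = "phantom")
  })
}

#' Depth of the planted surface along a normalized ray
#'
#' Solves `z = S(x z, y z)` for the spec's surface model, where `(x, y)` is
#' the undistorted normalized imaging coordinate of the ray. Used both to
#' render the TOF depth raster and as the independent geometric oracle in
#' tests.
#'
#' @param spec a [phantom_spec()].
#' @param ray length-2 vector or `n x 2` matrix of normalized coordinates.
#' @return depth(s) in mm.
#' @export
surface_depth <- function(spec, ray) {
  m <- as_point_matrix(ray)
  a <- spec$surface_slope[1L]; b <- spec$surface_slope[2L]
  denom <- 1 - a * m[, 1L] - b * m[, 2L]
  vm_assert(all(denom > 0), "veinmap_range_error",
            "ray does not intersect the surface in front of the camera")
  z <- spec$surface_z0 / denom
  if (spec$surface == "bump") {
    for (it in 1:40) {
      X <- m[, 1L] * z; Y <- m[, 2L] * z
      z_new <- (spec$surface_z0 + a * X + b * Y) -
        spec$bump_height * exp(-(X^2 + Y^2) / (2 * spec$bump_sigma^2))
      if (max(abs(z_new - z)) < 1e-10) { z <- z_new; break }
      z <- z_new
    }
  }
  if (length(ray) == 2L && is.null(dim(ray))) z[1L] else z
}

#' Generate the TOF side of a synthetic scene
#'
#' Renders the planted surface into a TOF depth raster through the distorted
#' sampling grid (each pixel's ray is its undistorted normalized coordinate),
#' derives an amplitude raster by sampling the SWIR phantom through the
#' planted map, and emits control-point pairs: the F1 side in raw
#' (distorted) TOF pixel coordinates — where an operator would click — and
#' the F2 side the exact image of the undistorted point under the planted
#' map, optionally jittered and contaminated with gross outliers.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tof` (a [tof_frame()]), `pairs`
#'   (a [control_point_pairs()]), `map` (the planted [linear_map2d()]) and
#'   `phantom` (the matching [generate_phantom()] output).
#' @export
generate_tof_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ph <- generate_phantom(spec)
  intr <- spec$tof_intrinsics
  tw <- spec$tof_width; th <- spec$tof_height
  px <- matrix(rep(0:(tw - 1), each = th), th, tw)
  py <- matrix(rep(0:(th - 1), times = tw), th, tw)
  pix <- cbind(as.vector(px), as.vector(py))
  ray <- undistort_point(normalize_pixel(pix, intr), intr)
  depth <- matrix(surface_depth(spec, ray), th, tw)
  # amplitude: the phantom seen through the planted map (nearest-pixel)
  p_und <- denormalize_point(ray, intr)
  q <- apply_linear_map(spec$map, p_und)
  qc <- round(q[, 1L]); qr <- round(q[, 2L])
  inside <- qc >= 0 & qc < spec$width & qr >= 0 & qr < spec$height
  amp <- numeric(nrow(q))
  amp[inside] <- ph$image$pixels[qr[inside] + 1L + qc[inside] * spec$height]
  amplitude <- matrix(amp, th, tw)
  tof <- tof_frame(depth, amplitude, intr)
  pairs <- with_seed(spec$seed, {
    x1 <- matrix(NA_real_, 0L, 2L)
    while (nrow(x1) < spec$n_pairs) {
      cand <- cbind(stats::runif(4L * spec$n_pairs, 0, tw - 1),
                    stats::runif(4L * spec$n_pairs, 0, th - 1))
      cu <- denormalize_point(
        undistort_point(normalize_pixel(cand, intr), intr), intr)
      cq <- apply_linear_map(spec$map, cu)
      ci <- round(cq[, 1L]); ri <- round(cq[, 2L])
      ok <- ci >= 0 & ci < spec$width & ri >= 0 & ri < spec$height
      ok[ok] <- ph$foreground[ri[ok] + 1L + ci[ok] * spec$height]
      x1 <- rbind(x1, cand[ok, , drop = FALSE])
    }
    x1 <- x1[seq_len(spec$n_pairs), , drop = FALSE]
    u1 <- denormalize_point(
      undistort_point(normalize_pixel(x1, intr), intr), intr)
    x2 <- apply_linear_map(spec$map, u1)
    if (spec$pair_jitter_sd > 0) {
      x2 <- x2 + matrix(stats::rnorm(length(x2), 0, spec$pair_jitter_sd),
                        ncol = 2L)
    }
    n_out <- ceiling(spec$pair_outlier_frac * spec$n_pairs)
    if (n_out > 0L) {
      idx <- sample.int(spec$n_pairs, n_out)
      ang <- stats::runif(n_out, 0, 2 * pi)
      mag <- stats::runif(n_out, 10, 60)
      x2[idx, ] <- x2[idx, ] + cbind(mag * cos(ang), mag * sin(ang))
    }
    control_point_pairs(x1, x2)
  })
  list(tof = tof, pairs = pairs, map = spec$map, phantom = ph)
}
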