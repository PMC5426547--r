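planted_map <- function() {
  th <- 3 * pi / 180
  linear_map2d(3.5 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
               c(12.5, -8.25))
}

exact_pairs <- function(n, map, seed = 1) {
  set.seed(seed)
  x1 <- cbind(runif(n, 0, 176), runif(n, 0, 144))
  control_point_pairs(x1, apply_linear_map(map, x1))
}

test_that("least squares recovers a planted map exactly and flags degeneracy", {
  map <- planted_map()
  pairs <- exact_pairs(25, map)
  fit <- estimate_linear_map(pairs)
  expect_lt(max(abs(fit$R - map$R)), 1e-9)
  expect_lt(max(abs(fit$T - map$T)), 1e-9)

  id_pairs <- control_point_pairs(pairs$x1, pairs$x1)
  fit_id <- estimate_linear_map(id_pairs)
  expect_equal(fit_id$R, diag(2), tolerance = 1e-10)
  expect_equal(fit_id$T, c(0, 0), tolerance = 1e-9)

  col <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_linear_map(control_point_pairs(col, col + 1)),
               class = "veinmap_degenerate_error")
})

test_that("inlier counting uses a strict Euclidean threshold", {
  map <- planted_map()
  pairs <- exact_pairs(40, map)
  expect_equal(count_inliers(pairs, map, epsilon = 1e-9), 40L)

  # a pair displaced by exactly epsilon is NOT an inlier
  x2 <- pairs$x2; x2[1, 1] <- x2[1, 1] + 2
  shifted <- control_point_pairs(pairs$x1, x2)
  expect_equal(count_inliers(shifted, map, epsilon = 2), 39L)
  expect_equal(count_inliers(shifted, map, epsilon = 2 + 1e-9), 40L)

  # random perturbations: counts equal a direct per-pair distance check
  set.seed(7)
  x2r <- pairs$x2 + matrix(rnorm(80, 0, 2), ncol = 2)
  pr <- control_point_pairs(pairs$x1, x2r)
  e <- sqrt(rowSums((apply_linear_map(map, pr$x1) - pr$x2)^2))
  expect_equal(count_inliers(pr, map, epsilon = 2), sum(e < 2))

  # monotone non-decreasing in epsilon
  eps <- c(0.5, 1, 2, 4, 8)
  counts <- vapply(eps, function(ep) count_inliers(pr, map, ep), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("RANSAC recovers the map from exact pairs at the calibration size", {
  map <- planted_map()
  pairs <- exact_pairs(100, map, seed = 3)
  fit <- ransac_register(pairs, epsilon = 2, iterations = 500, seed = 1)
  expect_equal(fit$inliers, 100L)
  expect_lt(max(abs(fit$R - map$R)), 1e-9)
  expect_lt(max(abs(fit$T - map$T)), 1e-9)
})

test_that("RANSAC rejects 30% gross outliers", {
  map <- planted_map()
  pairs <- exact_pairs(70, map, seed = 4)
  set.seed(99)
  out_x1 <- cbind(runif(30, 0, 176), runif(30, 0, 144))
  out_x2 <- cbind(runif(30, 0, 636), runif(30, 0, 508))
  mixed <- control_point_pairs(rbind(pairs$x1, out_x1),
                               rbind(pairs$x2, out_x2))
  fit <- ransac_register(mixed, epsilon = 2, iterations = 2000, seed = 5)
  expect_gte(fit$inliers, 70L)
  expect_lt(max(abs(fit$R - map$R)), 1e-2)
  expect_lt(sqrt(sum((fit$T - map$T)^2)), 0.5)
})

test_that("RANSAC with no outliers equals the least-squares solution", {
  map <- planted_map()
  pairs <- exact_pairs(50, map, seed = 6)
  set.seed(1)
  noisy <- control_point_pairs(pairs$x1,
                               pairs$x2 + matrix(rnorm(100, 0, 0.1), ncol = 2))
  fit_r <- ransac_register(noisy, epsilon = 2, iterations = 300, seed = 2)
  fit_ls <- estimate_linear_map(noisy)
  expect_equal(fit_r$R, fit_ls$R, tolerance = 1e-12)
  expect_equal(fit_r$T, fit_ls$T, tolerance = 1e-12)
})

test_that("RANSAC is deterministic under a fixed seed and fails on degenerate input", {
  map <- planted_map()
  pairs <- exact_pairs(30, map, seed = 8)
  f1 <- ransac_register(pairs, epsilon = 2, iterations = 100, seed = 3)
  f2 <- ransac_register(pairs, epsilon = 2, iterations = 100, seed = 3)
  expect_identical(f1$R, f2$R)
  expect_identical(f1$T, f2$T)

  same <- control_point_pairs(matrix(5, 10, 2), matrix(9, 10, 2))
  expect_error(ransac_register(same, epsilon = 2, iterations = 50, seed = 1),
               class = "veinmap_degenerate_error")
})

test_that("identity registration reproduces the depth raster", {
  intr0 <- camera_intrinsics(fx = 100, fy = 100, cx = 21.5, cy = 17.5)
  set.seed(2)
  depth <- matrix(400 + rnorm(36 * 44, 0, 5), 36, 44)
  tof <- tof_frame(depth, matrix(100, 36, 44), intr0)
  swir <- swir_image(matrix(1000, 36, 44), bit_depth = 14L)
  fused <- register_tof_to_swir(tof, linear_map2d(diag(2), c(0, 0)), swir,
                                fill_radius = 0)
  expect_true(all(fused$valid))
  expect_equal(fused$depth_reg, depth)
})

test_that("an all-invalid TOF frame registers to an all-invalid SWIR-D", {
  intr0 <- camera_intrinsics(fx = 100, fy = 100, cx = 21.5, cy = 17.5)
  tof <- tof_frame(matrix(-1, 36, 44), matrix(0, 36, 44), intr0)
  swir <- swir_image(matrix(0, 128, 160), bit_depth = 14L)
  fused <- register_tof_to_swir(tof, linear_map2d(diag(2) * 3.5, c(0, 0)), swir)
  expect_false(any(fused$valid))
})

test_that("planted planar scenes register to within 1 mm depth error", {
  spec <- small_spec(seed = 21, surface = "plane")
  sc <- generate_tof_scene(spec)
  fused <- register_tof_to_swir(sc$tof, sc$map, sc$phantom$image)
  v <- which(fused$valid)
  # oracle: invert the planted map, undo distortion, evaluate the plane
  nr <- nrow(fused$valid)
  px <- cbind((v - 1) %/% nr, (v - 1) %% nr)
  back <- t(solve(sc$map$R) %*% (t(px) - sc$map$T))
  ray <- normalize_pixel(back, spec$tof_intrinsics)
  z_true <- surface_depth(spec, ray)
  err <- abs(fused$depth_reg[v] - z_true)
  expect_gte(mean(err < 1), 0.95)
})

test_that("vein mapping emits one surface point per valid vein pixel", {
  spec <- small_spec(seed = 22, surface = "plane")
  sc <- generate_tof_scene(spec)
  fused <- register_tof_to_swir(sc$tof, sc$map, sc$phantom$image)

  expect_equal(nrow(map_veins_3d(matrix(FALSE, 128, 160), fused)), 0L)

  mask <- sc$phantom$truth
  pts <- map_veins_3d(mask, fused)
  expect_equal(nrow(pts), sum(mask & fused$valid))
  plane_z <- spec$surface_z0 + spec$surface_slope[1] * pts[, 1] +
    spec$surface_slope[2] * pts[, 2]
  expect_lt(max(abs(pts[, 3] - plane_z)), 2)
})

test_that("registration is covariant under a rescaled SWIR grid", {
  spec <- small_spec(seed = 23, surface = "plane")
  sc <- generate_tof_scene(spec)
  fused1 <- register_tof_to_swir(sc$tof, sc$map, sc$phantom$image)
  s <- 0.5
  map2 <- linear_map2d(s * sc$map$R, s * sc$map$T)
  swir2 <- swir_image(matrix(0, 64, 80), bit_depth = 14L)
  fused2 <- register_tof_to_swir(sc$tof, map2, swir2,
                                 fill_radius = 2)
  # compare depth at corresponding pixel centers
  r2v <- as.vector(row(fused2$valid)) - 1L
  c2v <- as.vector(col(fused2$valid)) - 1L
  idx1 <- cbind(round(r2v / s) + 1L, round(c2v / s) + 1L)
  ok <- as.vector(fused2$valid) & fused1$valid[idx1]
  expect_gt(mean(ok), 0.5)
  dd <- abs(as.vector(fused2$depth_reg)[ok] - fused1$depth_reg[idx1][ok])
  expect_lt(stats::quantile(dd, 0.95), 1)   # interpolation tolerance (mm)
})
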