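km_img <- function(x, ncol = 1L) {
  matrix(x, length(x) / ncol, ncol)
}

test_that("three distinct values give a zero-error partition", {
  x <- rep(c(10, 120, 230), times = c(5, 7, 9))
  img <- km_img(x, 1L)
  m <- kmeans_segment(img, matrix(TRUE, nrow(img), 1L), K = 3, seed = 1)
  expect_equal(m$J, 0)
  expect_equal(m$centroids, c(10, 120, 230))
  expect_equal(m$sizes, c(5L, 7L, 9L))
})

test_that("separated 1-D groups are recovered exactly (exhaustive oracle)", {
  x <- c(0:9, 100:109, 200:209)
  img <- km_img(x)
  m <- kmeans_segment(img, matrix(TRUE, 30, 1), K = 3, seed = 1)
  expect_equal(m$centroids, c(4.5, 104.5, 204.5))

  # oracle: every 3-cluster partition of sorted 1-D data is defined by two
  # thresholds; enumerate all of them and verify the fit attains the minimum
  xs <- sort(x)
  best <- Inf
  for (i in 1:28) for (j in (i + 1):29) {
    g <- list(xs[1:i], xs[(i + 1):j], xs[(j + 1):30])
    wss <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
    best <- min(best, wss)
  }
  expect_equal(m$J, best)
})

test_that("fit agrees with stats::kmeans on well-separated data", {
  set.seed(42)
  x <- c(rnorm(60, 20, 3), rnorm(70, 120, 5), rnorm(50, 240, 4))
  img <- km_img(x)
  m <- kmeans_segment(img, matrix(TRUE, length(x), 1), K = 3, seed = 2)
  # the reference implementation may warn about empty clusters on unlucky
  # random restarts; only its converged optimum matters here
  ref <- suppressWarnings(
    stats::kmeans(x, centers = 3, nstart = 10, algorithm = "Lloyd"))
  expect_equal(m$centroids, sort(as.vector(ref$centers)), tolerance = 1e-8)
  expect_equal(m$J, ref$tot.withinss, tolerance = 1e-8)
})

test_that("duplicating every pixel keeps centroids and doubles the objective", {
  set.seed(9)
  x <- c(rnorm(40, 30, 5), rnorm(40, 150, 8), rnorm(40, 220, 6))
  img1 <- km_img(x)
  img2 <- km_img(c(x, x))
  m1 <- kmeans_segment(img1, matrix(TRUE, length(x), 1), seed = 3)
  m2 <- kmeans_segment(img2, matrix(TRUE, 2 * length(x), 1), seed = 3)
  expect_equal(m2$centroids, m1$centroids, tolerance = 1e-8)
  expect_equal(m2$J, 2 * m1$J, tolerance = 1e-6)
})

test_that("objective trace is non-increasing across Lloyd iterations", {
  for (s in 1:20) {
    set.seed(s)
    x <- runif(300, 0, 255)
    m <- kmeans_segment(km_img(x), matrix(TRUE, 300, 1), seed = s)
    expect_true(all(diff(m$J_trace) <= 1e-9), label = sprintf("seed %d", s))
  }
})

test_that("result is invariant to pixel ordering for a fixed seed", {
  set.seed(5)
  x <- runif(400, 0, 1000)
  perm <- sample.int(400)
  m1 <- kmeans_segment(km_img(x), matrix(TRUE, 400, 1), seed = 11)
  m2 <- kmeans_segment(km_img(x[perm]), matrix(TRUE, 400, 1), seed = 11)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(as.vector(m1$labels)[perm], as.vector(m2$labels))
})

test_that("too few distinct masked values raise a degenerate error", {
  img <- km_img(rep(c(1, 2), 10))
  expect_error(kmeans_segment(img, matrix(TRUE, 20, 1), K = 3),
               class = "veinmap_degenerate_error")
})

test_that("the vein cluster is the darkest; ties warn and break low", {
  x <- rep(c(10, 120, 230), times = c(5, 7, 9))
  m <- kmeans_segment(km_img(x), matrix(TRUE, 21, 1), seed = 1)
  sel <- select_vein_cluster(m)
  expect_equal(sum(sel), 5L)
  expect_true(all(x[sel] == 10))

  tied <- m
  tied$centroids <- c(50, 50, 50)
  expect_warning(select_vein_cluster(tied), "tied")
})

test_that("k-means recovers planted veins with high cluster purity", {
  spec <- small_spec(seed = 14, vein_darkening = 0.3)
  ph <- generate_phantom(spec)
  masks <- build_masks(segment_foreground(ph$image)$foreground)
  enh <- enhance_contrast(ph$image, masks$mask_narrow)
  model <- kmeans_segment(enh, masks$mask_narrow, seed = 1)
  sel <- select_vein_cluster(model)
  # at least 90% of the selected cluster lies on planted vein pixels
  expect_gte(mean(ph$truth[sel]), 0.9)
})
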