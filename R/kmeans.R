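# k-means vein segmentation.
#
# Pixels inside the ROI are clustered on intensity alone (a 1-D feature)
# into K = 3 groups — background, surrounding tissue and subcutaneous veins.
# Centroids minimize the within-cluster sum of squared errors
# J_K = sum_k sum_{i in C_k} (x_i - m_k)^2 by Lloyd iteration from a seeded
# k-means++ initialization. Blood absorbs NIR strongly, so the vein cluster
# is the one with the lowest centroid intensity.

#' k-means clustering of masked pixel intensities
#'
#' Runs on the sorted intensity vector so the result is invariant to pixel
#' ordering; labels are assigned back to pixels by nearest final centroid
#' (ties to the lower cluster index). Iteration stops when the largest
#' centroid movement drops below `tol` or after `max_iter` sweeps. The
#' objective trace `J_trace` (recorded after each centroid update) is
#' non-increasing.
#'
#' @param img a [swir_image()] (typically contrast-enhanced) or numeric
#'   matrix.
#' @param roi logical mask of pixels to cluster.
#' @param K number of clusters.
#' @param seed RNG seed for the k-means++ initialization.
#' @param tol convergence tolerance on centroid movement (intensity units).
#' @param max_iter Lloyd iteration cap.
#' @return Object of class `kmeans_model`: `centroids` (ascending), `labels`
#'   (integer matrix, `NA` outside the ROI), `sizes`, `J` (final objective),
#'   `J_trace`, `K`, `iterations`, `roi`.
#' @export
kmeans_segment <- function(img, roi, K = 3L, seed = 1L, tol = 1e-6,
                           max_iter = 100L) {
  x_mat <- if (inherits(img, "swir_image")) img$pixels else img
  vm_assert(is_binary_matrix(roi) && identical(dim(roi), dim(x_mat)),
            "veinmap_format_error", "roi must be binary and match the image")
  roi <- as_logical_mask(roi)
  x <- x_mat[roi]
  ux <- unique(x)
  if (length(ux) < K) {
    vm_stop("veinmap_degenerate_error",
            sprintf("need at least %d distinct masked intensities, have %d",
                    K, length(ux)))
  }
  xs <- sort(x)
  centroids <- with_seed(seed, kmeanspp_init_1d(xs, K))
  J_trace <- numeric(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    lab <- assign_nearest_1d(xs, centroids)
    new_c <- centroids
    for (k in seq_len(K)) {
      members <- xs[lab == k]
      if (length(members) > 0L) {
        new_c[k] <- mean(members)
      } else {
        # re-seed an emptied cluster at the point worst served by the rest
        d2 <- (xs - centroids[lab])^2
        new_c[k] <- xs[which.max(d2)]
      }
    }
    lab <- assign_nearest_1d(xs, new_c)
    J_trace <- c(J_trace, sum((xs - new_c[lab])^2))
    moved <- max(abs(new_c - centroids))
    centroids <- new_c
    if (moved < tol || iterations >= max_iter) break
  }
  ord <- order(centroids)
  centroids <- centroids[ord]
  labels_px <- assign_nearest_1d(x, centroids)
  lab_mat <- matrix(NA_integer_, nrow(x_mat), ncol(x_mat))
  lab_mat[roi] <- labels_px
  structure(list(centroids = centroids,
                 labels = lab_mat,
                 sizes = tabulate(labels_px, nbins = K),
                 J = sum((x - centroids[labels_px])^2),
                 J_trace = J_trace,
                 K = as.integer(K),
                 iterations = iterations,
                 seed = seed,
                 roi = roi),
            class = "kmeans_model")
}

# k-means++ seeding on a 1-D sample: first centroid uniform, each next drawn
# with probability proportional to squared distance to the nearest centroid.
kmeanspp_init_1d <- function(x, K) {
  n <- length(x)
  centroids <- numeric(K)
  centroids[1L] <- x[sample.int(n, 1L)]
  d2 <- (x - centroids[1L])^2
  for (k in 2:K) {
    if (all(d2 == 0)) {
      # all mass on existing centroids; pick any remaining distinct value
      centroids[k] <- x[sample.int(n, 1L)]
    } else {
      centroids[k] <- x[sample.int(n, 1L, prob = d2)]
    }
    d2 <- pmin(d2, (x - centroids[k])^2)
  }
  centroids
}

# Nearest-centroid assignment in 1-D; ties go to the lower cluster index.
assign_nearest_1d <- function(x, centroids) {
  d <- outer(x, centroids, function(a, b) (a - b)^2)
  max.col(-d, ties.method = "first")
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> K = %d, %d px, J = %.4g (%d iterations)\n",
              x$K, sum(x$sizes), x$J, x$iterations))
  cat("  centroids:", paste(format(x$centroids, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Select the vein cluster from a fitted k-means model
#'
#' Veins are strong NIR absorbers, hence dark: the vein cluster is the one
#' with the lowest centroid intensity. An exact tie is broken toward the
#' lowest cluster index, with a warning.
#'
#' @param model a [kmeans_segment()] fit.
#' @return logical vein mask over the image grid.
#' @export
select_vein_cluster <- function(model) {
  stopifnot(inherits(model, "kmeans_model"))
  lo <- which(model$centroids == min(model$centroids))
  if (length(lo) > 1L) {
    warning("tied lowest centroids; selecting the lowest cluster index")
  }
  sel <- lo[1L]
  mask <- !is.na(model$labels) & model$labels == sel
  mask
}
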