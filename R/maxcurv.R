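# Maximum-curvature vein extraction.
#
# A vein crossed transversally appears as a dent — a concave-up valley — in
# the intensity profile. The method scans cross-sectional profiles in four
# directions (horizontal, vertical, both 45-degree diagonals), computes the
# curvature of each profile, scores the local curvature maxima inside
# concave regions, accumulates the scores into a plane, reinforces scores
# that line up with their neighbours, and binarizes.

#' Curvature of a 1-D intensity profile
#'
#' `kappa = P'' / (1 + P'^2)^(3/2)` with derivatives taken from the
#' Gaussian-smoothed profile by central finite differences. Sign convention:
#' concave-up valleys (dents, i.e. vein cross-sections) have positive
#' curvature.
#'
#' @param profile numeric vector, length at least 5.
#' @param sigma Gaussian smoothing standard deviation in samples; `0`
#'   disables smoothing.
#' @return numeric vector of curvatures, one per sample.
#' @export
profile_curvature <- function(profile, sigma = 2) {
  vm_assert(length(profile) >= 5L, "veinmap_format_error",
            "profile must have at least 5 samples")
  s <- if (sigma > 0) {
    kr <- min(max(1L, ceiling(4 * sigma)), length(profile) - 1L)
    convolve_odd(profile, gaussian_kernel(sigma, radius = kr))
  } else profile
  n <- length(s)
  # odd-reflection padding: linear profiles keep exactly zero curvature at
  # the boundaries (no spurious end dents at ROI-run edges)
  sp <- pad_odd(s, 1L)
  d1 <- (sp[3:(n + 2L)] - sp[1:n]) / 2
  d2 <- sp[3:(n + 2L)] - 2 * sp[2:(n + 1L)] + sp[1:n]
  d2 / (1 + d1^2)^1.5
}

#' Score curvature dents along a profile
#'
#' Each maximal run of strictly positive curvature yields one dent center at
#' the position of maximum curvature within the run, with score
#' `Scr = max(kappa) * run width`: wide, strongly curved valleys — vein
#' cross-sections — score high, while narrow noise wrinkles score low.
#'
#' @param kappa numeric curvature vector (finite).
#' @param positions positions associated with the samples (defaults to
#'   1-based sample indices).
#' @return data.frame with columns `center` and `score`; zero rows when no
#'   positive run exists.
#' @export
score_dents <- function(kappa, positions = seq_along(kappa)) {
  vm_assert(all(is.finite(kappa)), "veinmap_range_error",
            "curvature must be finite")
  pos_run <- rle(kappa > 0)
  ends <- cumsum(pos_run$lengths)
  starts <- ends - pos_run$lengths + 1L
  keep <- which(pos_run$values)
  if (length(keep) == 0L) {
    return(data.frame(center = positions[0], score = numeric(0)))
  }
  centers <- numeric(length(keep))
  scores <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    run <- starts[i]:ends[i]
    kmax <- which.max(kappa[run])
    centers[j] <- positions[run[kmax]]
    scores[j] <- kappa[run[kmax]] * length(run)
  }
  data.frame(center = centers, score = scores)
}

# Index vectors (column-major, 1-based) for every scan line of each of the
# four directions over an nr x nc grid. Diagonals are sampled at unit pixel
# steps along the 45-degree lattice lines, no interpolation.
direction_lines <- function(nr, nc) {
  rows <- lapply(seq_len(nr), function(r) r + (seq_len(nc) - 1L) * nr)
  cols <- lapply(seq_len(nc), function(c) (c - 1L) * nr + seq_len(nr))
  # main diagonals (down-right): constant c - r
  diag1 <- lapply(seq(-(nr - 1L), nc - 1L), function(k) {
    r <- max(1L, 1L - k):min(nr, nc - k)
    (r + k - 1L) * nr + r
  })
  # anti-diagonals (down-left): constant c + r
  diag2 <- lapply(seq(2L, nr + nc), function(k) {
    r <- max(1L, k - nc):min(nr, k - 1L)
    (k - r - 1L) * nr + r
  })
  list(horizontal = rows, vertical = cols, diag_dr = diag1, diag_dl = diag2)
}

#' Accumulate dent scores over four scan directions
#'
#' For every row, column and both 45-degree diagonals, restricted to the ROI,
#' the cross-sectional profile is scored with [profile_curvature()] and
#' [score_dents()], and the scores are added into an accumulator plane `V`
#' at the dent-center pixels. Intensities are rescaled to `[0, 1]` before
#' curvature so scores are comparable across bit depths.
#'
#' @param img enhanced [swir_image()] (or plain matrix already in `[0,1]`).
#' @param roi logical ROI matrix; profiles are the maximal ROI runs of each
#'   scan line (runs shorter than 5 samples are skipped).
#' @param sigma profile smoothing, see [profile_curvature()].
#' @return Object of class `curvature_plane`: list with `V` (accumulator,
#'   `>= 0`, zero outside the ROI) and `directions` (the four per-direction
#'   contribution planes).
#' @export
accumulate_plane <- function(img, roi, sigma = 2) {
  if (inherits(img, "swir_image")) {
    x <- img$pixels / (2^img$bit_depth - 1)
  } else {
    x <- img
  }
  vm_assert(is_binary_matrix(roi) && identical(dim(roi), dim(x)),
            "veinmap_format_error", "roi must be binary and match the image")
  roi <- as_logical_mask(roi)
  nr <- nrow(x); nc <- ncol(x)
  lines <- direction_lines(nr, nc)
  planes <- lapply(lines, function(dir_lines) {
    V <- matrix(0, nr, nc)
    for (idx in dir_lines) {
      if (length(idx) < 5L) next
      inroi <- roi[idx]
      if (!any(inroi)) next
      runs <- rle(inroi)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (i in which(runs$values & runs$lengths >= 5L)) {
        seg <- idx[starts[i]:ends[i]]
        kappa <- profile_curvature(x[seg], sigma)
        dents <- score_dents(kappa, positions = seg)
        if (nrow(dents) > 0L) {
          V[dents$center] <- V[dents$center] + dents$score
        }
      }
    }
    V
  })
  V <- planes[[1L]] + planes[[2L]] + planes[[3L]] + planes[[4L]]
  structure(list(V = V, directions = planes), class = "curvature_plane")
}

#' Connect dent centers and binarize the score plane
#'
#' Scores are reinforced along each of the four directions: for direction
#' `d`, `C_d(p) = min(max of the two neighbours of p on one side along d,
#' max of the two on the other side)` — a pixel survives only if supported
#' on both sides, which removes isolated responses and bridges one-pixel
#' gaps along a vein. `G = max_d C_d` is thresholded at the median of its
#' strictly positive values (the default rule; an explicit `threshold`
#' overrides it).
#'
#' @param plane a `curvature_plane` from [accumulate_plane()] (or a plain
#'   non-negative score matrix).
#' @param threshold optional explicit threshold on `G`.
#' @return logical vein mask (empty when no positive scores exist).
#' @export
connect_and_binarize <- function(plane, threshold = NULL) {
  V <- if (inherits(plane, "curvature_plane")) plane$V else plane
  vm_assert(all(V >= 0), "veinmap_range_error", "score plane must be >= 0")
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  G <- matrix(0, nrow(V), ncol(V))
  for (d in offs) {
    side1 <- pmax(shift_mat(V, -d[1L], -d[2L]), shift_mat(V, -2L * d[1L], -2L * d[2L]))
    side2 <- pmax(shift_mat(V, d[1L], d[2L]), shift_mat(V, 2L * d[1L], 2L * d[2L]))
    G <- pmax(G, pmin(side1, side2))
  }
  if (is.null(threshold)) {
    pos <- G[G > 0]
    if (length(pos) == 0L) return(matrix(FALSE, nrow(V), ncol(V)))
    threshold <- stats::median(pos)
  }
  G > threshold
}
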