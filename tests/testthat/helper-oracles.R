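# Shared fixtures and independent brute-force oracles.

# Small, fast phantom for unit tests (full camera geometry is exercised in
# the acceptance suite).
small_spec <- function(seed = 1L, ...) {
  defaults <- list(width = 160L, height = 128L, tof_width = 44L,
                   tof_height = 36L,
                   tof_intrinsics = camera_intrinsics(fx = 56, fy = 56,
                                                      cx = 21.5, cy = 17.5,
                                                      k1 = -0.1, k2 = 0.01),
                   vein_width = 6, n_pairs = 40L, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Phantom with geometry only: no noise, texture, shading or lighting ramp.
geometric_spec <- function(seed = 1L, ...) {
  phantom_spec(noise_sigma = 0, texture_amp = 0, limb_shading = 0,
               illumination_gradient = 0, seed = seed, ...)
}

# Exhaustive Otsu: minimize the weighted intra-class variance (equivalently
# the total within-class sum of squares) over every candidate level.
otsu_bruteforce <- function(v, bins = 256L) {
  v <- floor(pmin(pmax(v, 0), bins - 1))
  best_t <- NA_integer_; best <- Inf
  for (t in 0:(bins - 1L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best) { best <- wss; best_t <- t }
  }
  best_t
}

# Set-definition binary dilation: out(p) = any(in(p - o)) over kernel
# offsets o = -(w %/% 2) .. (w - 1) %/% 2 (the package's documented anchor).
dilate_bruteforce <- function(m, w) {
  offs <- seq.int(-(w %/% 2L), (w - 1L) %/% 2L)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in offs) for (dc in offs) {
    out <- out | shift_logical(m, dr, dc)
  }
  out
}

shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Brute-force dent scan: maximal strictly-positive runs of kappa.
dents_bruteforce <- function(kappa) {
  centers <- integer(0); scores <- numeric(0)
  i <- 1L; n <- length(kappa)
  while (i <= n) {
    if (kappa[i] > 0) {
      j <- i
      while (j < n && kappa[j + 1L] > 0) j <- j + 1L
      run <- i:j
      centers <- c(centers, run[which.max(kappa[run])])
      scores <- c(scores, max(kappa[run]) * length(run))
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(center = centers, score = scores)
}

# Per-pixel min/max connection template + median binarization, double loop.
connect_bruteforce <- function(V) {
  nr <- nrow(V); nc <- ncol(V)
  at <- function(r, c) if (r >= 1 && r <= nr && c >= 1 && c <= nc) V[r, c] else 0
  G <- matrix(0, nr, nc)
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    g <- 0
    for (d in dirs) {
      s1 <- max(at(r + d[1], c + d[2]), at(r + 2 * d[1], c + 2 * d[2]))
      s2 <- max(at(r - d[1], c - d[2]), at(r - 2 * d[1], c - 2 * d[2]))
      g <- max(g, min(s1, s2))
    }
    G[r, c] <- g
  }
  pos <- G[G > 0]
  if (length(pos) == 0L) return(matrix(FALSE, nr, nc))
  G > stats::median(pos)
}

# 90-degree counter-clockwise rotation of a matrix.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

expect_veinmap_error <- function(expr, class) {
  expect_error(expr, class = class)
}
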