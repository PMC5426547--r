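# Internal helpers shared across modules.

# Classed error constructor so callers can distinguish failure modes
# (format, range, degenerate input, convergence) programmatically.
vm_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "veinmap_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

vm_assert <- function(cond, class, msg) {
  if (!isTRUE(cond)) vm_stop(class, msg)
}

# Run `expr` under a given RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Sampled, renormalized Gaussian kernel of standard deviation `sigma` (px).
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  z <- seq(-radius, radius)
  k <- exp(-z^2 / (2 * sigma^2))
  k / sum(k)
}

# Odd (point-symmetric) reflection padding: linear trends continue through
# the boundary, so smoothing and differencing stay exact on linear profiles.
pad_odd <- function(x, r) {
  n <- length(x)
  r <- min(r, n - 1L)
  c(2 * x[1L] - x[(r + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - r)])
}

# 1-D convolution with odd-reflection padding; returns same length.
convolve_odd <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  xp <- pad_odd(x, r)
  n <- length(x)
  out <- numeric(n)
  # direct accumulation: kernel lengths are small (radius <= ~4 sigma)
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * xp[j:(j + n - 1L)]
  }
  out
}

is_binary_matrix <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_logical_mask <- function(m) {
  if (is.logical(m)) m else matrix(m != 0, nrow(m), ncol(m))
}
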