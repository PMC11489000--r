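# Internal numeric helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so every simulator is a pure function of its arguments.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Stable per-subject seed derived from a master seed; keeps results invariant
# to the order in which subjects are processed. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + as.double(index) * 7919) %% 2147483629L) + 1L
}

# One-dimensional Gaussian smoothing matrix (n x n), rows normalised so that
# edges are renormalised rather than darkened.
gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-0.5 * (d / sigma)^2)
  w[abs(d) > ceiling(4 * sigma)] <- 0
  sweep(w, 1L, rowSums(w), "/")
}

#' Masked separable Gaussian smoothing of a 2D field
#'
#' Smooths `img` with an isotropic Gaussian of standard deviation `sigma`
#' voxels. When `mask` is supplied, only voxels inside the mask contribute and
#' the result is renormalised by the smoothed mask, so values do not bleed in
#' from outside the support. Voxels outside the mask are returned as NA.
#'
#' @param img numeric matrix.
#' @param sigma smoothing scale in voxels.
#' @param mask optional logical matrix of the same shape.
#' @return numeric matrix of the same shape.
#' @keywords internal
#' @noRd
smooth2d <- function(img, sigma, mask = NULL) {
  stopifnot(is.matrix(img))
  sx <- gauss_smoother(nrow(img), sigma)
  sy <- gauss_smoother(ncol(img), sigma)
  if (is.null(mask)) return(sx %*% img %*% t(sy))
  stopifnot(identical(dim(mask), dim(img)))
  w <- matrix(as.numeric(mask), nrow(img))
  img[!mask] <- 0  # NAs outside the support must not propagate
  num <- sx %*% (img * w) %*% t(sy)
  den <- sx %*% w %*% t(sy)
  out <- num / den
  out[!mask] <- NA_real_
  out
}

# Standardised smooth Gaussian random field: white noise blurred at
# `scale` voxels, then z-scored. Consumes the current RNG stream.
smooth_gaussian_field <- function(shape, scale) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  s <- smooth2d(z, scale)
  (s - mean(s)) / stats::sd(s)
}

# Map a standardised field to a positive lognormal field with a target mean
# and relative dispersion (SD/mean) inside `mask`; the mean is matched exactly
# by a final rescale.
lognormal_field <- function(z, mask, mean, rd) {
  sigma <- sqrt(log1p(rd^2))
  x <- exp(sigma * z)
  x * (mean / base::mean(x[mask]))
}

# Filled ellipse mask on an nr x nc grid (centre and semi-axes in voxels).
ellipse_mask <- function(nr, nc, cx, cy, rx, ry) {
  xs <- matrix(seq_len(nr), nr, nc)
  ys <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

# Spatial mean and relative dispersion (sample SD / mean) of a voxel vector.
spatial_summary <- function(values, what = "values") {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("need at least 2 valid voxels to summarise ", what)
  m <- mean(values)
  if (m <= 0)
    stop("relative dispersion undefined: spatial mean of ", what, " is <= 0")
  c(mean = m, rd = stats::sd(values) / m)
}

# Tiny stable content hash (FNV-1a over serialized bytes) used to stamp run
# outputs with their configuration; avoids an external digest dependency.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
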