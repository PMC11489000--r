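# Specific-ventilation mapping by matched-filter template correlation.

#' Default specific-ventilation candidate grid
#'
#' 50 logarithmically spaced SV candidates on \[0.01, 10\], covering the
#' physiological range (roughly 0.05-0.5 at rest) with headroom for both
#' near-gas-trapping and very fast-equilibrating units.
#'
#' @param n number of candidates.
#' @param lower,upper grid bounds (dimensionless SV).
#' @return strictly increasing numeric vector.
#' @export
default_sv_grid <- function(n = 50, lower = 0.01, upper = 10) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Build normalised washin/washout templates
#'
#' For each candidate SV, drives the alveolar gas dilution recursion
#' ([gas_step()]) with the schedule's inspired-O2 sequence (starting in
#' equilibrium with room air) and z-normalises the resulting time course to
#' zero mean and unit Euclidean norm. The inner product of a similarly
#' normalised voxel time course with a template is then exactly the Pearson
#' correlation, which is what the estimator maximises. Candidates whose
#' template is numerically constant are excluded with a notice.
#'
#' @param schedule a `breath_schedule`.
#' @param grid strictly increasing positive SV candidates.
#' @return matrix (breaths x candidates) with attribute `grid` holding the
#'   retained candidate values.
#' @export
build_templates <- function(schedule, grid = default_sv_grid()) {
  stopifnot(inherits(schedule, "breath_schedule"))
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and positive")
  nb <- length(schedule$fio2)
  f <- rep(0.21, length(grid))
  tpl <- matrix(NA_real_, nb, length(grid))
  for (n in seq_len(nb)) {
    f <- gas_step(f, schedule$fio2[n], grid)
    tpl[n, ] <- f
  }
  centred <- sweep(tpl, 2L, colMeans(tpl))
  norms <- sqrt(colSums(centred^2))
  keep <- norms > 1e-10
  if (!all(keep))
    message(sum(!keep), " constant template(s) below the numerical floor excluded")
  out <- sweep(centred[, keep, drop = FALSE], 2L, norms[keep], "/")
  attr(out, "grid") <- grid[keep]
  out
}

#' Rigid integer-shift alignment of an image time series
#'
#' Aligns every frame to the series median image by FFT phase correlation,
#' restricted to whole-voxel translations. The logged shift of frame k is its
#' estimated displacement relative to the reference; alignment applies the
#' inverse translation circularly, so
#' `circular_shift(input_frame, -dx, -dy)` reproduces the output frame
#' exactly and the operation is invertible. All-zero frames cannot be
#' aligned and are flagged with a zero shift.
#'
#' @param series numeric array (x, y, frame) with at least 2 frames, or an
#'   `sv_series` object.
#' @param max_shift largest plausible displacement in voxels; larger apparent
#'   shifts are treated as registration failure for that frame (zero shift,
#'   flagged).
#' @return list with `aligned` (array), `shifts` (frames x 2 integer matrix)
#'   and `flagged` (logical per frame).
#' @export
register_series <- function(series, max_shift = 10) {
  if (inherits(series, "sv_series")) series <- series$series
  stopifnot(length(dim(series)) == 3)
  nb <- dim(series)[3]
  if (nb < 2) stop("need at least 2 frames to register")
  ref <- apply(series, c(1, 2), stats::median)
  fref <- stats::fft(ref)
  nr <- nrow(ref); nc <- ncol(ref)
  shifts <- matrix(0L, nb, 2, dimnames = list(NULL, c("dx", "dy")))
  flagged <- logical(nb)
  aligned <- series
  for (k in seq_len(nb)) {
    frame <- series[, , k]
    if (all(frame == 0)) { flagged[k] <- TRUE; next }
    cross <- fref * Conj(stats::fft(frame))
    cc <- Re(stats::fft(cross, inverse = TRUE))
    peak <- which.max(cc)
    dx <- (peak - 1) %% nr
    dy <- (peak - 1) %/% nr
    if (dx > nr / 2) dx <- dx - nr
    if (dy > nc / 2) dy <- dy - nc
    if (abs(dx) > max_shift || abs(dy) > max_shift) { flagged[k] <- TRUE; next }
    shifts[k, ] <- as.integer(c(-dx, -dy))   # displacement of the frame
    aligned[, , k] <- circular_shift(frame, dx, dy)
  }
  list(aligned = aligned, shifts = shifts, flagged = flagged)
}

#' Circular translation of a matrix by whole voxels
#'
#' Moves content by (dx, dy) voxels towards larger indices, wrapping at the
#' edges; exactly invertible by negating the shift. Used by
#' [register_series()] both to model frame displacement and to undo it.
#'
#' @param m numeric matrix.
#' @param dx,dy integer shifts along rows/columns.
#' @return the translated matrix.
#' @export
circular_shift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dx) %% nr) + 1, ((seq_len(nc) - 1 - dy) %% nc) + 1]
}

#' Estimate a specific-ventilation map by template matching
#'
#' For every lung voxel, computes the Pearson correlation between its signal
#' time course and the model washin/washout template of each candidate SV,
#' and assigns the candidate with the highest correlation (ties broken
#' towards the smaller SV). Because correlation is invariant to affine
#' rescaling of the time course, the estimate does not depend on local coil
#' gain or baseline signal. Voxels whose best correlation falls below
#' `min_corr`, or whose time course has zero variance, carry no trusted
#' estimate and are excluded from the valid mask; counts are reported in the
#' QC slot.
#'
#' @param series numeric array (x, y, breath) or an `sv_series` object.
#' @param schedule the `breath_schedule` that generated the series.
#' @param mask logical lung mask (taken from the `sv_series` if omitted).
#' @param grid SV candidate values (see [default_sv_grid()]).
#' @param min_corr minimum acceptable template correlation (default 0.5).
#' @return object of class `sv_map` with matrices `sv` and `correlation`
#'   (NA outside the valid mask), `valid_mask`, the `grid`, and `qc` counts.
#' @export
estimate_sv_map <- function(series, schedule, mask = NULL,
                            grid = default_sv_grid(), min_corr = 0.5) {
  if (inherits(series, "sv_series")) {
    if (is.null(mask)) mask <- series$lung_mask
    series <- series$series
  }
  stopifnot(length(dim(series)) == 3, is.matrix(mask))
  if (dim(series)[3] != length(schedule$fio2))
    stop("series frame count must equal the schedule length")
  if (!any(mask)) stop("lung mask is empty")

  tpl <- build_templates(schedule, grid)
  grid <- attr(tpl, "grid")
  idx <- which(mask)
  x <- t(apply(series, 3, function(fr) fr[idx]))   # breaths x voxels
  x <- sweep(x, 2L, colMeans(x))
  norms <- sqrt(colSums(x^2))
  flat <- norms <= 1e-12
  norms[flat] <- 1
  x <- sweep(x, 2L, norms, "/")

  r <- crossprod(x, tpl)                           # voxels x candidates
  best <- max.col(r, ties.method = "first")        # first = smaller SV on ties
  best_r <- r[cbind(seq_along(best), best)]
  ok <- !flat & best_r >= min_corr

  shp <- dim(mask)
  sv <- matrix(NA_real_, shp[1], shp[2])
  corr <- matrix(NA_real_, shp[1], shp[2])
  valid <- matrix(FALSE, shp[1], shp[2])
  sv[idx[ok]] <- grid[best[ok]]
  corr[idx[ok]] <- best_r[ok]
  valid[idx[ok]] <- TRUE

  structure(list(sv = sv, correlation = corr, valid_mask = valid,
                 grid = grid, min_corr = min_corr,
                 qc = list(n_mask = length(idx), n_valid = sum(ok),
                           n_flat = sum(flat),
                           n_low_corr = sum(!flat & best_r < min_corr))),
            class = "sv_map")
}

#' @export
print.sv_map <- function(x, ...) {
  cat("Specific-ventilation map\n")
  cat(sprintf("  %d/%d voxels valid (%d flat, %d below r = %.2f)\n",
              x$qc$n_valid, x$qc$n_mask, x$qc$n_flat, x$qc$n_low_corr,
              x$min_corr))
  if (x$qc$n_valid >= 2) {
    s <- sv_summary(x)
    cat(sprintf("  mean SV %.3f, relative dispersion %.3f\n", s["mean"], s["rd"]))
  }
  invisible(x)
}

#' Spatial summary of a specific-ventilation map
#'
#' Mean SV and relative dispersion (spatial sample SD divided by spatial
#' mean, the standard regional heterogeneity index) over the valid voxels.
#'
#' @param map an `sv_map`, or a numeric vector of SV values.
#' @return named vector `c(mean, rd)`.
#' @export
sv_summary <- function(map) {
  values <- if (inherits(map, "sv_map")) map$sv[map$valid_mask] else map
  spatial_summary(values, "SV")
}
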