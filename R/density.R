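# Dual-echo proton-density mapping and coil-sensitivity estimation.

#' Back-extrapolate dual-echo signal to TE = 0
#'
#' Under monoexponential transverse decay S(TE) = S0 exp(-TE/T2*), two echoes
#' determine both unknowns in closed form:
#' \deqn{T_2^* = (TE_2 - TE_1)/\ln(S_1/S_2), \quad
#'       S_0 = S_1 (S_1/S_2)^{TE_1/(TE_2-TE_1)}.}
#' Voxels that do not decay (S1 <= S2, e.g. pure noise) have no defined T2*
#' and are flagged and returned as NA.
#'
#' @param s1,s2 signal at the first/second echo (matrices or vectors).
#' @param te1,te2 echo times in ms, 0 < te1 < te2.
#' @return list with `s0`, `t2star` (same shape as the input, NA where
#'   flagged) and the logical `flagged` map.
#' @examples
#' extrapolate_s0(100, 50, 1, 2)  # s0 = 200, t2star = 1/ln 2
#' @export
extrapolate_s0 <- function(s1, s2, te1, te2) {
  if (!(te1 > 0) || te2 <= te1) stop("need 0 < te1 < te2")
  if (!identical(dim(s1), dim(s2)) || length(s1) != length(s2))
    stop("echo images must have the same shape")
  bad <- !(is.finite(s1) & is.finite(s2)) | s2 <= 0 | s1 <= s2
  ratio <- s1 / s2
  ratio[bad] <- NA_real_
  t2star <- (te2 - te1) / log(ratio)
  s0 <- s1 * ratio^(te1 / (te2 - te1))
  s0[bad] <- NA_real_
  list(s0 = s0, t2star = t2star, flagged = bad)
}

#' Calibrate an extrapolated signal map to absolute water density
#'
#' Converts the TE = 0 signal map to mL H2O per cm^3 using the in-field
#' reference phantom of known density: the calibration factor is the median
#' phantom-ROI signal divided by the known density, and density = S0 /
#' calibration_factor. Any global scanner gain cancels in the ratio. The
#' median (rather than mean) makes the calibration robust to edge voxels of
#' the ROI.
#'
#' @param s0 TE = 0 signal map, or the list returned by [extrapolate_s0()].
#' @param phantom_roi logical matrix marking the reference phantom.
#' @param phantom_known_density its known water density (mL H2O/cm^3).
#' @return object of class `density_map` with `density`, `t2star` (when the
#'   input carried it) and `calibration_factor`.
#' @export
calibrate_density <- function(s0, phantom_roi, phantom_known_density = 1.0) {
  t2star <- NULL
  if (is.list(s0)) { t2star <- s0$t2star; s0 <- s0$s0 }
  stopifnot(identical(dim(s0), dim(phantom_roi)))
  if (phantom_known_density <= 0) stop("phantom density must be positive")
  ref <- s0[phantom_roi]
  ref <- ref[is.finite(ref) & ref > 0]
  if (length(ref) < 10)
    stop("phantom ROI must contain at least 10 voxels with positive signal")
  cal <- stats::median(ref) / phantom_known_density
  structure(list(density = s0 / cal, t2star = t2star,
                 calibration_factor = cal),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- x$density[is.finite(x$density)]
  cat(sprintf("Density map: %d voxels, median %.3f mL H2O/cm^3 (calibration %.4g)\n",
              length(d), stats::median(d), x$calibration_factor))
  invisible(x)
}

#' Estimate the surface-coil sensitivity field
#'
#' The torso (surface) coil signal divided by the body-coil signal isolates
#' the receive sensitivity, since the underlying proton density cancels.
#' Receive fields vary smoothly over a 40 cm field of view, so the default
#' regularisation fits a low-order 2D polynomial surface to the ratio over
#' the support (the classical bias-field model; unbiased at the support
#' edges and exact for polynomial fields). `method = "gaussian"` instead
#' blurs the ratio at `smoothing_scale` voxels within the support; it tracks
#' higher-order structure but is biased where the support is one-sided.
#' Either way the field is normalised to median 1 over the support, fixing
#' the arbitrary relative gain of the two coils.
#'
#' @param torso_s0,body_s0 TE = 0 signal maps from the two coils.
#' @param smoothing_scale Gaussian smoothing SD in voxels (for
#'   `method = "gaussian"`).
#' @param support logical matrix of voxels with reliable signal (lung plus
#'   reference phantom); at least 50 voxels.
#' @param method `"polynomial"` (default) or `"gaussian"`.
#' @param order polynomial surface order (default 2).
#' @return object of class `coil_field` with the `sensitivity` matrix
#'   (defined everywhere for the polynomial fit, NA outside the support for
#'   the Gaussian), `method` and `smoothing_scale`.
#' @export
estimate_coil_field <- function(torso_s0, body_s0, smoothing_scale = 5,
                                support, method = c("polynomial", "gaussian"),
                                order = 2) {
  method <- match.arg(method)
  stopifnot(identical(dim(torso_s0), dim(body_s0)),
            identical(dim(torso_s0), dim(support)))
  support <- support & is.finite(torso_s0) & is.finite(body_s0) & body_s0 > 0
  if (sum(support) < 50)
    stop("coil-field support too small (< 50 usable voxels)")
  ratio <- matrix(NA_real_, nrow(torso_s0), ncol(torso_s0))
  ratio[support] <- torso_s0[support] / body_s0[support]
  if (method == "polynomial") {
    nr <- nrow(ratio); nc <- ncol(ratio)
    xs <- (matrix(seq_len(nr), nr, nc) - 1) / (nr - 1)
    ys <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 1) / (nc - 1)
    terms <- list()
    for (i in 0:order) for (j in 0:(order - i))
      terms[[length(terms) + 1]] <- xs^i * ys^j
    basis <- vapply(terms, function(t) t[support], numeric(sum(support)))
    beta <- stats::lm.fit(basis, ratio[support])$coefficients
    beta[is.na(beta)] <- 0
    sens <- Reduce(`+`, Map(function(t, b) t * b, terms, beta))
  } else {
    sens <- smooth2d(ratio, smoothing_scale, mask = support)
  }
  sens <- sens / stats::median(sens[support])
  if (any(sens[support] <= 0))
    stop("estimated coil sensitivity is not positive over the support")
  structure(list(sensitivity = sens, method = method,
                 smoothing_scale = smoothing_scale),
            class = "coil_field")
}

#' @export
print.coil_field <- function(x, ...) {
  s <- x$sensitivity[is.finite(x$sensitivity)]
  cat(sprintf("Coil sensitivity field: %d voxels, range %.2f-%.2f (median-1 normalised, smoothing %g vox)\n",
              length(s), min(s), max(s), x$smoothing_scale))
  invisible(x)
}
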