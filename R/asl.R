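# Arterial-spin-labelling perfusion quantification: subtraction, coil
# correction, phantom calibration, large-vessel filtering.

#' Subtract the selective and nonselective ASL images
#'
#' The nonselective acquisition inverts all spins; the selective one spares
#' inflowing blood, so the voxelwise difference reflects blood delivered to
#' the slice during one cardiac cycle. Negative differences (noise) are
#' preserved — zero-clipping would bias the mean perfusion upward — and their
#' count is reported as an attribute for QC.
#'
#' @param selective selective-inversion image, or an `asl_pair` object.
#' @param nonselective nonselective-inversion image (ignored when an
#'   `asl_pair` is given).
#' @return numeric matrix with attribute `n_negative`.
#' @export
subtract_pair <- function(selective, nonselective = NULL) {
  if (inherits(selective, "asl_pair")) {
    nonselective <- selective$nonselective
    selective <- selective$selective
  }
  if (!identical(dim(selective), dim(nonselective)))
    stop("selective and nonselective images must have the same shape")
  diff <- selective - nonselective
  attr(diff, "n_negative") <- sum(diff < 0)
  diff
}

#' Coil-correct and calibrate an ASL subtraction to absolute perfusion
#'
#' Divides the subtraction image by the coil sensitivity, converts signal to
#' millilitres of blood via the in-field reference phantom (whose
#' coil-corrected signal per mL water is known), and scales per-cycle
#' delivery to per-minute perfusion with the heart rate:
#' delivered = (subtraction / coil) / (signal-per-mL x voxel volume),
#' q = delivered x heart rate (mL blood / min / mL lung).
#'
#' @param subtraction output of [subtract_pair()].
#' @param coil_field a [estimate_coil_field()] object, or a sensitivity
#'   matrix; must be positive over the lung.
#' @param reference the nonselective image, from which the phantom-ROI
#'   calibration signal is read.
#' @param phantom_roi logical matrix marking the reference phantom.
#' @param lung_mask logical matrix of lung voxels to quantify.
#' @param phantom_density known phantom water density (mL H2O/cm^3).
#' @param voxel_volume voxel volume in cm^3.
#' @param heart_rate beats per minute.
#' @return object of class `q_map` (unfiltered: `vessel_removed_mask` empty).
#' @export
correct_and_calibrate <- function(subtraction, coil_field, reference,
                                  phantom_roi, lung_mask,
                                  phantom_density = 1.0, voxel_volume,
                                  heart_rate) {
  sens <- if (inherits(coil_field, "coil_field")) coil_field$sensitivity
          else coil_field
  stopifnot(identical(dim(subtraction), dim(sens)),
            identical(dim(subtraction), dim(phantom_roi)),
            identical(dim(subtraction), dim(lung_mask)))
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (any(!is.finite(sens[lung_mask])) || any(sens[lung_mask] <= 0))
    stop("coil field must be positive and finite over the lung")
  ref <- reference[phantom_roi] / sens[phantom_roi]
  ref <- ref[is.finite(ref)]
  if (length(ref) < 1 || stats::median(ref) <= 0)
    stop("nonpositive calibration signal in the phantom ROI")
  signal_per_ml <- stats::median(ref) / (phantom_density * voxel_volume)

  delivered <- matrix(NA_real_, nrow(subtraction), ncol(subtraction))
  delivered[lung_mask] <- (subtraction[lung_mask] / sens[lung_mask]) /
    (signal_per_ml * voxel_volume)
  structure(list(q = delivered * heart_rate, delivered = delivered,
                 lung_mask = lung_mask,
                 vessel_removed_mask = matrix(FALSE, nrow(subtraction),
                                              ncol(subtraction)),
                 heart_rate = heart_rate, threshold_fraction = NA_real_,
                 signal_per_ml = signal_per_ml),
            class = "q_map")
}

#' Remove conduit vessels from a perfusion map
#'
#' Large pulmonary vessels carry blood destined for other regions, so their
#' apparent delivery is not local perfusion. Voxels whose delivered blood
#' volume strictly exceeds `threshold_fraction` (default 0.35) times the
#' maximum delivered value are marked in `vessel_removed_mask` and excluded
#' from subsequent summaries; boundary voxels exactly at the threshold are
#' retained. A uniform map has no outliers by definition: it is left intact
#' with a degeneracy warning rather than emptied.
#'
#' @param qmap an unfiltered `q_map`.
#' @param threshold_fraction fraction of the maximum delivered value, in
#'   (0, 1\].
#' @return the `q_map` with `vessel_removed_mask`, `threshold_fraction` and
#'   `n_removed` set.
#' @export
filter_vessels <- function(qmap, threshold_fraction = 0.35) {
  stopifnot(inherits(qmap, "q_map"))
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]")
  d <- qmap$delivered[qmap$lung_mask]
  if (!any(d > 0, na.rm = TRUE))
    stop("need at least one positive delivered voxel to filter")
  dmax <- max(d, na.rm = TRUE)
  if (diff(range(d, na.rm = TRUE)) < 1e-12 * abs(dmax)) {
    warning("uniform delivered map: no vessel outliers to remove")
    removed <- qmap$lung_mask & FALSE
  } else {
    removed <- qmap$lung_mask & !is.na(qmap$delivered) &
      qmap$delivered > threshold_fraction * dmax
  }
  qmap$vessel_removed_mask <- removed
  qmap$threshold_fraction <- threshold_fraction
  qmap$n_removed <- sum(removed)
  qmap
}

#' Spatial summary of a perfusion map
#'
#' Mean perfusion (mL/min/mL) and relative dispersion (sample SD over mean)
#' across retained lung voxels, i.e. excluding filtered conduit vessels.
#'
#' @param qmap a `q_map` (filtered or unfiltered).
#' @return named vector `c(mean, rd)`.
#' @export
q_summary <- function(qmap) {
  stopifnot(inherits(qmap, "q_map"))
  keep <- qmap$lung_mask & !qmap$vessel_removed_mask
  spatial_summary(qmap$q[keep], "Q")
}

#' @export
print.q_map <- function(x, ...) {
  n_lung <- sum(x$lung_mask)
  cat(sprintf("Perfusion map: %d lung voxels, HR %.0f bpm\n",
              n_lung, x$heart_rate))
  if (!is.na(x$threshold_fraction))
    cat(sprintf("  vessel filter %.0f%% of max delivered: %d voxels removed\n",
                100 * x$threshold_fraction, sum(x$vessel_removed_mask)))
  keep <- x$lung_mask & !x$vessel_removed_mask
  if (sum(keep) >= 2) {
    s <- q_summary(x)
    cat(sprintf("  mean Q %.2f mL/min/mL, relative dispersion %.3f\n",
                s["mean"], s["rd"]))
  }
  invisible(x)
}
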