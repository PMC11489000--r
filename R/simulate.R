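# Forward signal models: oxygen-enhanced washin series, ASL pair, dual-echo
# density pair. All are pure functions of (phantom, parameters, seed).

#' Simulate an oxygen-enhanced specific-ventilation image series
#'
#' Iterates the alveolar gas dilution recursion ([gas_step()]) per voxel over
#' a breath schedule and renders one image per breath at signal level:
#' \deqn{S_n = S_{air} (1 + e \cdot (f_n - 0.21)/0.79)}
#' where e is the maximal fractional signal change between breathing air and
#' 100% O2 (dissolved oxygen shortens T1, raising the signal of an
#' inversion-prepared acquisition). The SV estimator is correlation-based and
#' hence invariant to the per-voxel amplitude, so the exact relaxivity
#' constant is immaterial; only the shape of the washin/washout time course
#' carries information. Background voxels carry noise only; the reference
#' phantom ROI has a constant (O2-insensitive) signal.
#'
#' @param phantom a [make_phantom()] object.
#' @param schedule a [default_schedule()] object (or any `breath_schedule`).
#' @param enhancement maximal fractional enhancement at 100% O2, in (0, 0.5].
#' @param snr mean lung signal divided by the additive Gaussian noise SD;
#'   `Inf` for a noiseless series.
#' @param seed integer seed for the noise stream.
#' @param baseline_signal arbitrary scanner gain for the air-breathing signal.
#' @return object of class `sv_series`: the `series` array (x, y, breath),
#'   plus the schedule, lung mask and simulation parameters.
#' @export
simulate_sv_series <- function(phantom, schedule, enhancement = 0.12,
                               snr = 40, seed = 1L, baseline_signal = 100) {
  stopifnot(inherits(phantom, "lung_phantom"),
            inherits(schedule, "breath_schedule"))
  if (length(schedule$fio2) == 0) stop("breath schedule is empty")
  if (!is.finite(enhancement) || enhancement <= 0 || enhancement > 0.5)
    stop("enhancement must lie in (0, 0.5]")
  if (!(snr > 0)) stop("snr must be positive")

  nb <- length(schedule$fio2)
  shp <- phantom$shape
  s_air <- baseline_signal * phantom$coil_field
  s_air[!phantom$lung_mask] <- 0
  s_air[phantom$phantom_roi] <- baseline_signal *
    phantom$coil_field[phantom$phantom_roi]

  f <- matrix(0.21, shp[1], shp[2])
  series <- array(0, dim = c(shp, nb))
  for (n in seq_len(nb)) {
    f <- gas_step(f, schedule$fio2[n], phantom$sv_true)
    frame <- s_air * (1 + enhancement * (f - 0.21) / 0.79)
    frame[phantom$phantom_roi] <- s_air[phantom$phantom_roi]  # O2-insensitive
    series[, , n] <- frame
  }
  if (is.finite(snr)) {
    sd_noise <- mean(s_air[phantom$lung_mask]) / snr
    series <- local_seed(seed,
      series + array(stats::rnorm(length(series), sd = sd_noise), dim(series)))
  }
  structure(list(series = series, schedule = schedule,
                 lung_mask = phantom$lung_mask, enhancement = enhancement,
                 snr = snr, seed = as.integer(seed)),
            class = "sv_series")
}

#' Simulate a selective/nonselective arterial spin labelling pair
#'
#' The nonselective image is the static tissue signal (water density times
#' voxel volume, scaled by the coil sensitivity). The selective image adds
#' the signal of blood delivered to the slice during one cardiac cycle,
#' q / HR mL blood per mL lung, so that the noiseless subtraction image is
#' proportional to per-voxel delivered blood volume scaled by the coil field.
#' The inversion delay TI is 80% of one R-R interval.
#'
#' @param phantom a [make_phantom()] object.
#' @param snr signal-to-noise ratio of the perfusion-weighted signal: mean
#'   lung subtraction signal over the per-image noise SD; `Inf` disables
#'   noise.
#' @param seed integer seed.
#' @param signal_per_ml scanner gain in signal units per mL water.
#' @return object of class `asl_pair` with `selective`, `nonselective`,
#'   `ti` (ms), `heart_rate` and the simulation parameters.
#' @export
simulate_asl_pair <- function(phantom, snr = 30, seed = 1L,
                              signal_per_ml = 1000) {
  stopifnot(inherits(phantom, "lung_phantom"))
  if (phantom$heart_rate <= 0) stop("heart_rate must be positive")
  if (!(snr > 0)) stop("snr must be positive")
  water_ml <- phantom$density_true * phantom$voxel_volume
  nonsel <- signal_per_ml * phantom$coil_field * water_ml
  delivered <- phantom$q_true / phantom$heart_rate        # mL blood / mL lung / cycle
  sel <- nonsel + signal_per_ml * phantom$coil_field *
    delivered * phantom$voxel_volume
  if (is.finite(snr)) {
    sd_noise <- mean((sel - nonsel)[phantom$lung_mask]) / snr
    noise <- local_seed(seed, stats::rnorm(2 * length(nonsel), sd = sd_noise))
    sel <- sel + matrix(noise[seq_along(nonsel)], nrow(nonsel))
    nonsel <- nonsel + matrix(noise[-seq_along(nonsel)], nrow(nonsel))
  }
  structure(list(selective = sel, nonselective = nonsel,
                 ti = 0.8 * 60000 / phantom$heart_rate,
                 heart_rate = phantom$heart_rate, snr = snr,
                 seed = as.integer(seed)),
            class = "asl_pair")
}

#' Simulate a dual-echo proton-density acquisition
#'
#' Signal at echo time TE decays monoexponentially with the effective
#' transverse relaxation time: S(TE) = A * density * coil * exp(-TE/T2*).
#' The body coil has unit (flat) sensitivity; the torso coil applies the
#' phantom's smooth surface-coil field. Echo times default to the short-TE
#' FLASH pair used for lung density mapping (0.82 and 1.8 ms).
#'
#' @param phantom a [make_phantom()] object.
#' @param te1,te2 echo times in ms, 0 < te1 < te2.
#' @param t2star_map per-voxel T2* in ms (defaults to the phantom's truth).
#' @param snr mean lung first-echo signal over noise SD; `Inf` disables noise.
#' @param seed integer seed.
#' @param coil `"body"` (unit sensitivity) or `"torso"` (coil field applied).
#' @param signal_per_ml scanner gain.
#' @return object of class `dual_echo` with `echo1`, `echo2`, `te1`, `te2`,
#'   `coil`.
#' @export
simulate_dual_echo <- function(phantom, te1 = 0.82, te2 = 1.8,
                               t2star_map = phantom$t2star_true,
                               snr = 50, seed = 1L,
                               coil = c("torso", "body"),
                               signal_per_ml = 1000) {
  stopifnot(inherits(phantom, "lung_phantom"))
  coil <- match.arg(coil)
  if (!(te1 > 0) || te2 <= te1) stop("need 0 < te1 < te2")
  if (any(t2star_map <= 0, na.rm = TRUE)) stop("t2star must be positive")
  if (!(snr > 0)) stop("snr must be positive")
  sens <- if (coil == "torso") phantom$coil_field else
    matrix(1, phantom$shape[1], phantom$shape[2])
  a <- signal_per_ml * phantom$density_true * sens
  decay1 <- exp(-te1 / t2star_map); decay1[is.na(decay1)] <- 0
  decay2 <- exp(-te2 / t2star_map); decay2[is.na(decay2)] <- 0
  e1 <- a * decay1
  e2 <- a * decay2
  if (is.finite(snr)) {
    sd_noise <- mean(e1[phantom$lung_mask]) / snr
    noise <- local_seed(seed, stats::rnorm(2 * length(e1), sd = sd_noise))
    e1 <- e1 + matrix(noise[seq_along(e1)], nrow(e1))
    e2 <- e2 + matrix(noise[-seq_along(e1)], nrow(e1))
  }
  structure(list(echo1 = e1, echo2 = e2, te1 = te1, te2 = te2, coil = coil,
                 snr = snr, seed = as.integer(seed)),
            class = "dual_echo")
}

#' Simulate the full per-subject acquisition bundle
#'
#' Convenience wrapper producing everything one imaging session yields: the
#' O2-enhanced series, the ASL pair, and dual-echo pairs with both the body
#' and the torso coil. Sub-simulators receive distinct seeds derived from
#' `seed`.
#'
#' @inheritParams simulate_sv_series
#' @param snr_sv,snr_asl,snr_echo per-acquisition signal-to-noise ratios.
#' @return list of class `acquisition_bundle`.
#' @export
simulate_acquisitions <- function(phantom, schedule = default_schedule(),
                                  enhancement = 0.12, snr_sv = 40,
                                  snr_asl = 30, snr_echo = 50, seed = 1L) {
  structure(list(
    sv_series = simulate_sv_series(phantom, schedule, enhancement,
                                   snr = snr_sv, seed = derive_seed(seed, 1)),
    asl = simulate_asl_pair(phantom, snr = snr_asl,
                            seed = derive_seed(seed, 2)),
    echo_body = simulate_dual_echo(phantom, snr = snr_echo,
                                   seed = derive_seed(seed, 3), coil = "body"),
    echo_torso = simulate_dual_echo(phantom, snr = snr_echo,
                                    seed = derive_seed(seed, 4), coil = "torso"),
    seed = as.integer(seed)
  ), class = "acquisition_bundle")
}
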