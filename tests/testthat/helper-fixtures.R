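# Shared fixtures, built once per test run. All phantoms are small and
# noiseless unless a test needs otherwise.

fix <- new.env()

fixture_phantom <- function() {
  if (is.null(fix$phantom)) fix$phantom <- make_phantom(seed = 5)
  fix$phantom
}

# phantom whose ground-truth SV values lie exactly on the estimation grid
fixture_ongrid_phantom <- function() {
  if (is.null(fix$ongrid))
    fix$ongrid <- make_phantom(seed = 3, sv_grid = default_sv_grid())
  fix$ongrid
}

fixture_schedule <- function() {
  if (is.null(fix$schedule)) fix$schedule <- default_schedule()
  fix$schedule
}

fixture_noiseless_series <- function() {
  if (is.null(fix$series))
    fix$series <- simulate_sv_series(fixture_ongrid_phantom(),
                                     fixture_schedule(), snr = Inf)
  fix$series
}

# minimal hand-built perfusion map for summary arithmetic
tiny_qmap <- function(q_values) {
  n <- length(q_values)
  structure(list(q = matrix(q_values, 1), delivered = matrix(q_values / 60, 1),
                 lung_mask = matrix(TRUE, 1, n),
                 vessel_removed_mask = matrix(FALSE, 1, n),
                 heart_rate = 60, threshold_fraction = NA_real_),
            class = "q_map")
}
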