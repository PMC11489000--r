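test_that("ASL subtraction is the plain voxelwise difference with QC", {
  ph <- fixture_phantom()
  pair <- simulate_asl_pair(ph, snr = Inf)
  expect_equal(max(abs(subtract_pair(pair$nonselective, pair$nonselective))), 0)
  d <- subtract_pair(pair)
  # noiseless difference proportional to delivered blood times the coil field
  expected <- ph$q_true / ph$heart_rate * ph$coil_field
  lung <- ph$lung_mask
  ratio <- d[lung] / expected[lung]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  expect_error(subtract_pair(pair$selective, pair$selective[1:10, 1:10]),
               "same shape")
  # background subtraction averages to ~0 within its standard error
  noisy <- simulate_asl_pair(ph, snr = 10, seed = 2)
  dn <- subtract_pair(noisy)
  bg <- !ph$lung_mask & !ph$phantom_roi
  se <- sd(dn[bg]) / sqrt(sum(bg))
  expect_lt(abs(mean(dn[bg])), 4 * se)
  expect_gt(attr(dn, "n_negative"), 0)             # negatives preserved
})

test_that("coil correction and phantom calibration close the loop exactly", {
  ph <- fixture_phantom()
  pair <- simulate_asl_pair(ph, snr = Inf)
  qm <- correct_and_calibrate(subtract_pair(pair), ph$coil_field,
                              reference = pair$nonselective,
                              phantom_roi = ph$phantom_roi,
                              lung_mask = ph$lung_mask,
                              phantom_density = ph$phantom_density,
                              voxel_volume = ph$voxel_volume,
                              heart_rate = ph$heart_rate)
  lung <- ph$lung_mask
  expect_equal(qm$q[lung], ph$q_true[lung], tolerance = 1e-6)
  expect_equal(qm$q[lung], qm$delivered[lung] * ph$heart_rate, tolerance = 1e-12)
  # doubling the coil gain everywhere (signals included) leaves q unchanged
  ph2 <- ph
  ph2$coil_field <- 2 * ph$coil_field
  pair2 <- simulate_asl_pair(ph2, snr = Inf)
  qm2 <- correct_and_calibrate(subtract_pair(pair2), ph2$coil_field,
                               pair2$nonselective, ph$phantom_roi,
                               ph$lung_mask, ph$phantom_density,
                               ph$voxel_volume, ph$heart_rate)
  expect_equal(qm2$q[lung], qm$q[lung], tolerance = 1e-12)
  # same delivered volume per cycle at twice the heart rate doubles q
  qm3 <- correct_and_calibrate(subtract_pair(pair), ph$coil_field,
                               pair$nonselective, ph$phantom_roi,
                               ph$lung_mask, ph$phantom_density,
                               ph$voxel_volume, 2 * ph$heart_rate)
  expect_equal(qm3$q[lung], 2 * qm$q[lung], tolerance = 1e-12)
  # nonpositive calibration signal is an error
  broken <- pair$nonselective
  broken[ph$phantom_roi] <- -1
  expect_error(correct_and_calibrate(subtract_pair(pair), ph$coil_field,
                                     broken, ph$phantom_roi, ph$lung_mask,
                                     ph$phantom_density, ph$voxel_volume,
                                     ph$heart_rate),
               "calibration signal")
})

make_filtered_qmap <- function(seed = 9, rd = 0.15, threshold = 0.35) {
  ph <- make_phantom(seed = seed, q_params = list(mean = 1.4, rd = rd))
  pair <- simulate_asl_pair(ph, snr = Inf)
  qm <- correct_and_calibrate(subtract_pair(pair), ph$coil_field,
                              pair$nonselective, ph$phantom_roi, ph$lung_mask,
                              ph$phantom_density, ph$voxel_volume,
                              ph$heart_rate)
  list(phantom = ph, qmap = filter_vessels(qm, threshold))
}

test_that("the 35% filter removes exactly the constructed vessel voxels", {
  r <- make_filtered_qmap()
  expect_identical(r$qmap$vessel_removed_mask, r$phantom$vessel_mask)
  expect_gt(r$qmap$n_removed, 0)
  # retained-voxel bound: nothing retained above the threshold fraction
  keep <- r$qmap$lung_mask & !r$qmap$vessel_removed_mask
  dmax <- max(r$qmap$delivered[r$qmap$lung_mask])
  expect_lte(max(r$qmap$delivered[keep]), 0.35 * dmax + 1e-12)
  # conservation of total delivered signal across filtering
  total <- sum(r$qmap$delivered[r$qmap$lung_mask])
  expect_equal(sum(r$qmap$delivered[keep]) +
                 sum(r$qmap$delivered[r$qmap$vessel_removed_mask]),
               total, tolerance = 1e-12)
})

test_that("vessel filtering is monotone in the threshold and guards edge cases", {
  r <- make_filtered_qmap()
  qm <- r$qmap
  thresholds <- c(0.9, 0.6, 0.35, 0.2, 0.1)
  removed <- vapply(thresholds,
                    function(tf) filter_vessels(qm, tf)$n_removed, numeric(1))
  expect_true(all(diff(removed) >= 0))
  expect_identical(filter_vessels(qm, 1.0)$n_removed, 0L)
  expect_error(filter_vessels(qm, 0), "threshold_fraction")
  expect_error(filter_vessels(qm, 1.2), "threshold_fraction")
  uniform <- qm
  uniform$delivered[uniform$lung_mask] <- 0.02
  uniform$q[uniform$lung_mask] <- 0.02 * uniform$heart_rate
  expect_warning(fu <- filter_vessels(uniform, 0.35), "uniform")
  expect_identical(fu$n_removed, 0L)
})

test_that("perfusion summaries use retained voxels and the sample-SD RD", {
  qm <- tiny_qmap(c(1, 3))
  s <- q_summary(qm)
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["rd"]), sd(c(1, 3)) / 2, tolerance = 1e-12)
  expect_equal(unname(q_summary(tiny_qmap(rep(1.4, 5)))["rd"]), 0)
  r <- make_filtered_qmap()
  keep <- r$qmap$lung_mask & !r$qmap$vessel_removed_mask
  expect_equal(unname(q_summary(r$qmap)["mean"]), mean(r$qmap$q[keep]))
  one <- tiny_qmap(2)
  expect_error(q_summary(one), "at least 2")
})
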