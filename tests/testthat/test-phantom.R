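test_that("phantom construction hits the requested SV mean and its invariants", {
  ph <- make_phantom(shape = c(64, 64), sv_params = list(mean = 0.20, rd = 0.35),
                     seed = 7)
  m <- mean(ph$sv_true[ph$lung_mask])
  expect_gte(m, 0.18)
  expect_lte(m, 0.22)
  # invariants
  expect_true(all(ph$sv_true[ph$lung_mask] >= 0))
  expect_true(all(ph$sv_true[!ph$lung_mask] == 0))
  expect_true(all(ph$q_true >= 0))
  expect_true(all(ph$lung_mask[ph$vessel_mask]))          # vessels inside lung
  expect_false(any(ph$phantom_roi & ph$lung_mask))        # ROI outside lung
  expect_true(all(ph$coil_field > 0))
  inside <- ph$lung_mask | ph$phantom_roi
  expect_true(all(ph$density_true[inside] > 0 & ph$density_true[inside] <= 1.1))
  # vessels must stand clear of the parenchyma for the 35% filter
  parench_med <- median(ph$q_true[ph$lung_mask & !ph$vessel_mask])
  expect_true(all(ph$q_true[ph$vessel_mask] > 3 * parench_med))
})

test_that("identical seed and parameters give a bit-identical phantom", {
  expect_identical(make_phantom(seed = 7), make_phantom(seed = 7))
  expect_false(identical(make_phantom(seed = 7), make_phantom(seed = 8)))
})

test_that("degenerate phantom requests fail loudly", {
  expect_error(make_phantom(sv_params = list(mean = -0.1, rd = 0.3)),
               "positive means")
  expect_error(make_phantom(shape = c(16, 16)), "32")
})

test_that("the default breath schedule is the 140-breath alternating protocol", {
  sch <- default_schedule(breath_rate = 12)
  expect_length(sch$fio2, 140)
  expect_true(all(sch$fio2[1:20] == 0.21))       # air first
  expect_true(all(sch$fio2[21:60] == 1.00))      # extended first O2 cycle
  expect_identical(sum(sch$fio2 == 1.00), 80L)   # 40 + 20 + 20
  expect_true(all(sch$fio2 %in% c(0.21, 1.00)))
  expect_error(default_schedule(breath_rate = 25), "breath_rate")
})

test_that("the gas dilution step has its fixed point, bounds and hand value", {
  expect_equal(gas_step(0.21, 1.0, 0), 0.21)
  expect_equal(gas_step(0.21, 0.21, 0.5), 0.21)
  expect_equal(gas_step(0.21, 1.0, 0.2), 0.3416667, tolerance = 1e-6)
  expect_error(gas_step(0.21, 1.0, -0.1), "non-negative")
  # result always between resident and inspired fraction
  set.seed(42)
  for (i in 1:50) {
    fp <- runif(1); fi <- runif(1); sv <- rexp(1)
    r <- gas_step(fp, fi, sv)
    expect_gte(r, min(fp, fi) - 1e-12)
    expect_lte(r, max(fp, fi) + 1e-12)
  }
})

test_that("simulated washin signal is flat at sv = 0 and tracks FiO2 at huge sv", {
  ph <- fixture_phantom()
  sch <- fixture_schedule()
  ser <- fixture_noiseless_series()
  bg <- which(!fixture_ongrid_phantom()$lung_mask &
                !fixture_ongrid_phantom()$phantom_roi, arr.ind = TRUE)[1, ]
  expect_equal(sd(ser$series[bg[1], bg[2], ]), 0)
  # sv -> infinity analogue: signal proportional to FiO2 with <= 1 breath lag
  f <- 0.21
  trace <- numeric(140)
  for (n in 1:140) { f <- gas_step(f, sch$fio2[n], 1e3); trace[n] <- f }
  expect_true(all(abs(trace - sch$fio2) < 1e-3))
})

test_that("fraction of washin plateau follows the closed-form geometric decay", {
  # one voxel, sv = 0.2, 20 air breaths then 40 O2 breaths
  sv <- 0.2
  f <- 0.21
  for (n in 1:20) f <- gas_step(f, 0.21, sv)
  for (n in 1:40) f <- gas_step(f, 1.00, sv)
  frac <- (f - 0.21) / 0.79
  expect_equal(frac, 1 - (1 / 1.2)^40, tolerance = 1e-12)
})

test_that("time to equilibrium decreases monotonically with sv (noiseless)", {
  svs <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  target <- 1 - exp(-1)
  n63 <- vapply(svs, function(sv) {
    f <- 0.21
    frac <- 0
    k <- 0
    while (frac < target) {
      prev <- frac
      f <- gas_step(f, 1, sv)
      frac <- (f - 0.21) / 0.79
      k <- k + 1
    }
    k - 1 + (target - prev) / (frac - prev)   # interpolated crossing breath
  }, numeric(1))
  expect_true(all(diff(n63) < 0))
})

test_that("ASL forward model scales with delivery per cardiac cycle", {
  ph <- fixture_phantom()
  ph0 <- ph
  ph0$q_true[] <- 0
  pair0 <- simulate_asl_pair(ph0, snr = Inf)
  expect_equal(max(abs(pair0$selective - pair0$nonselective)), 0)
  # doubling heart rate halves per-cycle delivery, hence the subtraction
  ph2 <- ph
  ph2$heart_rate <- 2 * ph$heart_rate
  s1 <- subtract_pair(simulate_asl_pair(ph, snr = Inf))
  s2 <- subtract_pair(simulate_asl_pair(ph2, snr = Inf))
  expect_equal(as.numeric(s2), as.numeric(s1) / 2, tolerance = 1e-12)
  # TI equals 80% of the R-R interval
  pair <- simulate_asl_pair(ph, snr = Inf)
  expect_equal(pair$ti, 0.8 * 60000 / ph$heart_rate, tolerance = 1)
})

test_that("dual-echo signals decay monoexponentially and vanish without water", {
  ph <- fixture_phantom()
  de <- simulate_dual_echo(ph, snr = Inf, coil = "body")
  inside <- ph$lung_mask
  ratio <- de$echo1[inside] / de$echo2[inside]
  expect_equal(ratio, exp((de$te2 - de$te1) / ph$t2star_true[inside]),
               tolerance = 1e-12)
  # T2* -> infinity analogue: echoes coincide
  long <- simulate_dual_echo(ph, t2star_map = matrix(1e6, 64, 64),
                             snr = Inf, coil = "body")
  expect_equal(long$echo1[inside], long$echo2[inside], tolerance = 1e-4)
  # zero-density voxels give zero signal at both echoes
  bg <- !ph$lung_mask & !ph$phantom_roi
  expect_true(all(de$echo1[bg] == 0) && all(de$echo2[bg] == 0))
  expect_error(simulate_dual_echo(ph, te1 = 2, te2 = 1), "te1 < te2")
})

test_that("simulators are pure functions of phantom, parameters and seed", {
  ph <- fixture_phantom()
  sch <- fixture_schedule()
  expect_identical(simulate_sv_series(ph, sch, snr = 20, seed = 11),
                   simulate_sv_series(ph, sch, snr = 20, seed = 11))
  expect_identical(simulate_asl_pair(ph, snr = 10, seed = 4),
                   simulate_asl_pair(ph, snr = 10, seed = 4))
  expect_identical(simulate_dual_echo(ph, snr = 10, seed = 4),
                   simulate_dual_echo(ph, snr = 10, seed = 4))
  expect_error(simulate_sv_series(ph, structure(list(fio2 = numeric(0),
                                                     breath_rate = 12),
                                                class = "breath_schedule")),
               "empty")
})
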