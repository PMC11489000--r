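test_that("paired comparison matches the textbook t statistic", {
  r <- paired_comparison(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand example: differences {1,2,3} -> t = 2 / (1/sqrt(3)) on 2 df
  r2 <- paired_comparison(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r2$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(r2$estimate, 2)
  # zero-variance nonzero differences are degenerate, flagged
  r3 <- paired_comparison(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_lt(r3$p_value, 1e-300)
  expect_match(r3$note, "zero-variance")
  expect_error(paired_comparison(1:4, 1:3), "equal length")
  expect_error(paired_comparison(1:2, 3:4), "at least 3")
})

test_that("a modest paired effect is detected with the expected power", {
  # true post increase +3 bpm, SD 4, n = 14: expected power about 0.72
  set.seed(2024)
  hits <- 0L
  for (i in 1:500) {
    pre <- rnorm(14, 68, 10)
    post <- pre + rnorm(14, 3, 4)
    if (paired_comparison(pre, post)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.70)
})

test_that("Levene's test gates the independent comparison path", {
  r <- independent_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  # 10x variance ratio routes to the unequal-variance path
  set.seed(11)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 0, sqrt(10))
  r2 <- independent_comparison(a, b)
  expect_identical(r2$method, "welch-t")
  expect_lt(r2$levene_p, 0.05)
  # homoscedastic groups use the pooled path and match the closed form
  a2 <- c(1, 2, 3, 4)
  b2 <- c(2, 3, 4, 5)
  r3 <- independent_comparison(a2, b2)
  expect_identical(r3$method, "independent-t")
  sp <- sqrt((3 * var(a2) + 3 * var(b2)) / 6)
  expect_equal(r3$statistic, (mean(a2) - mean(b2)) / (sp * sqrt(1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_error(independent_comparison(1, c(1, 2)), "at least 2")
})

test_that("the correlation screen handles monotone, missing and constant data", {
  df <- data.frame(x = 1:10, y = (1:10)^2, z = -(1:10) + rnorm(10, 0, 0.01),
                   w = rep(1, 10), v = c(1:8, NA, NA))
  set.seed(1)
  out <- correlation_screen(df, list(c("x", "y"), c("x", "z"), c("x", "w"),
                                     c("x", "v")))
  expect_equal(out$estimate[1], 1)                     # monotone -> rho = 1
  expect_lt(out$estimate[2], -0.99)
  expect_match(out$flag[3], "constant")
  expect_identical(out$n[4], 8L)                       # pairwise deletion
  pear <- correlation_screen(df, list(c("x", "z")), method = "pearson")
  expect_identical(pear$method, "pearson")
  expect_error(correlation_screen(df, list(c("x", "nope"))), "unknown column")
})

test_that("noncentral-t sample size matches the power.t.test oracle", {
  r <- required_sample_size(0.5, 0.05, 0.80)
  oracle <- power.t.test(delta = 0.5, sd = 1, sig.level = 0.05, power = 0.80)
  expect_identical(r$n_per_group, as.integer(ceiling(oracle$n)))
  expect_identical(r$n_per_group, 64L)
  # the achieved power brackets the target at n and fails at n - 1
  expect_gte(r$power_achieved, 0.80)
  expect_lt(power.t.test(n = r$n_per_group - 1, delta = 0.5,
                         sig.level = 0.05)$power, 0.80)
  # monotone in effect size and in target power
  ns_d <- vapply(c(0.2, 0.4, 0.6, 0.8),
                 function(d) required_sample_size(d)$n_per_group, integer(1))
  expect_true(all(diff(ns_d) < 0))
  ns_p <- vapply(c(0.5, 0.7, 0.9, 0.95),
                 function(p) required_sample_size(0.5, power = p)$n_per_group,
                 integer(1))
  expect_true(all(diff(ns_p) > 0))
  # power barely above alpha needs only the minimal group
  expect_identical(required_sample_size(0.5, 0.05, 0.055)$n_per_group, 2L)
  expect_error(required_sample_size(0), "infinite")
  expect_error(required_sample_size(0.5, power = 1.2), "power")
})

test_that("group summary tables mirror the three-column comparison layout", {
  cfg <- default_cohort_config()
  tab <- simulate_cohort(cfg, seed = 4)
  rep <- build_summary_tables(tab)
  # truth tables carry no LCI column; the remaining five metrics are reported
  expect_identical(rep$metric,
                   c("mean_sv", "rd_sv", "mean_q", "rd_q", "heart_rate"))
  # mean (SD) strings round-trip to the computed values at print precision
  parsed <- regmatches(rep$pre[1], regexec("([0-9.]+) \\(([0-9.]+)\\)", rep$pre[1]))[[1]]
  expect_equal(as.numeric(parsed[2]), round(rep$pre_mean[1], 2))
  expect_equal(as.numeric(parsed[3]), round(rep$pre_sd[1], 2))
  # optional BH-adjusted columns are appended when requested
  rep2 <- build_summary_tables(tab, adjust = TRUE)
  expect_true("p_pre_vs_post_bh" %in% names(rep2))
  expect_true(all(rep2$p_pre_vs_post_bh >= rep2$p_pre_vs_post - 1e-12,
                  na.rm = TRUE))
})

test_that("a cohort with no true effects shows no systematic significance", {
  cfg <- default_cohort_config()
  cfg$population$sv_mean_vaper <- cfg$population$sv_mean_control
  cfg$population$sv_sd_vaper <- cfg$population$sv_sd_control
  cfg$effects$hr_post_delta <- 0
  cfg$effects$sv_post_delta <- 0
  cfg$effects$bmi_q_slope <- 0
  set.seed(5)
  p_all <- c()
  for (i in 1:10) {
    tab <- simulate_cohort(cfg, seed = 1000 + i)
    rep <- build_summary_tables(tab, metrics = c("mean_sv", "mean_q",
                                                 "heart_rate"))
    p_all <- c(p_all, rep$p_control_vs_pre, rep$p_pre_vs_post)
  }
  expect_lt(mean(p_all < 0.05), 0.15)
})
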