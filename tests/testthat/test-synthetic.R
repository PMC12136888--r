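test_that("identical seeds reproduce every generator byte-for-byte", {
  a <- simulate_thermogram(fp_ld_first, fp_ld_second, seed = 11)
  b <- simulate_thermogram(fp_ld_first, fp_ld_second, seed = 11)
  expect_identical(a, b)

  comps <- mp_three_components()
  expect_identical(simulate_mp_events(comps, 500, 0.3, seed = 11),
                   simulate_mp_events(comps, 500, 0.3, seed = 11))

  sp <- data.frame(s_S = c(54.6, 91.3), fraction = c(0.4, 0.6),
                   ratio_260_230 = c(0.58, 0.47))
  expect_identical(simulate_auc_peaks(sp, jitter = 1, seed = 11),
                   simulate_auc_peaks(sp, jitter = 1, seed = 11))

  peps <- data.frame(start = 1, end = 10,
                     plateau_control = 5, rate_control = 0.01,
                     plateau_heated = 6, rate_heated = 0.01)
  expect_identical(simulate_hdx(peps, seed = 11),
                   simulate_hdx(peps, seed = 11))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(3)
  set.seed(99)
  invisible(simulate_thermogram(fp_ld_first, NULL, seed = 5))
  invisible(simulate_mp_events(mp_three_components(), 100, 0.1, seed = 5))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("noiseless thermogram equals the closed-form model on the grid", {
  grid <- seq(30, 100, by = 0.5)
  tg <- simulate_thermogram(fp_ld_first, fp_ld_second, grid = grid,
                            noise_sd = 0, baseline = c(0.001, 0.85))
  gt <- attr(tg, "ground_truth")
  expected <- 0.001 * grid + 0.85 +
    gt$first$amp * fraction_unfolded(gt$first$dH, gt$first$dS, grid + 273.15) +
    gt$second$amp * fraction_unfolded(gt$second$dH, gt$second$dS, grid + 273.15)
  expect_equal(tg$signal, expected, tolerance = 1e-12)
})

test_that("noiseless single-transition signal crosses the baseline midpoint at Tm", {
  tg <- simulate_thermogram(list(Tm_C = 62, dH = 1.46e5, amp = 0.03), NULL,
                            grid = seq(30, 95, by = 0.001), noise_sd = 0,
                            baseline = c(0.001, 0.85))
  at_tm <- tg$signal[which.min(abs(tg$temperature_C - 62))]
  # folded level + half the amplitude: fU(Tm) = 1/2
  expect_equal(at_tm, 0.001 * 62 + 0.85 + 0.03 / 2, tolerance = 1e-6)
})

test_that("thermogram without transitions is a pure linear baseline", {
  grid <- seq(30, 100, by = 0.1)
  tg <- simulate_thermogram(NULL, NULL, grid = grid, noise_sd = 0,
                            baseline = c(0.002, 0.8))
  expect_equal(tg$signal, 0.002 * grid + 0.8, tolerance = 1e-14)
})

test_that("overlapping transitions are rejected as unfittable", {
  expect_error(
    simulate_thermogram(list(Tm_C = 62, dH = 1e5),
                        list(Tm_C = 63.5, dH = 1e5)),
    "cannot be resolved")
})

test_that("mp generator honours mixture moments and the unbinding sign rule", {
  one <- data.frame(label = "FP", mean = 4.51e6, sd = 0.15e6, weight = 1)
  ev <- simulate_mp_events(one, 4000, unbinding_prob = 0, seed = 3)
  expect_true(all(ev$mass_Da > 0))
  se <- 0.15e6 / sqrt(4000)
  expect_lt(abs(mean(ev$mass_Da) - 4.51e6), 3 * se)

  ev2 <- simulate_mp_events(one, 5000, unbinding_prob = 0.426, seed = 3)
  p_hat <- mean(ev2$mass_Da < 0)
  expect_lt(abs(p_hat - 0.426), 3 * sqrt(0.426 * 0.574 / 5000))
  expect_identical(ev2$unbinding, ev2$mass_Da < 0)
})

test_that("mp generator validates its inputs", {
  one <- data.frame(mean = 4e6, sd = 1e5, weight = 1)
  expect_error(simulate_mp_events(one, 0, 0), "n_events")
  expect_error(simulate_mp_events(one, 10, 1.2), "unbinding_prob")
  bad <- data.frame(mean = c(1, 2), sd = c(1, 1), weight = c(0.5, 0.6))
  expect_error(simulate_mp_events(bad, 10, 0), "sum to 1")
})

test_that("noise-component draws stay inside the |mass| < 2 MDa artifact window", {
  comps <- data.frame(label = c("noise", "FP"),
                      mean = c(0, 4.51e6), sd = c(1.5e6, 0.12e6),
                      weight = c(0.5, 0.5))
  ev <- simulate_mp_events(comps, 3000, unbinding_prob = 0.3, seed = 8)
  expect_true(all(abs(ev$mass_Da[ev$component == "noise"]) < 2e6))
})

test_that("auc peak generator passes species through exactly at zero jitter", {
  sp <- data.frame(s_S = 91.3, fraction = 1.0, ratio_260_230 = 0.47)
  pk <- simulate_auc_peaks(sp, jitter = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$s_S, 91.3)
  expect_equal(pk$area_260 / pk$area_230, 0.47)

  empty <- simulate_auc_peaks(data.frame())
  expect_equal(nrow(empty), 0L)
})

test_that("hdx generator follows the saturation curve and validates inputs", {
  peps <- data.frame(start = 1, end = 12,
                     plateau_control = 4, rate_control = 0.02,
                     plateau_heated = 5, rate_heated = 0.02)
  tab <- simulate_hdx(peps, noise_sd = 0, n_replicates = 1, seed = 1)
  t600 <- tab[tab$time_s == 600 & tab$state == "heated", "uptake_Da"]
  expect_equal(t600, 5 * (1 - exp(-0.02 * 600)), tolerance = 1e-12)

  bad <- peps; bad$plateau_heated <- -1
  expect_error(simulate_hdx(bad), "non-negative")
})
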