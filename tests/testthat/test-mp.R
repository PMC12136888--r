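test_that("calibration line passes through two standards and matches OLS", {
  two <- data.frame(name = c("a", "b"), mass_Da = c(66e3, 660e3),
                    contrast = c(0.003, 0.03))
  cal <- fit_mass_calibration(two)
  expect_equal(apply_calibration(cal, two$contrast), two$mass_Da)

  # noisy collinear standards: residuals equal the closed-form OLS oracle
  set.seed(5)
  st <- data.frame(name = c("bsa", "apf", "tg"),
                   contrast = c(0.003, 0.02, 0.03))
  st$mass_Da <- 2.2e7 * st$contrast + 1e3 + rnorm(3, 0, 5e3)
  cal <- fit_mass_calibration(st)
  X <- cbind(1, st$contrast)
  beta <- solve(t(X) %*% X, t(X) %*% st$mass_Da)
  expect_equal(cal$intercept, beta[1], tolerance = 1e-8)
  expect_equal(cal$slope, beta[2], tolerance = 1e-8)
  expect_equal(cal$residuals, as.vector(st$mass_Da - X %*% beta),
               tolerance = 1e-8)

  expect_error(fit_mass_calibration(two[1, ]), "at least 2")
  dup <- two; dup$contrast <- c(0.01, 0.01)
  expect_error(fit_mass_calibration(dup), "duplicate")
})

test_that("histogram bins are half-open and conserve in-range counts", {
  ev <- c(2.5e6, 2.5e6, rep(3.123e6, 10), 7.5e6, -1e6)
  h <- build_histogram(ev, bin_width = 5e4, mass_range = c(2e6, 7e6))
  expect_equal(sum(h$count), 12)            # out-of-range events dropped
  expect_equal(h$count[h$mid == 3.125e6], 10)
  # event exactly on an edge goes to the upper bin
  h2 <- build_histogram(2.05e6, bin_width = 5e4, mass_range = c(2e6, 7e6))
  expect_equal(h2$count[h2$mid == 2.075e6], 1)
  expect_equal(sum(h2$count), 1)
  expect_error(build_histogram(ev, bin_width = 5e4, mass_range = c(3e6, 3e6)),
               "empty")
})

test_that("three-species mixtures are recovered within 2% means and 0.03 weights", {
  comps <- mp_three_components()
  worst_mean <- 0; worst_w <- 0
  for (s in 1:20) {
    ev <- simulate_mp_events(comps, 5000, unbinding_prob = 0, seed = s)
    h <- build_histogram(ev)
    mix <- fit_species_mixture(h, comps[c("label", "mean")])
    expect_true(mix$converged)
    expect_true(all(mix$components$area >= 0))
    # areas conserve total histogram counts within 5%
    expect_lt(abs(sum(mix$components$area) - sum(h$count)) / sum(h$count),
              0.05)
    merr <- max(abs(mix$components$mean - comps$mean) / comps$mean)
    werr <- max(abs(mix$components$area / sum(mix$components$area) -
                      comps$weight))
    worst_mean <- max(worst_mean, merr)
    worst_w <- max(worst_w, werr)
  }
  expect_lt(worst_mean, 0.02)
  expect_lt(worst_w, 0.03)
})

test_that("single-component fit captures the total count within 1%", {
  one <- data.frame(label = "FP", mean = 4.51e6, sd = 0.12e6, weight = 1)
  ev <- simulate_mp_events(one, 4000, unbinding_prob = 0, seed = 21)
  h <- build_histogram(ev)
  mix <- fit_species_mixture(h, one[c("label", "mean")])
  expect_lt(abs(sum(mix$components$area) - sum(h$count)) / sum(h$count),
            0.01)
})

test_that("duplicate components trigger a merge warning", {
  one <- data.frame(label = "FP", mean = 4.51e6, sd = 0.12e6, weight = 1)
  ev <- simulate_mp_events(one, 3000, unbinding_prob = 0, seed = 22)
  h <- build_histogram(ev)
  specs <- data.frame(label = c("FP", "FP2"), mean = c(4.51e6, 4.52e6))
  expect_warning(fit_species_mixture(h, specs), "collapsed")
})

test_that("ep_ratio follows the area arithmetic and the 14.8% rule", {
  fake_mix <- function(ep, fp, op = 0) {
    structure(list(components = data.frame(
      label = c("EP", "FP", "OP"), mean = c(3.73e6, 4.51e6, 5.3e6),
      sd = 1e5, amplitude = 1, area = c(ep, fp, op)),
      bin_width = 5e4, residual_rms = 0, converged = TRUE,
      merged = character()), class = "species_mixture_fit")
  }
  r <- ep_ratio(fake_mix(30, 60, 10))
  expect_equal(r$ep_ratio, 0.30)
  expect_true(r$significant)
  r2 <- ep_ratio(fake_mix(10, 90))
  expect_equal(r2$ep_ratio, 0.10)
  expect_false(r2$significant)
  r0 <- ep_ratio(fake_mix(0, 100))
  expect_equal(r0$ep_ratio, 0)
  expect_false(r0$significant)
  # invariance under uniform area rescaling
  expect_equal(ep_ratio(fake_mix(3, 6, 1))$ep_ratio, 0.30)
  # boundary: strictly greater than the threshold (37/250 = 0.148 exactly)
  expect_false(ep_ratio(fake_mix(37, 213))$significant)

  nofp <- fake_mix(1, 1)
  nofp$components <- nofp$components[nofp$components$label != "FP", ]
  expect_error(ep_ratio(nofp), "FP")
})

test_that("noise_threshold is mean plus k standard deviations", {
  expect_equal(noise_threshold(0.077, 0.023, 3), 0.146)
  expect_equal(noise_threshold(0.1, 0), 0.1)
  expect_equal(noise_threshold(0.1, 0.05, k = 0), 0.1)
  expect_error(noise_threshold(0.1, -0.01), "noise_sd")
})

test_that("unbinding_fraction equals the brute-force count oracle", {
  expect_equal(unbinding_fraction(c(-1, -2, -3, rep(1, 7))), 0.3)
  expect_equal(unbinding_fraction(rep(2, 5)), 0)
  # zero counts as binding
  expect_equal(unbinding_fraction(c(0, -1)), 0.5)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(200)
    expect_equal(unbinding_fraction(x), sum(x < 0) / length(x))
  }
  expect_error(unbinding_fraction(numeric()), "empty")
})

test_that("antibody-binding shifts are detected against the pooled-SE rule", {
  base <- data.frame(label = "FP", mean = 4.51e6, sd = 0.12e6, weight = 1)
  shifted <- base; shifted$mean <- 4.51e6 + 0.9e6
  fit_of <- function(comps, seed) {
    ev <- simulate_mp_events(comps, 3000, unbinding_prob = 0, seed = seed)
    fit_species_mixture(build_histogram(ev, mass_range = c(2e6, 7e6)),
                        comps[c("label", "mean")])
  }
  pre <- fit_of(base, 31); post <- fit_of(shifted, 32)
  v <- detect_antibody_binding(pre, post)
  expect_true(v$bound)
  expect_lt(abs(v$shift_Da - 0.9e6) / 0.9e6, 0.05)
  # identical fits: zero shift, not bound
  same <- detect_antibody_binding(pre, pre)
  expect_equal(same$shift_Da, 0)
  expect_false(same$bound)
})
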