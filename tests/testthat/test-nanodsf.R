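test_that("fraction_unfolded matches direct evaluation and its limits", {
  # at Tm = dH/dS the exponent vanishes
  expect_equal(fraction_unfolded(1.46e5, 434, 1.46e5 / 434), 0.5)
  # direct evaluation at 62 degC with R = 1.987
  direct <- function(dH, dS, T) {
    e <- exp(-dH / (1.987 * T) + dS / 1.987); e / (1 + e)
  }
  expect_equal(fraction_unfolded(1.46e5, 434, 335.15),
               direct(1.46e5, 434, 335.15), tolerance = 1e-12)
  expect_equal(round(fraction_unfolded(1.46e5, 434, 335.15), 3), 0.306)
  # infinite-cooperativity limit: step at Tm
  Tm <- 1.46e5 / 434
  expect_lt(fraction_unfolded(1e9, 1e9 / Tm, Tm - 0.5), 1e-6)
  expect_gt(fraction_unfolded(1e9, 1e9 / Tm, Tm + 0.5), 1 - 1e-6)
  expect_error(fraction_unfolded(1e5, 400, -3), "positive")
})

test_that("fraction_unfolded is bounded and monotone over random parameters", {
  set.seed(42)
  for (i in 1:25) {
    dH <- runif(1, 5e4, 5e5)
    Tm <- runif(1, 310, 360)
    TK <- seq(280, 380, by = 0.5)
    fu <- fraction_unfolded(dH, dH / Tm, TK)
    expect_true(all(fu >= 0 & fu <= 1))
    # non-decreasing everywhere; strictly increasing away from the
    # double-precision saturation plateaus at 0 and 1
    expect_true(all(diff(fu) >= 0))
    core <- fu > 1e-12 & fu < 1 - 1e-12
    expect_true(all(diff(fu[core]) > 0))
  }
})

test_that("melting and onset temperatures invert the two-state model", {
  expect_equal(melting_temperature(3.21e5, 925), 321000 / 925 - 273.15,
               tolerance = 1e-12)
  expect_equal(round(melting_temperature(3.21e5, 925), 1), 73.9)
  expect_equal(melting_temperature(2.7315e5, 1000), 0)
  # ratio invariance
  expect_equal(melting_temperature(2 * 1.46e5, 2 * 434),
               melting_temperature(1.46e5, 434))

  expect_equal(round(onset_temperature(1.46e5, 434), 1), 58.8)
  expect_equal(onset_temperature(1.46e5, 434, f_onset = 0.5),
               melting_temperature(1.46e5, 434))
  # closed-form consistency: fU at the returned temperatures
  set.seed(7)
  for (i in 1:20) {
    dH <- runif(1, 5e4, 5e5); dS <- runif(1, 150, 1200)
    Tm <- melting_temperature(dH, dS)
    To <- onset_temperature(dH, dS)
    expect_lt(abs(fraction_unfolded(dH, dS, Tm + 273.15) - 0.5), 1e-9)
    expect_lt(abs(fraction_unfolded(dH, dS, To + 273.15) - 0.05), 1e-9)
    expect_lt(To, Tm)
  }
  expect_error(melting_temperature(-1, 400), "positive")
  expect_error(onset_temperature(1e5, 400, f_onset = 0.7), "f_onset")
})

test_that("predict_signal interpolates between the two baselines", {
  p <- transition_params(2e5, 2e5 / 335.15, a = 0.001, b = 0.85,
                         c = 0.002, d = 0.90)
  # far below Tm: folded baseline; far above: unfolded baseline
  expect_equal(predict_signal(p, 10), 0.001 * 10 + 0.85, tolerance = 1e-8)
  expect_equal(predict_signal(p, 95), 0.002 * 95 + 0.90, tolerance = 1e-4)
  # at Tm the signal is the baseline mean
  TmC <- 335.15 - 273.15
  expect_equal(predict_signal(p, TmC),
               ((0.001 * TmC + 0.85) + (0.002 * TmC + 0.90)) / 2,
               tolerance = 1e-9)
})

test_that("noiseless round trip recovers generating parameters to 0.1%", {
  # shared-slope truth, first-transition scheme
  dH <- 1.46e5; dS <- dH / 335.15
  p <- transition_params(dH, dS, a = 0.001, b = 0.85, c = 0.001, d = 0.88)
  tg <- data.frame(temperature_C = seq(45, 70, by = 0.1))
  tg$signal <- predict_signal(p, tg$temperature_C)
  f <- fit_first_transition(tg, c(45, 70))
  expect_true(f$converged)
  expect_lt(abs(f$params$dH - dH) / dH, 1e-3)
  expect_lt(abs(f$params$dS - dS) / dS, 1e-3)
  expect_lt(abs(f$Tm_C - (335.15 - 273.15)), 0.01)

  # free-baseline scheme on a single major transition
  dH2 <- 2.78e5; Tm2K <- 73.8 + 273.15
  p2 <- transition_params(dH2, dH2 / Tm2K, a = 0.0012, b = 0.86,
                          c = 0.0008, d = 1.02)
  tg2 <- data.frame(temperature_C = seq(65, 85, by = 0.1))
  tg2$signal <- predict_signal(p2, tg2$temperature_C)
  f2 <- fit_second_transition(tg2, c(65, 85), inherited = NULL)
  expect_true(f2$converged)
  expect_lt(abs(f2$params$dH - dH2) / dH2, 1e-3)
  expect_lt(abs(f2$Tm_C - 73.8), 0.01)
})

test_that("study-condition thermograms are recovered within reporting tolerances", {
  res <- lapply(1:20, function(s) {
    tg <- simulate_thermogram(fp_ld_first, fp_ld_second,
                              noise_sd = 1e-3, seed = s)
    f <- fit_thermogram(tg)
    expect_true(f$first$converged)
    expect_true(f$second$converged)
    # closed-form Tm/Tonset consistency on every fit
    for (tr in f) {
      expect_lt(abs(fraction_unfolded(tr$params$dH, tr$params$dS,
                                      tr$Tm_C + 273.15) - 0.5), 1e-9)
      expect_lt(abs(fraction_unfolded(tr$params$dH, tr$params$dS,
                                      tr$Tonset_C + 273.15) - 0.05), 1e-9)
      expect_lt(tr$Tonset_C, tr$Tm_C)
    }
    c(Tm1 = f$first$Tm_C, dH1 = f$first$params$dH, Tm2 = f$second$Tm_C)
  })
  m <- colMeans(do.call(rbind, res))
  expect_lt(abs(m["Tm1"] - 62.0), 0.5)
  expect_lt(abs(m["dH1"] - 1.46e5) / 1.46e5, 0.05)
  expect_lt(abs(m["Tm2"] - 73.7), 0.3)
})

test_that("curves without a first transition are flagged, not fitted", {
  # pure baseline
  tgb <- simulate_thermogram(NULL, NULL, noise_sd = 1e-3, seed = 2)
  fb <- fit_first_transition(tgb)
  expect_false(fb$converged)
  expect_match(fb$reason, "transition|flat")
  # empty-particle-like curve: only the major VP3 transition
  tge <- simulate_thermogram(NULL, second = list(Tm_C = 73.8, dH = 2.78e5),
                             noise_sd = 1e-3, seed = 3)
  expect_false(fit_first_transition(tge)$converged)
  f2 <- fit_second_transition(tge, inherited = NULL)
  expect_true(f2$converged)
  expect_lt(abs(f2$params$dH - 2.78e5) / 2.78e5, 0.05)
})

test_that("second-transition fit validates window ordering", {
  tg <- simulate_thermogram(fp_ld_first, fp_ld_second, noise_sd = 1e-3,
                            seed = 4)
  f1 <- fit_first_transition(tg)
  expect_error(fit_second_transition(tg, window = c(40, 60), inherited = f1),
               "precede")
})

test_that("per-gram normalisation reproduces the globular-range assignment", {
  pg <- per_gram(1.46e5, 434, 2.2e4)
  expect_equal(pg$h, 146000 / 22000)           # 6.64 cal/g
  expect_equal(pg$s_g, 434 / 22000)            # 1.97e-2 cal/(K g)
  expect_true(pg$within_globular_range)
  # mass equal to dH gives 1 cal/g, far outside the range
  expect_false(per_gram(1.46e5, 434, 1.46e5)$within_globular_range)
  # scale invariance: per_gram(k dH, k dS, k m) == per_gram(dH, dS, m)
  a <- per_gram(1.46e5, 434, 2.2e4)
  b <- per_gram(3 * 1.46e5, 3 * 434, 3 * 2.2e4)
  expect_equal(a$h, b$h)
  expect_equal(a$s_g, b$s_g)
  expect_error(per_gram(1e5, 400, 0), "positive")
})

test_that("replicate summaries are means and SDs of per-replicate fits", {
  fits <- lapply(1:3, function(s) {
    tg <- simulate_thermogram(fp_ld_first, fp_ld_second,
                              noise_sd = 1e-3, seed = 100 + s)
    fit_first_transition(tg)
  })
  s <- summarise_fits(fits)
  expect_setequal(s$parameter, c("Tonset_C", "Tm_C", "dH", "dS"))
  tms <- vapply(fits, function(f) f$Tm_C, numeric(1))
  expect_equal(s$mean[s$parameter == "Tm_C"], mean(tms))
  expect_equal(s$sd[s$parameter == "Tm_C"], sd(tms))
  expect_true(all(s$n == 3))
})

test_that("thermogram tables round-trip through delimited text", {
  tg <- simulate_thermogram(fp_ld_first, NULL, noise_sd = 1e-3, seed = 6)
  tg$sample_id <- "FP_LD"; tg$replicate <- 1L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_output_table(tg, path, seed = 6)
  back <- read_thermograms(path)
  expect_equal(back$signal, tg$signal, tolerance = 1e-12)
  expect_equal(back$sample_id[1], "FP_LD")
})
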