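#' Two-state unfolded fraction
#'
#' Equilibrium fraction of unfolded protein in the two-state model
#' `K = fU/(1 - fU)`, `dG = dH - T*dS = -RT log K`, so
#' `fU = exp(-dH/(R T) + dS/R) / (1 + exp(-dH/(R T) + dS/R))`.
#'
#' @param dH van't Hoff enthalpy change, cal/mol (> 0 for unfolding)
#' @param dS entropy change, cal/(K·mol)
#' @param T_K absolute temperature(s), K
#' @return unfolded fraction in \[0, 1\], same length as `T_K`
#' @export
fraction_unfolded <- function(dH, dS, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("T_K must be a positive absolute temperature in kelvin")
  x <- -dH / (.RGAS * T_K) + dS / .RGAS
  stats::plogis(x)  # exp(x)/(1+exp(x)), overflow-safe
}

#' Melting temperature from two-state parameters
#'
#' Temperature at which `fU = 0.5`, i.e. `Tm = dH/dS` (in kelvin),
#' returned in °C.
#'
#' @inheritParams fraction_unfolded
#' @return Tm in °C
#' @export
melting_temperature <- function(dH, dS) {
  if (any(dH <= 0) || any(dS <= 0)) stop("dH and dS must be positive")
  dH / dS - .KELVIN
}

#' Onset temperature from two-state parameters
#'
#' Temperature at which the unfolded fraction equals `f_onset`
#' (default 0.05). Closed form from inverting the two-state expression:
#' `T = dH / (dS + R log((1 - f)/f))`.
#'
#' @inheritParams fraction_unfolded
#' @param f_onset unfolded fraction defining the onset, in (0, 0.5\]
#' @return onset temperature in °C
#' @export
onset_temperature <- function(dH, dS, f_onset = 0.05) {
  if (any(dH <= 0) || any(dS <= 0)) stop("dH and dS must be positive")
  if (f_onset <= 0 || f_onset > 0.5) stop("f_onset must lie in (0, 0.5]")
  dH / (dS + .RGAS * log((1 - f_onset) / f_onset)) - .KELVIN
}

#' Construct two-state transition parameters
#'
#' Bundles the thermodynamic parameters with the linear baselines of the
#' folded (`E_F = a*T + b`) and unfolded (`E_U = c*T + d`) states; baseline
#' slopes are per °C and intercepts in signal units at 0 °C.
#'
#' @param dH enthalpy change, cal/mol
#' @param dS entropy change, cal/(K·mol)
#' @param a,b folded-baseline slope and intercept
#' @param c,d unfolded-baseline slope and intercept
#' @return an object of class `transition_params`
#' @export
transition_params <- function(dH, dS, a, b, c, d) {
  stopifnot(dH > 0, dS > 0)
  structure(list(dH = dH, dS = dS, a = a, b = b, c = c, d = d),
            class = "transition_params")
}

#' Predicted nano-DSF signal for one two-state transition
#'
#' `E(T) = E_F + (E_U - E_F) * fU(T)` with linear baselines.
#'
#' @param params a [transition_params()] object
#' @param temperature_C temperature grid in °C
#' @return predicted F350/F330 signal
#' @export
predict_signal <- function(params, temperature_C) {
  T_K <- temperature_C + .KELVIN
  fU <- fraction_unfolded(params$dH, params$dS, T_K)
  EF <- params$a * temperature_C + params$b
  EU <- params$c * temperature_C + params$d
  EF + (EU - EF) * fU
}

# Reparameterised model used by the optimiser: (Tm_K, dH) instead of
# (dH, dS) so the sigmoid midpoint is a direct parameter; dS = dH/Tm_K.
.fu_tm <- function(dH, Tm_K, T_K) stats::plogis(dH / .RGAS * (1 / Tm_K - 1 / T_K))

#' Fit the first unfolding transition of a thermogram
#'
#' Nonlinear least squares of the two-state model over a temperature
#' window, with the constraint that the folded and unfolded baselines
#' share one slope (`a = c`), the scheme used for the small pre-transition
#' of VP1-containing capsids where the window is too narrow to determine
#' two slopes.
#'
#' @param tg a thermogram data frame with columns `temperature_C`, `signal`
#' @param window length-2 numeric, °C window to fit (default `c(45, 70)`)
#' @param f_onset unfolded fraction defining Tonset (default 0.05)
#' @return an object of class `transition_fit`; inspect `$converged` —
#'   a thermogram with no transition in the window (e.g. an empty-particle
#'   or VP3-only sample) yields `converged = FALSE` with diagnostics
#'   rather than an error
#' @export
fit_first_transition <- function(tg, window = c(45, 70), f_onset = 0.05) {
  .fit_transition(tg, window, mode = "first", inherited = NULL,
                  f_onset = f_onset)
}

#' Fit the second (major) unfolding transition of a thermogram
#'
#' For samples whose first transition was fitted, the folded baseline of
#' the second transition is fixed to the unfolded baseline of the first
#' (`a2 = c1`, `b2 = d1`); for single-transition samples (no `inherited`)
#' all four baseline parameters are free.
#'
#' @inheritParams fit_first_transition
#' @param window °C window to fit (default `c(65, 85)`)
#' @param inherited a `transition_fit` from [fit_first_transition()], or
#'   `NULL` for single-transition samples
#' @return an object of class `transition_fit`
#' @export
fit_second_transition <- function(tg, window = c(65, 85), inherited = NULL,
                                  f_onset = 0.05) {
  if (!is.null(inherited)) {
    if (!inherits(inherited, "transition_fit"))
      stop("inherited must be a transition_fit")
    if (inherited$window[2] > window[2])
      stop("inherited fit window must precede the second-transition window")
  }
  mode <- if (is.null(inherited)) "free" else "second"
  .fit_transition(tg, window, mode = mode, inherited = inherited,
                  f_onset = f_onset)
}

# Shared fitting engine. mode: "first" (a = c), "second" (folded baseline
# fixed from inherited), "free" (all baselines free).
.fit_transition <- function(tg, window, mode, inherited, f_onset) {
  stopifnot(is.data.frame(tg),
            all(c("temperature_C", "signal") %in% names(tg)),
            length(window) == 2L, window[1] < window[2])
  sel <- tg$temperature_C >= window[1] & tg$temperature_C <= window[2]
  Tc <- tg$temperature_C[sel]
  y <- tg$signal[sel]
  if (length(Tc) < 20L)
    stop("fit window must contain at least 20 points")

  fail <- function(reason) {
    structure(list(converged = FALSE, reason = reason, mode = mode,
                   window = window, n = length(Tc)),
              class = "transition_fit")
  }
  if (stats::sd(y) < .Machine$double.eps^0.5)
    return(fail("signal is flat over the window"))

  # --- initial values ------------------------------------------------
  # Tm: temperature of maximum smoothed derivative; dH: 1e5 cal/mol;
  # baselines: linear fits to the outer 20% of the window.
  dy <- diff(y) / diff(Tc)
  k <- max(1L, min(21L, length(dy) %/% 4L))
  dys <- stats::filter(dy, rep(1 / k, k), sides = 2)
  Tm0_deriv <- Tc[which.max(dys)] + .KELVIN
  # multi-start: derivative argmax plus fixed quartiles of the window,
  # all clamped strictly inside; best fit by residual sum wins
  Tm0_set <- unique(pmin(pmax(
    c(Tm0_deriv, window[1] + c(0.3, 0.5, 0.7) * diff(window) + .KELVIN),
    window[1] + 1 + .KELVIN), window[2] - 1 + .KELVIN))
  dH0 <- 1e5
  lo_idx <- Tc <= window[1] + 0.2 * diff(window)
  hi_idx <- Tc >= window[2] - 0.2 * diff(window)
  lo_fit <- stats::coef(stats::lm(y[lo_idx] ~ Tc[lo_idx]))
  hi_fit <- stats::coef(stats::lm(y[hi_idx] ~ Tc[hi_idx]))
  # observed rise of the window top above the extrapolated folded
  # baseline: a robust positive starting transition amplitude
  amp0 <- max(mean(y[hi_idx]) -
                (lo_fit[1] + lo_fit[2] * mean(Tc[hi_idx])),
              0.05 * diff(range(y)))

  dat <- data.frame(Tc = Tc, TK = Tc + .KELVIN, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                     ptol = 1e-8)
  fit_from <- function(Tm0) switch(mode,
    first = {
      # a = c constraint collapses the model to baseline + amp * fU with
      # amp = d - b; amp bounded >= 0 (F350/F330 rises on unfolding)
      start <- list(dH = dH0, TmK = Tm0, a = unname(lo_fit[2]),
                    b = unname(lo_fit[1]), amp = unname(amp0))
      try(minpack.lm::nlsLM(
        y ~ (a * Tc + b) + amp * .fu_tm(dH, TmK, TK),
        data = dat, start = start,
        lower = c(dH = 1e3, TmK = window[1] + .KELVIN,
                  a = -Inf, b = -Inf, amp = 0),
        upper = c(dH = 1e8, TmK = window[2] + .KELVIN,
                  a = Inf, b = Inf, amp = Inf),
        control = ctrl), silent = TRUE)
    },
    second = {
      a1 <- inherited$params$c
      b1 <- inherited$params$d
      start <- list(dH = dH0, TmK = Tm0, cc = unname(hi_fit[2]),
                    d = unname(hi_fit[1]))
      try(minpack.lm::nlsLM(
        y ~ (a1 * Tc + b1) +
          ((cc * Tc + d) - (a1 * Tc + b1)) * .fu_tm(dH, TmK, TK),
        data = c(dat, list(a1 = a1, b1 = b1)), start = start,
        lower = c(dH = 1e3, TmK = window[1] + .KELVIN, cc = -Inf, d = -Inf),
        upper = c(dH = 1e8, TmK = window[2] + .KELVIN, cc = Inf, d = Inf),
        control = ctrl), silent = TRUE)
    },
    free = {
      start <- list(dH = dH0, TmK = Tm0,
                    a = unname(lo_fit[2]), b = unname(lo_fit[1]),
                    cc = unname(hi_fit[2]), d = unname(hi_fit[1]))
      try(minpack.lm::nlsLM(
        y ~ (a * Tc + b) +
          ((cc * Tc + d) - (a * Tc + b)) * .fu_tm(dH, TmK, TK),
        data = dat, start = start,
        lower = c(dH = 1e3, TmK = window[1] + .KELVIN,
                  a = -Inf, b = -Inf, cc = -Inf, d = -Inf),
        upper = c(dH = 1e8, TmK = window[2] + .KELVIN,
                  a = Inf, b = Inf, cc = Inf, d = Inf),
        control = ctrl), silent = TRUE)
    },
    stop("unknown mode"))

  fits <- lapply(Tm0_set, fit_from)
  fits <- Filter(function(f) !inherits(f, "try-error"), fits)
  # discard fits pinned at a window edge, with no real transition, or
  # whose sigmoid does not substantially complete inside the window
  # (the windowed scheme presumes the transition is contained in it)
  inside <- function(f) {
    cf <- stats::coef(f)
    dH <- unname(cf["dH"]); TmK <- unname(cf["TmK"])
    fu_lo <- .fu_tm(dH, TmK, window[1] + .KELVIN)
    fu_hi <- .fu_tm(dH, TmK, window[2] + .KELVIN)
    Tm_C <- TmK - .KELVIN
    amp <- switch(mode,
      first = unname(cf["amp"]),
      second = (unname(cf["cc"]) - inherited$params$c) * Tm_C +
        (unname(cf["d"]) - inherited$params$d),
      free = (unname(cf["cc"]) - unname(cf["a"])) * Tm_C +
        (unname(cf["d"]) - unname(cf["b"])))
    dH > 1.5e3 && amp > 0 &&
      TmK > window[1] + .KELVIN + 1e-6 &&
      TmK < window[2] + .KELVIN - 1e-6 &&
      fu_lo < 0.25 && fu_hi > 0.75
  }
  fits <- Filter(inside, fits)
  if (!length(fits))
    return(fail("no transition found inside the window"))
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]

  cf <- stats::coef(fit)
  dH <- unname(cf["dH"]); TmK <- unname(cf["TmK"])
  dS <- dH / TmK
  params <- switch(mode,
    first = transition_params(dH, dS, a = unname(cf["a"]), b = unname(cf["b"]),
                              c = unname(cf["a"]),
                              d = unname(cf["b"] + cf["amp"])),
    second = transition_params(dH, dS, a = inherited$params$c,
                               b = inherited$params$d,
                               c = unname(cf["cc"]), d = unname(cf["d"])),
    free = transition_params(dH, dS, a = unname(cf["a"]), b = unname(cf["b"]),
                             c = unname(cf["cc"]), d = unname(cf["d"])))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  # amplitude must separate the baselines at Tm, otherwise the
  # "transition" is a baseline artifact
  Tm_C <- TmK - .KELVIN
  amp <- (params$c - params$a) * Tm_C + (params$d - params$b)
  resid_rms <- sqrt(mean(stats::residuals(fit)^2))
  if (abs(amp) < max(1e-6, 10 * resid_rms / sqrt(length(Tc))))
    return(fail("transition amplitude indistinguishable from noise"))

  structure(list(
    converged = TRUE, mode = mode, params = params,
    Tm_C = melting_temperature(dH, dS),
    Tonset_C = onset_temperature(dH, dS, f_onset),
    f_onset = f_onset, residual_rms = resid_rms,
    se = se, window = window, n = length(Tc)),
    class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Two-state fit (%s): FAILED — %s\n", x$mode, x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "Two-state fit (%s baselines), window %g-%g degC, n = %d\n",
    x$mode, x$window[1], x$window[2], x$n))
  cat(sprintf("  dH = %.4g cal/mol, dS = %.4g cal/(K.mol)\n",
              x$params$dH, x$params$dS))
  cat(sprintf("  Tm = %.2f degC, Tonset(fU=%.2g) = %.2f degC, RMS = %.3g\n",
              x$Tm_C, x$f_onset, x$Tonset_C, x$residual_rms))
  invisible(x)
}

#' Fit both transitions of a thermogram with the windowed constraint scheme
#'
#' Convenience wrapper: fits the first transition with the shared-slope
#' constraint, then the second with its folded baseline inherited from the
#' first transition's unfolded baseline. When the first transition is not
#' found (empty particles or VP3-only capsids show no pre-transition), the
#' second transition is fitted with free baselines.
#'
#' @inheritParams fit_first_transition
#' @param window1,window2 °C fit windows for the two transitions
#' @return list with elements `first` and `second` (`transition_fit`s)
#' @export
fit_thermogram <- function(tg, window1 = c(45, 70), window2 = c(65, 85),
                           f_onset = 0.05) {
  first <- fit_first_transition(tg, window1, f_onset = f_onset)
  second <- fit_second_transition(
    tg, window2,
    inherited = if (first$converged) first else NULL,
    f_onset = f_onset)
  list(first = first, second = second)
}

#' Per-gram thermodynamic parameters and globular-range classification
#'
#' Normalises molar unfolding parameters by the mass of the candidate
#' unfolding domain and classifies the result against the calorimetric
#' range of globular proteins near 62 °C (5.7–8.7 cal/g for enthalpy,
#' 1.7–2.7e-2 cal/(K·g) for entropy). Matching both ranges supports
#' assigning the transition to the unfolding of a domain of that mass.
#'
#' @inheritParams fraction_unfolded
#' @param domain_mass candidate domain mass in g/mol (Da)
#' @param h_range,s_range globular reference ranges (cal/g, cal/(K·g))
#' @return list with `h` (cal/g), `s_g` (cal/(K·g)), `domain_mass`,
#'   `within_globular_range` (logical)
#' @export
per_gram <- function(dH, dS, domain_mass,
                     h_range = c(5.7, 8.7),
                     s_range = c(1.7e-2, 2.7e-2)) {
  if (domain_mass <= 0) stop("domain_mass must be positive")
  h <- dH / domain_mass
  s_g <- dS / domain_mass
  within <- h >= h_range[1] & h <= h_range[2] &
    s_g >= s_range[1] & s_g <= s_range[2]
  list(h = h, s_g = s_g, domain_mass = domain_mass,
       within_globular_range = within,
       h_range = h_range, s_range = s_range)
}

#' Summarise replicate transition fits as mean and SD per parameter
#'
#' Replicates are fitted independently; the reported value of each
#' parameter is the mean over replicates with its SD, which is why a
#' summary table's mean Tm need not equal mean(dH)/mean(dS).
#'
#' @param fits list of converged `transition_fit` objects (replicates)
#' @return data.frame with one row per parameter: mean, sd, n
#' @export
summarise_fits <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L)
    return(data.frame(parameter = character(), mean = numeric(),
                      sd = numeric(), n = integer()))
  grab <- function(f) c(Tonset_C = f$Tonset_C, Tm_C = f$Tm_C,
                        dH = f$params$dH, dS = f$params$dS)
  m <- do.call(rbind, lapply(fits, grab))
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             n = nrow(m), row.names = NULL)
}

#' Read thermograms from a delimited text file
#'
#' Expected columns: `temperature_C`, `signal`, `sample_id`, `replicate`.
#' Lines starting with `#` are treated as comments.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return data.frame of thermogram records
#' @export
read_thermograms <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("temperature_C", "signal", "sample_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("thermogram table is missing columns: ", paste(miss, collapse = ", "))
  df
}
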