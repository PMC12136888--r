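# Synthetic instrument emulators. Each generator draws from the same
# statistical model the corresponding analysis module fits, stores its
# generating parameters as attributes ("ground truth"), and is fully
# determined by its seed.

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a nano-DSF thermogram with known ground truth
#'
#' The noiseless signal is a global linear baseline plus one or two
#' additive sigmoidal transitions:
#' `E(T) = a*T + b + amp1 * fU1(T) + amp2 * fU2(T)`,
#' each `fU` the two-state unfolded fraction at the transition's `(Tm, dH)`
#' (`dS = dH/Tm_K`, so the midpoint is exactly `Tm`). Independent Gaussian
#' noise of SD `noise_sd` is added to every point. This composition makes
#' windowed two-transition fitting exact: over the first window the signal
#' follows the shared-slope model, and over the second window the folded
#' baseline equals the first transition's unfolded baseline.
#'
#' @param first list with `Tm_C` (°C) and `dH` (cal/mol), and optionally
#'   `amp` (signal amplitude of the transition, default 0.03); or `NULL`
#'   for no first transition
#' @param second same structure as `first` (default amplitude 0.15); or
#'   `NULL` for a single-transition (or baseline-only) curve
#' @param grid temperature grid in °C (strictly increasing)
#' @param noise_sd Gaussian noise SD in signal units (>= 0)
#' @param seed integer RNG seed
#' @param baseline length-2 numeric `c(slope, intercept)` of the global
#'   linear baseline
#' @param min_separation_C minimum allowed Tm separation between two
#'   supplied transitions; closer pairs are rejected because windowed
#'   fitting cannot resolve them
#' @return data.frame with columns `temperature_C`, `signal`; generating
#'   parameters in `attr(, "ground_truth")`
#' @export
simulate_thermogram <- function(first, second = NULL,
                                grid = seq(30, 100, by = 0.1),
                                noise_sd = 1e-3, seed = NULL,
                                baseline = c(0.001, 0.85),
                                min_separation_C = 2) {
  stopifnot(noise_sd >= 0, all(diff(grid) > 0))
  norm_tr <- function(tr, default_amp) {
    if (is.null(tr)) return(NULL)
    stopifnot(is.list(tr), !is.null(tr$Tm_C), !is.null(tr$dH), tr$dH > 0)
    if (is.null(tr$amp)) tr$amp <- default_amp
    tr$dS <- tr$dH / (tr$Tm_C + .KELVIN)
    stopifnot(tr$dS > 0)
    tr
  }
  first <- norm_tr(first, 0.03)
  second <- norm_tr(second, 0.15)
  if (!is.null(first) && !is.null(second) &&
      abs(second$Tm_C - first$Tm_C) < min_separation_C)
    stop("transitions closer than ", min_separation_C,
         " degC cannot be resolved by windowed fitting")

  TK <- grid + .KELVIN
  E <- baseline[1] * grid + baseline[2]
  for (tr in list(first, second))
    if (!is.null(tr))
      E <- E + tr$amp * fraction_unfolded(tr$dH, tr$dS, TK)

  noise <- if (noise_sd > 0)
    .with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  else rep(0, length(grid))

  out <- data.frame(temperature_C = grid, signal = E + noise)
  attr(out, "ground_truth") <- list(first = first, second = second,
                                    baseline = baseline,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate mass-photometry landing/unbinding events
#'
#' Event masses are drawn from a Gaussian mixture (one component per
#' particle species, e.g. empty/full/overpackaged, plus optionally a
#' near-zero noise component); each event is independently flagged as an
#' unbinding event with probability `unbinding_prob` and reported with
#' negative sign, mirroring how interferometric mass photometry displays
#' unbinding on the negative mass axis.
#'
#' @param components data.frame (or list coercible to one) with columns
#'   `mean` (Da), `sd` (Da), `weight` (mixture weights summing to 1), and
#'   optionally `label`
#' @param n_events number of events to draw (> 0)
#' @param unbinding_prob probability that an event is an unbinding event
#' @param seed integer RNG seed
#' @return data.frame with columns `mass_Da` (signed), `component`
#'   (ground-truth label), `unbinding` (logical); generating parameters in
#'   `attr(, "ground_truth")`
#' @export
simulate_mp_events <- function(components, n_events, unbinding_prob = 0,
                               seed = NULL) {
  components <- as.data.frame(components)
  stopifnot(all(c("mean", "sd", "weight") %in% names(components)),
            all(components$sd >= 0), all(components$weight >= 0))
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must sum to 1")
  if (n_events <= 0) stop("n_events must be positive")
  if (unbinding_prob < 0 || unbinding_prob > 1)
    stop("unbinding_prob must lie in [0, 1]")
  if (is.null(components$label))
    components$label <- paste0("comp", seq_len(nrow(components)))

  .with_seed(seed, {
    idx <- sample.int(nrow(components), n_events, replace = TRUE,
                      prob = components$weight)
    mass <- stats::rnorm(n_events, components$mean[idx], components$sd[idx])
    # the instrument-artifact component lives at |mass| < 2 MDa; truncate
    # its draws there so it never bleeds into the particle window
    is_noise <- components$label[idx] == "noise"
    while (any(bad <- is_noise & abs(mass) >= 2e6))
      mass[bad] <- stats::rnorm(sum(bad), components$mean[idx][bad],
                                components$sd[idx][bad])
    unb <- stats::runif(n_events) < unbinding_prob
    out <- data.frame(mass_Da = ifelse(unb, -abs(mass), abs(mass)),
                      component = components$label[idx],
                      unbinding = unb)
    attr(out, "ground_truth") <- list(components = components,
                                      unbinding_prob = unbinding_prob,
                                      n_events = n_events, seed = seed)
    out
  })
}

#' Simulate a table of sedimentation-velocity peaks
#'
#' Emulates the peak table extracted from a c(s) distribution with
#' two-wavelength detection: each species contributes one peak whose s
#' value is jittered and whose 230 nm / 260 nm areas follow its mass
#' fraction and A260/A230 composition ratio.
#'
#' @param species data.frame with columns `s_S` (svedbergs), `fraction`
#'   (mass fraction of total 230 nm signal), `ratio_260_230`; optionally
#'   `label`
#' @param jitter SD of Gaussian jitter applied to s values, in S
#' @param total_area_230 total 230 nm area distributed across species
#' @param seed integer RNG seed
#' @return data.frame with columns `s_S`, `area_230`, `area_260`,
#'   `ratio_260_230` (+ `label` if supplied); ground truth in attributes
#' @export
simulate_auc_peaks <- function(species, jitter = 0, total_area_230 = 1,
                               seed = NULL) {
  species <- as.data.frame(species)
  if (nrow(species) == 0L) {
    out <- data.frame(s_S = numeric(), area_230 = numeric(),
                      area_260 = numeric(), ratio_260_230 = numeric())
    attr(out, "ground_truth") <- list(species = species, jitter = jitter)
    return(out)
  }
  stopifnot(all(c("s_S", "fraction", "ratio_260_230") %in% names(species)),
            all(species$s_S > 0), jitter >= 0)
  .with_seed(seed, {
    s <- species$s_S + if (jitter > 0)
      stats::rnorm(nrow(species), 0, jitter) else 0
    a230 <- total_area_230 * species$fraction
    out <- data.frame(s_S = s, area_230 = a230,
                      area_260 = a230 * species$ratio_260_230,
                      ratio_260_230 = species$ratio_260_230)
    if (!is.null(species$label)) out$label <- species$label
    attr(out, "ground_truth") <- list(species = species, jitter = jitter,
                                      seed = seed)
    out
  })
}

#' Simulate hydrogen/deuterium-exchange uptake tables for two states
#'
#' Per peptide and state, deuterium uptake follows a single-exponential
#' approach to a plateau, `D(t) = plateau * (1 - exp(-k t))`, sampled at
#' the labeling time series with i.i.d. Gaussian noise per replicate.
#'
#' @param peptides data.frame with columns `start`, `end` and per-state
#'   plateaus/rates: `plateau_<state>` (Da) and `rate_<state>` (1/s) for
#'   each element of `states`; optional `modification`
#' @param states character vector of state labels (default
#'   `c("control", "heated")`)
#' @param times labeling times in seconds, positive increasing
#' @param noise_sd Gaussian noise SD in Da
#' @param n_replicates replicates per state/time
#' @param seed integer RNG seed
#' @return data.frame with columns `start`, `end`, `modification`, `state`,
#'   `time_s`, `replicate`, `uptake_Da`; ground truth in attributes
#' @export
simulate_hdx <- function(peptides, states = c("control", "heated"),
                         times = c(15, 30, 180, 600, 3600),
                         noise_sd = 0.05, n_replicates = 3, seed = NULL) {
  peptides <- as.data.frame(peptides)
  stopifnot(all(c("start", "end") %in% names(peptides)),
            all(diff(times) > 0), all(times > 0), noise_sd >= 0)
  if (is.null(peptides$modification)) peptides$modification <- ""
  for (st in states) {
    pcol <- paste0("plateau_", st); rcol <- paste0("rate_", st)
    if (!all(c(pcol, rcol) %in% names(peptides)))
      stop("peptides must carry columns ", pcol, " and ", rcol)
    if (any(peptides[[pcol]] < 0))
      stop("uptake plateaus must be non-negative")
  }
  grid <- expand.grid(pep = seq_len(nrow(peptides)), state = states,
                      time_s = times, replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  plateau <- mapply(function(p, st) peptides[[paste0("plateau_", st)]][p],
                    grid$pep, grid$state)
  rate <- mapply(function(p, st) peptides[[paste0("rate_", st)]][p],
                 grid$pep, grid$state)
  mu <- plateau * (1 - exp(-rate * grid$time_s))
  noise <- if (noise_sd > 0)
    .with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  else 0
  out <- data.frame(start = peptides$start[grid$pep],
                    end = peptides$end[grid$pep],
                    modification = peptides$modification[grid$pep],
                    state = grid$state, time_s = grid$time_s,
                    replicate = grid$replicate,
                    uptake_Da = pmax(0, mu + noise))
  attr(out, "ground_truth") <- list(peptides = peptides, states = states,
                                    times = times, noise_sd = noise_sd,
                                    n_replicates = n_replicates, seed = seed)
  out
}

#' Write a simulation manifest recording seed and ground truth
#'
#' @param ground_truth the `ground_truth` attribute of a simulated dataset
#'   (or any list of generating parameters)
#' @param path output file; written as YAML
#' @return `path`, invisibly
#' @export
write_manifest <- function(ground_truth, path) {
  clean <- rapply(ground_truth, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "ANY", how = "replace")
  yaml::write_yaml(clean, path)
  invisible(path)
}
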