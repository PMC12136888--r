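#' Fit a contrast-to-mass calibration line
#'
#' Ordinary least squares of known standard masses on measured contrasts
#' (BSA / apoferritin / thyroglobulin in a typical mass-photometry
#' calibration).
#'
#' @param standards data.frame with columns `name`, `mass_Da`, `contrast`
#' @return object of class `mass_calibration` with `slope` (Da per
#'   contrast unit), `intercept` (Da), `residuals`, and the standards
#' @export
fit_mass_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("mass_Da", "contrast") %in% names(standards)))
  if (nrow(standards) < 2L) stop("need at least 2 calibration standards")
  if (anyDuplicated(standards$contrast))
    stop("calibration standards have duplicate contrasts")
  fit <- stats::lm(mass_Da ~ contrast, data = standards)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 residuals = unname(stats::residuals(fit)),
                 standards = standards),
            class = "mass_calibration")
}

#' Apply a contrast-to-mass calibration
#'
#' @param cal a [fit_mass_calibration()] result
#' @param contrast numeric contrasts
#' @return masses in Da
#' @export
apply_calibration <- function(cal, contrast) {
  stopifnot(inherits(cal, "mass_calibration"))
  cal$intercept + cal$slope * contrast
}

#' Bin event masses into a histogram
#'
#' Half-open bins `[lo, hi)`: an event exactly on an edge belongs to the
#' upper bin. Events outside `mass_range` are dropped.
#'
#' @param events data.frame with column `mass_Da` (signed masses), or a
#'   numeric vector of masses
#' @param bin_width bin width in Da (default 50 kDa)
#' @param mass_range length-2 numeric, range analysed (default 2–7 MDa,
#'   the particle window)
#' @return data.frame with columns `mid` (bin centre, Da), `count`
#' @export
build_histogram <- function(events, bin_width = 5e4,
                            mass_range = c(2e6, 7e6)) {
  x <- if (is.data.frame(events)) events$mass_Da else events
  stopifnot(bin_width > 0)
  if (mass_range[2] <= mass_range[1]) stop("empty mass range")
  breaks <- seq(mass_range[1], mass_range[2] + bin_width, by = bin_width)
  x <- x[x >= mass_range[1] & x < breaks[length(breaks)]]
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(mid = breaks[-length(breaks)] + bin_width / 2, count = counts)
}

#' Fit a sum of Gaussian peaks to a mass histogram
#'
#' Least squares of `sum_i A_i exp(-(m - mu_i)^2 / (2 sd_i^2))` against
#' binned counts, the standard treatment of mass-photometry histograms.
#' Component means are box-constrained to `mean_tol` of their initial
#' guesses; per-component areas (event counts) come from the analytic
#' Gaussian integral divided by the bin width.
#'
#' @param hist a [build_histogram()] result (columns `mid`, `count`)
#' @param component_specs data.frame with columns `label` (e.g. "EP",
#'   "FP", "OP", "noise") and `mean` (initial mean, Da); optional `sd`
#'   initial guesses (default 3% of the mean)
#' @param mean_tol allowed fractional deviation of each fitted mean from
#'   its initial guess (default 0.20)
#' @return object of class `species_mixture_fit`: `components` data.frame
#'   (label, mean, sd, amplitude, area), `bin_width`, `residual_rms`,
#'   `converged`, `merged` (labels merged onto a shared mean, if any)
#' @export
fit_species_mixture <- function(hist, component_specs, mean_tol = 0.20) {
  stopifnot(is.data.frame(hist), all(c("mid", "count") %in% names(hist)))
  component_specs <- as.data.frame(component_specs)
  stopifnot(all(c("label", "mean") %in% names(component_specs)),
            nrow(component_specs) >= 1L)
  if (sum(hist$count) == 0) stop("histogram is empty")
  k <- nrow(component_specs)
  bw <- diff(hist$mid[1:2])
  if (is.null(component_specs$sd))
    component_specs$sd <- 0.03 * abs(component_specs$mean)

  # starting amplitudes: histogram height near each initial mean
  amp0 <- vapply(component_specs$mean, function(m) {
    max(hist$count[which.min(abs(hist$mid - m))], 1)
  }, numeric(1))

  par0 <- c(component_specs$mean, component_specs$sd, amp0)
  lower <- c(component_specs$mean * (1 - mean_tol), rep(bw / 2, k),
             rep(0, k))
  upper <- c(component_specs$mean * (1 + mean_tol),
             rep(diff(range(hist$mid)), k), rep(Inf, k))
  model <- function(p) {
    mu <- p[1:k]; sd <- p[(k + 1):(2 * k)]; A <- p[(2 * k + 1):(3 * k)]
    rowSums(vapply(seq_len(k), function(i)
      A[i] * exp(-(hist$mid - mu[i])^2 / (2 * sd[i]^2)),
      numeric(nrow(hist))))
  }
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) hist$count - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- res$info %in% 1:4
  p <- res$par
  comp <- data.frame(label = component_specs$label,
                     mean = p[1:k], sd = p[(k + 1):(2 * k)],
                     amplitude = p[(2 * k + 1):(3 * k)])
  comp$area <- comp$amplitude * comp$sd * sqrt(2 * pi) / bw

  # flag degenerate decompositions: components that collapsed onto one
  # mean, or that vanished because a neighbour absorbed their peak
  merged <- character()
  if (k > 1L) {
    ord <- order(comp$mean)
    for (i in seq_len(k - 1L)) {
      a <- ord[i]; b <- ord[i + 1L]
      if (abs(comp$mean[b] - comp$mean[a]) <
          0.5 * max(comp$sd[a], comp$sd[b]))
        merged <- c(merged, paste(comp$label[a], comp$label[b], sep = "+"))
    }
    vanished <- comp$label[comp$area < 1e-3 * sum(comp$area)]
    merged <- union(merged, vanished)
    if (length(merged))
      warning("mixture components collapsed or vanished: ",
              paste(merged, collapse = ", "))
  }
  structure(list(components = comp, bin_width = bw,
                 residual_rms = sqrt(mean(res$fvec^2)),
                 converged = converged, merged = merged),
            class = "species_mixture_fit")
}

#' @export
print.species_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%d components, bin %g kDa)%s\n",
              nrow(x$components), x$bin_width / 1e3,
              if (x$converged) "" else " [NOT CONVERGED]"))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-6s mean %7.3f MDa  sd %6.3f MDa  area %.1f\n",
                comp$label[i], comp$mean[i] / 1e6, comp$sd[i] / 1e6,
                comp$area[i]))
  invisible(x)
}

.mix_area <- function(mix, label) {
  i <- which(mix$components$label == label)
  if (!length(i)) return(NA_real_)
  sum(mix$components$area[i])
}

#' Empty-particle ratio and its significance
#'
#' `ep_ratio = EP area / (EP + FP + OP areas)`; a sample is flagged as
#' showing a significant EP increase when the ratio exceeds the noise
#' threshold (default 0.148, the +3 SD bound of the noise proportion
#' measured on unheated full-particle controls; recompute with
#' [noise_threshold()] for a new control set).
#'
#' @param mix a [fit_species_mixture()] result containing an FP component
#' @param threshold significance threshold on the ratio (default 0.148)
#' @return list with `ep_ratio`, `threshold`, `significant`
#' @export
ep_ratio <- function(mix, threshold = 0.148) {
  stopifnot(inherits(mix, "species_mixture_fit"))
  fp <- .mix_area(mix, "FP")
  if (is.na(fp)) stop("mixture fit contains no FP component")
  ep <- .mix_area(mix, "EP"); if (is.na(ep)) ep <- 0
  op <- .mix_area(mix, "OP"); if (is.na(op)) op <- 0
  ratio <- ep / (ep + fp + op)
  list(ep_ratio = ratio, threshold = threshold,
       significant = ratio > threshold)
}

#' Significance threshold from a control noise proportion
#'
#' `threshold = noise_mean + k * noise_sd` (default k = 3), the bound used
#' to call an EP increase significant relative to the analysis-artifact
#' background of a control sample.
#'
#' @param noise_mean mean noise proportion (fraction)
#' @param noise_sd SD of the noise proportion (fraction, >= 0)
#' @param k number of SDs (default 3)
#' @return threshold as a fraction
#' @export
noise_threshold <- function(noise_mean, noise_sd, k = 3) {
  stopifnot(noise_sd >= 0)
  noise_mean + k * noise_sd
}

#' Fraction of unbinding events
#'
#' Unbinding events carry negative signed mass; the fraction is
#' `count(mass < 0) / count(all)`. Events at exactly zero count as
#' binding.
#'
#' @param events data.frame with column `mass_Da`, or numeric vector
#' @return fraction in \[0, 1\]
#' @export
unbinding_fraction <- function(events) {
  x <- if (is.data.frame(events)) events$mass_Da else events
  if (!length(x)) stop("event set is empty")
  mean(x < 0)
}

#' Detect an antibody-binding mass shift between two mixture fits
#'
#' Compares the FP-component mean before and after antibody incubation;
#' binding is called when the shift exceeds `min_shift` (default 3 times
#' the pooled standard error of the two component means, each SE taken as
#' component SD over the square root of its area).
#'
#' @param pre_fit,post_fit [fit_species_mixture()] results with an FP
#'   component
#' @param min_shift minimum shift in Da to call binding, or `NULL` for
#'   the default 3x pooled SE rule
#' @return list with `shift_Da`, `min_shift`, `bound`
#' @export
detect_antibody_binding <- function(pre_fit, post_fit, min_shift = NULL) {
  comp_of <- function(m) {
    i <- which(m$components$label == "FP")
    if (!length(i)) stop("mixture fit contains no FP component")
    m$components[i[1], ]
  }
  pre <- comp_of(pre_fit); post <- comp_of(post_fit)
  shift <- post$mean - pre$mean
  if (is.null(min_shift)) {
    se2 <- pre$sd^2 / max(pre$area, 1) + post$sd^2 / max(post$area, 1)
    min_shift <- 3 * sqrt(se2)
  }
  list(shift_Da = shift, min_shift = min_shift, bound = shift > min_shift)
}

#' Read a mass-photometry event list from delimited text
#'
#' Accepts either a `mass_Da` column of signed masses, or a `contrast`
#' column plus a calibration to convert with.
#'
#' @param path file path
#' @param cal optional [fit_mass_calibration()] result, required when the
#'   table carries contrasts instead of masses
#' @param sep field separator (default tab)
#' @return data.frame with column `mass_Da`
#' @export
read_mp_events <- function(path, cal = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!"mass_Da" %in% names(df)) {
    if (!"contrast" %in% names(df))
      stop("event table needs a mass_Da or contrast column")
    if (is.null(cal))
      stop("contrast-based event table needs a calibration")
    df$mass_Da <- apply_calibration(cal, df$contrast)
  }
  df
}
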