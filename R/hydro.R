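# Svedberg-equation calculators. Internally CGS: masses g/mol, volumes
# mL/g (= cm^3/g), viscosity poise, friction g/s; sedimentation
# coefficients cross the interface in svedbergs (1 S = 1e-13 s).

.buoyancy <- function(vbar, rho) {
  b <- 1 - vbar * rho
  if (any(b <= 0))
    stop("neutral or negative buoyancy: (1 - vbar*rho) must be positive ",
         "for a sedimenting species")
  b
}

#' Sedimentation coefficient from the Svedberg relation
#'
#' `s = M (1 - vbar*rho) / (N_A * f)`.
#'
#' @param M molar mass, g/mol (Da)
#' @param vbar partial specific volume, mL/g
#' @param cond a [hydro_conditions()] object (solvent density/viscosity)
#' @param f translational frictional coefficient, g/s
#' @return sedimentation coefficient in svedbergs
#' @export
sedimentation_coefficient <- function(M, vbar, cond = hydro_conditions(), f) {
  stopifnot(M > 0, f > 0)
  M * .buoyancy(vbar, cond$rho) / (.NAVO * f) / .SVED
}

#' Frictional coefficient from an observed sedimentation coefficient
#'
#' Algebraic inverse of [sedimentation_coefficient()]:
#' `f = M (1 - vbar*rho) / (N_A * s)`.
#'
#' @inheritParams sedimentation_coefficient
#' @param s sedimentation coefficient in svedbergs
#' @return frictional coefficient in g/s
#' @export
frictional_coefficient <- function(M, vbar, cond = hydro_conditions(), s) {
  stopifnot(M > 0, s > 0)
  M * .buoyancy(vbar, cond$rho) / (.NAVO * s * .SVED)
}

#' Frictional coefficient of the anhydrous equivalent sphere
#'
#' Stokes friction `f0 = 6 pi eta R0` of a compact sphere with the
#' particle's anhydrous volume, `R0 = (3 M vbar / (4 pi N_A))^(1/3)`.
#'
#' @inheritParams sedimentation_coefficient
#' @return f0 in g/s
#' @export
sphere_frictional_coefficient <- function(M, vbar, cond = hydro_conditions()) {
  stopifnot(M > 0, vbar > 0)
  R0 <- (3 * M * vbar / (4 * pi * .NAVO))^(1 / 3)
  6 * pi * cond$eta * R0
}

#' Frictional ratio f/f0 of a sedimenting particle
#'
#' Experimental friction from the Svedberg relation divided by the
#' Stokes friction of the anhydrous equivalent sphere. Values near 1.2
#' indicate compact globular particles; substantially larger values an
#' elongated or extended shape. Ratios below 1 are physically impossible
#' and flagged with a warning.
#'
#' @inheritParams frictional_coefficient
#' @return dimensionless f/f0
#' @export
frictional_ratio <- function(M, s, vbar, cond = hydro_conditions()) {
  f <- frictional_coefficient(M, vbar, cond, s)
  f0 <- sphere_frictional_coefficient(M, vbar, cond)
  ratio <- f / f0
  if (any(ratio < 1))
    warning("frictional ratio below 1 is unphysical; check M, s, vbar")
  ratio
}

#' Expected s value after a mass change at constant shape
#'
#' Under the Svedberg relation with unchanged frictional coefficient and
#' partial specific volume, s scales linearly with mass:
#' `s_new = s_ref * M_new / M_ref`.
#'
#' @param s_ref reference sedimentation coefficient, S
#' @param M_ref,M_new reference and new molar masses (any common unit)
#' @return expected sedimentation coefficient in S
#' @export
expected_s_after_mass_change <- function(s_ref, M_ref, M_new) {
  stopifnot(M_ref > 0, M_new > 0)
  s_ref * M_new / M_ref
}

#' Mass-weighted composite partial specific volume
#'
#' For a particle built from components of different chemistry (e.g. a
#' protein capsid plus its ssDNA cargo), the particle vbar is the
#' mass-weighted mean of the component values.
#'
#' @param components data.frame with columns `mass_Da` and `vbar`
#' @return composite vbar in mL/g
#' @export
composite_vbar <- function(components) {
  components <- as.data.frame(components)
  if (nrow(components) == 0L) stop("component list is empty")
  stopifnot(all(c("mass_Da", "vbar") %in% names(components)),
            all(components$mass_Da > 0))
  sum(components$mass_Da * components$vbar) / sum(components$mass_Da)
}

#' Classify a sedimentation peak by its A260/A230 area ratio
#'
#' Nearest-reference classification: the peak is assigned the label whose
#' reference A260/A230 is closest; ties break toward the lower reference
#' ratio. Default references are an empty capsid (0.10) and a genome-
#' containing full particle (0.47).
#'
#' @param peak list or one-row data.frame with `area_230` and `area_260`
#'   (or a precomputed `ratio_260_230`)
#' @param references named numeric vector of reference ratios
#' @return the winning label (character)
#' @export
classify_peak <- function(peak, references = c(EP = 0.10, FP = 0.47)) {
  if (!length(references)) stop("reference set is empty")
  ratio <- if (!is.null(peak$ratio_260_230)) peak$ratio_260_230
  else {
    if (is.null(peak$area_230) || peak$area_230 <= 0)
      stop("peak has no 230 nm area; ratio undefined, unclassifiable")
    peak$area_260 / peak$area_230
  }
  d <- abs(references - ratio)
  cand <- names(references)[d == min(d)]
  if (length(cand) > 1L)
    cand <- cand[which.min(references[cand])]
  cand
}

#' Fraction of signal lost to large aggregates
#'
#' `(before - after) / before`, e.g. the loss of 230 nm absorbance after
#' a low-speed spin that pellets heat-induced aggregates.
#'
#' @param signal_before,signal_after scalar signals (before > 0)
#' @return fraction lost
#' @export
aggregate_loss <- function(signal_before, signal_after) {
  stopifnot(signal_before > 0)
  (signal_before - signal_after) / signal_before
}

#' Read a sedimentation peak table from delimited text
#'
#' Expected columns: `s_S`, `area_230`, `area_260`.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return data.frame with an added `ratio_260_230` column
#' @export
read_auc_peaks <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("s_S", "area_230", "area_260")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "))
  df$ratio_260_230 <- ifelse(df$area_230 > 0,
                             df$area_260 / df$area_230, NA_real_)
  df
}
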