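#' Construct a particle composition
#'
#' An AAV capsid is a 60-mer of VP1, VP2 and VP3; a particle optionally
#' carries an ssDNA cargo described by its base count and average
#' per-base mass. Monomer masses are serotype-specific inputs (see the
#' shipped `aav8_particle.yaml` config for AAV8 values).
#'
#' @param vp_counts integer vector `c(n_VP1, n_VP2, n_VP3)`, summing to 60
#' @param vp_monomer_masses numeric vector of the three monomer masses, Da
#' @param genome_bases number of cargo nucleotides (0 for an empty capsid)
#' @param per_base_mass average nucleotide mass, Da/nt (default 330)
#' @param allow_vp_loss allow counts not summing to 60 (heat-induced VP
#'   loss scenarios)
#' @return object of class `particle_composition`
#' @export
particle_composition <- function(vp_counts, vp_monomer_masses,
                                 genome_bases = 0, per_base_mass = 330,
                                 allow_vp_loss = FALSE) {
  stopifnot(length(vp_counts) == 3L, all(vp_counts >= 0),
            length(vp_monomer_masses) == 3L, all(vp_monomer_masses > 0),
            genome_bases >= 0, per_base_mass > 0)
  if (!allow_vp_loss && sum(vp_counts) != 60L)
    stop("VP counts must sum to 60 (use allow_vp_loss = TRUE for ",
         "VP-loss scenarios)")
  structure(list(vp_counts = vp_counts,
                 vp_monomer_masses = vp_monomer_masses,
                 genome_bases = genome_bases,
                 per_base_mass = per_base_mass),
            class = "particle_composition")
}

#' Theoretical particle mass
#'
#' Sum of VP monomer masses weighted by stoichiometry plus the cargo
#' mass (`genome_bases * per_base_mass`).
#'
#' @param comp a [particle_composition()] object
#' @return mass in Da
#' @export
particle_mass <- function(comp) {
  stopifnot(inherits(comp, "particle_composition"))
  sum(comp$vp_counts * comp$vp_monomer_masses) +
    comp$genome_bases * comp$per_base_mass
}

#' Cargo mass from measured total and empty-particle masses
#'
#' @param total_particle_mass measured particle mass, Da
#' @param empty_particle_mass empty-capsid mass, Da
#' @return cargo mass in Da
#' @export
cargo_mass <- function(total_particle_mass, empty_particle_mass) {
  if (total_particle_mass < empty_particle_mass)
    stop("total particle mass is below the empty-capsid mass")
  total_particle_mass - empty_particle_mass
}

#' Nucleotide count from an ssDNA mass
#'
#' @param mass ssDNA mass, Da
#' @param per_base_mass average nucleotide mass, Da/nt (default 330)
#' @return nearest integer base count
#' @export
bases_from_mass <- function(mass, per_base_mass = 330) {
  stopifnot(per_base_mass > 0, mass >= 0)
  round(mass / per_base_mass)
}

#' Enumerate cargo compositions consistent with a measured cargo mass
#'
#' Exhaustive bounded search over non-negative integer counts of the
#' candidate cargo species whose total mass lies within `tolerance` of
#' the target and whose total base count respects the packaging
#' capacity. Solutions are sorted by absolute mass residual, then by
#' total number of molecules (fewest first).
#'
#' @param target_cargo target cargo mass, Da
#' @param candidates data.frame with columns `label`, `mass_Da`, and
#'   optionally `bases` (defaults to `mass_Da / per_base_mass`)
#' @param tolerance allowed |total - target| in Da (>= 0)
#' @param max_total_bases packaging capacity in nt (default 5200,
#'   wild-type ~4.7 kb plus margin)
#' @param per_base_mass Da/nt used when `bases` is absent
#' @param max_molecules optional cap on the total molecule count per
#'   solution (default unlimited)
#' @return data.frame with one row per solution: one count column per
#'   candidate label, plus `total_mass_Da`, `residual_Da`, `total_bases`,
#'   `n_molecules`
#' @export
enumerate_cargo_compositions <- function(target_cargo, candidates,
                                         tolerance, max_total_bases = 5200,
                                         per_base_mass = 330,
                                         max_molecules = Inf) {
  candidates <- as.data.frame(candidates)
  stopifnot(nrow(candidates) >= 1L,
            all(c("label", "mass_Da") %in% names(candidates)),
            all(candidates$mass_Da > 0), tolerance >= 0, target_cargo >= 0)
  if (is.null(candidates$bases))
    candidates$bases <- round(candidates$mass_Da / per_base_mass)

  # per-species count ceiling from mass, capacity and molecule budget
  maxn <- pmin(floor((target_cargo + tolerance) / candidates$mass_Da),
               ifelse(candidates$bases > 0,
                      floor(max_total_bases / candidates$bases), Inf),
               max_molecules)
  maxn[!is.finite(maxn)] <- max(0, floor(max_molecules))
  grid <- do.call(expand.grid, lapply(maxn, function(m) 0:m))
  names(grid) <- candidates$label
  cnt <- as.matrix(grid)
  total_mass <- as.vector(cnt %*% candidates$mass_Da)
  total_bases <- as.vector(cnt %*% candidates$bases)
  n_mol <- rowSums(cnt)
  keep <- abs(total_mass - target_cargo) <= tolerance &
    total_bases <= max_total_bases & n_mol <= max_molecules
  out <- grid[keep, , drop = FALSE]
  out$total_mass_Da <- total_mass[keep]
  out$residual_Da <- total_mass[keep] - target_cargo
  out$total_bases <- total_bases[keep]
  out$n_molecules <- n_mol[keep]
  out <- out[order(abs(out$residual_Da), out$n_molecules), , drop = FALSE]
  rownames(out) <- NULL
  out
}
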