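---
title: "Models and methods: thermal stability and genome ejection analytics for rAAV capsids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: thermal stability and genome ejection analytics for rAAV capsids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavheat)
```

Recombinant adeno-associated virus (rAAV) particles are 60-mer protein
capsids (VP1:VP2:VP3, canonically 5:5:50) packaging a single-stranded
DNA genome. On heating, particles can eject their genome while the
capsid stays assembled; the unfolding of the VP1 N-terminal regions
(the ~22 kDa VP1u plus VP1/VP2 common region) gates this release. This
package implements the quantitative chain used to characterise that
process from four instrument classes — nano-DSF thermograms, mass
photometry (MP) event streams, sedimentation-velocity AUC (SV-AUC)
peak tables and HDX-MS uptake tables — together with a synthetic-data
generator that emulates each instrument with known ground truth, so
every fitting routine can be validated by parameter recovery.

## Two-state thermal unfolding of thermograms

The nano-DSF observable is the fluorescence ratio E = F350/F330 on a
temperature ramp. The unfolded fraction in a two-state equilibrium is

$$f_U(T) = \frac{\exp(-\Delta H/RT + \Delta S/R)}
               {1 + \exp(-\Delta H/RT + \Delta S/R)},$$

with R = 1.987 cal/(K·mol) throughout (calorie units to match the
calorimetric literature). The signal interpolates two linear baselines,
$E = E_F + (E_U - E_F) f_U$ with $E_F = aT + b$, $E_U = cT + d$.
Temperatures cross the interface in °C and are converted to kelvin
(offset 273.15) for all thermodynamic evaluation. `melting_temperature()`
returns $T_m = \Delta H/\Delta S$ (where $f_U = 1/2$);
`onset_temperature()` solves $f_U = f_{\text{onset}}$ (default 0.05)
in closed form, $T = \Delta H / (\Delta S + R\ln((1-f)/f))$, so
$f_U(T_m) = 0.5$ and $f_U(T_{onset}) = f_{\text{onset}}$ hold to
machine precision on every fit by construction.

Capsids with VP1/VP2 show a small pre-transition (VP1 N-termini
unfolding) before the major VP3 transition, so fitting is windowed:

* **First transition** (default window 45–70 °C): the window is too
  narrow to determine two baseline slopes, so the folded and unfolded
  baselines share one slope (a = c), collapsing the model to
  $aT + b + \text{amp}\, f_U(T)$ with amplitude $= d - b \ge 0$
  (F350/F330 rises on unfolding).
* **Second transition** (default window 65–85 °C): its folded baseline
  is fixed to the first transition's unfolded baseline ($a_2 = c_1$,
  $b_2 = d_1$); for samples with no first transition (empty particles,
  VP3-only capsids) all four baseline parameters are free.

The defaults were chosen from the fitted onsets (first onset ≈ 55 °C,
second onset ≈ 71–72 °C) so each window contains one nearly complete
sigmoid. Optimisation is Levenberg–Marquardt (minpack.lm) on the
reparameterisation $(T_m, \Delta H)$ with $\Delta S = \Delta H/T_m$ —
better conditioned than $(\Delta H, \Delta S)$, whose strong
correlation otherwise dominates the fit. Starting values: $T_m$ from
the maximum of a smoothed signal derivative plus three fixed window
quantiles (multi-start; best residual wins), $\Delta H = 10^5$ cal/mol,
baselines from linear fits to the outer 20% of the window, amplitude
from the rise of the window top above the extrapolated folded baseline.
A converged optimum is accepted only if it describes a real transition:
amplitude positive and above the noise floor, $T_m$ strictly inside the
window, and the fitted sigmoid substantially complete within it
($f_U < 0.25$ entering, $> 0.75$ leaving). Anything else is reported as
a flagged failure — deliberately, because empty and VP3-only particles
genuinely lack the first transition and must not be force-fitted.
Convergence uses a relative parameter tolerance of 1e-8.

Replicates are fitted independently and summarised as mean ± SD per
parameter (`summarise_fits()`); note this means a summary table's mean
$T_m$ need not equal mean $\Delta H$ / mean $\Delta S$.

`per_gram()` divides the molar parameters by a candidate domain mass
and classifies against the calorimetric ranges of globular proteins
near 62 °C (5.7–8.7 cal/g; 1.7–2.7 × 10⁻² cal/(K·g)). Of the candidate
domains only the ~22 kDa VP1 N-termini fall inside both ranges, which
is the quantitative basis for assigning the first transition to their
unfolding.

## Mass-photometry population decomposition

Landing events carry positive mass, unbinding events negative mass.
Species quantification uses binding events only, binned into a
histogram (default 50 kDa bins over the 2–7 MDa particle window;
half-open bins, edge values to the upper bin) and fitted by least
squares with a sum of Gaussians — histogram-level fitting rather than
event-level maximum likelihood, for fidelity to how MP distributions
are routinely analysed. Component means are box-constrained to ±20% of
their initial guesses; areas come from the analytic Gaussian integral.
Degenerate decompositions (two components collapsing onto one mean, or
a component vanishing into a neighbour) raise a warning instead of
silently returning.

The EP ratio is EP area / (EP + FP + OP areas). The default
significance threshold is 0.148: the operating constant derived from
control samples as the mean noise proportion (7.7%) plus three SDs
(2.3%). The strict arithmetic 0.077 + 3 × 0.023 = 0.146 differs in the
third decimal — the published constant evidently used unrounded SDs —
and the package keeps the published 0.148 as the default while
`noise_threshold()` recomputes mean + k·SD from any new control set.
`unbinding_fraction()` is the count of negative-mass events over all
events (exactly zero counts as binding; the tie rule is arbitrary but
fixed). Antibody binding is called when the FP-component mean shifts by
more than 3 pooled standard errors between pre- and post-incubation
fits.

## Hydrodynamic interpretation of sedimentation peaks

The Svedberg relation $s = M(1-\bar v\rho)/(N_A f)$ connects peak
position to mass and friction. Units are CGS internally (g, cm, s,
poise) with s in svedbergs (10⁻¹³ s) at the interface; $N_A$ =
6.022 × 10²³ mol⁻¹. The frictional ratio divides the experimental
$f = M(1-\bar v\rho)/(N_A s)$ by the Stokes friction
$f_0 = 6\pi\eta R_0$ of the anhydrous equivalent sphere,
$R_0 = (3M\bar v / 4\pi N_A)^{1/3}$ — the standard convention, with no
hydration shell. Ratios near 1.2 mean compact and globular; ~2 means
strongly elongated (e.g. a capsid tethering its ejected genome).
Values below 1 are unphysical and flagged.

Defaults: PBS at 20 °C (ρ = 1.005 g/mL, η = 1.002 cP), protein
$\bar v$ = 0.730 mL/g, ssDNA 0.550 mL/g, both configurable; a
composite particle takes the mass-weighted mean (`composite_vbar()`),
giving 0.698 mL/g for the 3.73 MDa capsid + 0.8 MDa genome. With these
defaults the control full particle (4.55 MDa, 91.3 S) gives
f/f₀ = 1.21. For the heated-sample peaks at 54.6 S and 84.7 S
(4.45 MDa) the same constants give ≈ 1.99 and ≈ 1.29 versus reported
values of 2.07 and 1.33; the ~4% gap reflects that the exact
$\bar v$, ρ and η behind the reported values are software-derived and
not recoverable from composition alone, so these two are treated as
approximate (5% bands) rather than exact targets.

`expected_s_after_mass_change()` scales s linearly with mass at
constant f and $\bar v$ — the null model for "mass loss only". The
observed heated peak falling below that prediction is what licenses the
conclusion that particle shape changed as well. Peaks are classified by
their A260/A230 area ratio against nearest references (defaults:
empty capsid 0.10, full particle 0.47; an extended set adds the
genome-ejected-but-tethered species at 0.58, needed because two
references can only ever produce two labels). Ties break toward the
lower reference — fixed, and exercised only on a set of measure zero.

## Particle mass model and cargo enumeration

`particle_mass()` is the VP-count-weighted sum of monomer masses plus
`genome_bases × per_base_mass`. Monomer masses are serotype-specific
inputs; the shipped `aav8_particle.yaml` carries approximate AAV8
sequence masses (81.6/66.6/59.8 kDa), which with 5:5:50 stoichiometry
give the 3.73 MDa empty and (with the 0.78 MDa designed genome)
4.51 MDa full particle. The per-base ssDNA mass is exposed, not
hidden, defaulting to 330 Da/nt: the quoted genome masses imply
anything from ~310 to ~340 Da/nt depending on which pair of printed
numbers is divided, so no single hidden constant is defensible.

`enumerate_cargo_compositions()` does an exhaustive bounded search over
non-negative integer counts of candidate cargo species, keeping
combinations whose total mass is within tolerance of the target and
whose total bases respect the packaging capacity (default 5.2 kb:
wild-type ~4.7 kb plus margin). It is validated against a naive
nested-loop oracle. For the 1.6 MDa overpackaged-particle cargo with
candidates {1.6, 0.8, 0.2} MDa it returns four compositions: one large
genome, two full genomes, one full genome + four fragments, and eight
fragments. The fourth is a genuine solution of the stated constraints
and is retained — fragment-dominated fills are in fact the dominant
observed species — even though narrative summaries often quote only the
first three.

## HDX-MS differential uptake

Per peptide (keyed by start, end and modification note — acetylated
N-terminal peptides are distinct species), uptake is averaged over
replicates per state and time; the accumulated difference is the sum
over the labeling series (15, 30, 180, 600, 3600 s) of the per-time
mean differences (treated − control). The pooled SD combines per-time
variances of the difference of means by root-sum-of-squares. A peptide
is significant when the accumulated difference strictly exceeds
3.281 Da. That constant is an instrument-calibrated operating value
whose statistical construction (α, number of comparisons) is not
derivable here, so it is a configurable default, with an optional
recomputation mode (k × median pooled SD) provided as an extension —
explicitly not the original derivation.

## The synthetic-data generator

The generator is the package's validation instrument, and its defaults
are the study conditions, not tuning knobs:

* **Thermograms**: global linear baseline plus one or two additive
  sigmoids, $E = aT + b + \text{amp}_1 f_{U,1} + \text{amp}_2 f_{U,2}$,
  with i.i.d. Gaussian noise. Transitions are parameterised by
  $(T_m, \Delta H)$ with $\Delta S = \Delta H/T_m$, so the synthetic
  truth is self-consistent at the stated midpoint. This additive
  composition makes the windowed constraint scheme exact: within the
  first window the curve follows the shared-slope model, and the second
  window's folded baseline equals the first's unfolded baseline.
  Transitions closer than 2 °C are rejected as unresolvable by
  windowed fitting. The default noise SD is 1 × 10⁻³ signal units — a
  realistic ratio-channel noise floor for capillary nano-DSF; the real
  instrument's noise magnitude is not published, so this is a package
  choice, documented and configurable. What the generator does *not*
  emulate: scan-rate effects, temperature-correlated drift,
  aggregation-induced scattering artifacts — so passing recovery tests
  demonstrates correctness of the fitting machinery under the stated
  noise model, not robustness to every real-world artifact.
* **MP events**: Gaussian mixture over species plus an optional
  zero-centred noise component truncated to |mass| < 2 MDa (the
  artifact window); each event flips to negative mass with the
  unbinding probability. Default study mixture: 3.73/4.51/5.3 MDa,
  SDs 0.12–0.15 MDa, n = 5000 events.
* **AUC peaks**: species rows with jittered s and areas split by mass
  fraction and composition ratio. No Lamm-equation physics — peak
  tables, not sedimentation profiles, are the package's input contract.
* **HDX uptake**: single-exponential approach to a per-state plateau,
  $D(t) = \text{plateau}(1 - e^{-kt})$, Gaussian noise 0.05 Da,
  triplicates.

All generators are deterministic given a seed, restore the caller's
RNG state, and attach their generating parameters as a `ground_truth`
attribute (exportable as a YAML manifest).

## Problem sizes and numerical choices

The validation suite fits 20 independent noisy thermograms (701-point
grids), twenty 5000-event MP mixtures and ten unbinding streams —
sizes chosen so that Monte Carlo error is well below the acceptance
tolerances (e.g. binomial SE of an unbinding fraction at n = 5000 is
0.7 percentage points) while the whole suite runs in seconds.
Tie-breaks (histogram bin edges upward, zero-mass events as binding,
classification ties to the lower reference) are arbitrary but fixed
and tested. Degenerate inputs — flat signals, empty event sets,
neutral-buoyancy particles, unreachable cargo targets — error or flag
explicitly rather than returning numbers.

## Known limitations

* The nano-DSF model is strictly two-state and equilibrium; kinetic
  (scan-rate-dependent) unfolding and three-state models are out of
  scope, and windowed fitting leaves a small systematic residual
  (≲2% in $\Delta H_1$) from the neighbouring transition's tail inside
  the window.
* Mixture decomposition needs initial means per component; it does not
  discover the number of species.
* The frictional-ratio calculation depends on $\bar v$, ρ and η whose
  study-specific values are not fully published; heated-particle
  shape ratios are therefore approximate.
* Raw instrument processing (interferometric movies, c(s) fitting,
  spectral deconvolution, peptide identification, back-exchange
  correction) is upstream of this package by design.
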