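---
title: "A multigroup Boltzmann-Fokker-Planck dose engine: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multigroup Boltzmann-Fokker-Planck dose engine: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfpdose)
```

## The problem

Electron beams of 1-20 MeV deposit dose in tissue through an enormous
number of small-energy-loss, small-angle collisions punctuated by rare
"catastrophic" events: hard (Moller) ionizations that eject a fast delta
ray, bremsstrahlung emission, and occasional large-angle elastic
deflections.  Resolving every collision deterministically is hopeless;
ignoring the catastrophic ones (the Fermi-Eyges/pencil-beam tradition)
fails badly near heterogeneities.  The Boltzmann-Fokker-Planck (BFP)
splitting keeps the best of both: soft collisions are collapsed into
continuous coefficients - a *restricted stopping power* `beta_g`
(MeV/cm) and a *restricted momentum transfer* `alpha_g` - while
catastrophic collisions are treated with full Boltzmann transfer matrices.
This package implements the whole chain in 1-D slab geometry:

1. a multigroup cross-section generator (`assemble_library()`) that builds,
   from analytic microscopic cross sections, the Legendre transfer matrices,
   catastrophic totals, restricted stopping powers and energy/charge
   deposition cross sections on a user group structure;
2. a discrete-ordinates (S_N) BFP solver (`solve_bfp()`) with Legendre
   scattering anisotropy, an extended transport correction for the
   forward-peaked elastic kernel, and a conservative multigroup
   continuous-slowing-down (CSD) operator;
3. an independent condensed-history Monte Carlo sampler (`run_mc()`) built
   on the *same* analytic cross sections and the *same* library, used as
   the verification reference;
4. benchmark drivers (`run_benchmark()`) for heterogeneous radiotherapy
   slab phantoms with the 2%-of-maximum-dose agreement statistic.

## Physics models

**Ionization** uses the relativistic free-electron Moller cross section.
By convention the lower-energy outgoing electron is the delta ray (energy
`W <= E/2`); the principal electron keeps `E - W`.  Both deflection
cosines follow from relativistic two-body kinematics,
`mu^2 = (E'/E)(E + 2 m_e)/(E' + 2 m_e)`, so the angular kernels are Dirac
distributions and the Legendre moments are evaluated analytically as
`P_l(mu(E, E'))` inside the energy integrals - no angular quadrature is
needed for this channel.

**Elastic scattering** uses the screened-Rutherford cross section with
Moliere's Thomas-Fermi screening parameter, multiplied by the
McKinley-Feshbach Mott ratio factor above 256 keV (below that energy the
ratio expansion is unreliable and the factor is off by default; the
switch is exposed).  Scattering with `mu <= 0.999999` is "large-angle"
and handled by within-group Legendre moments; the forward spike carries
no deflection and is summarised by `alpha_g`.  After the moments
`F_l` are computed, the *extended transport correction* replaces them by
`F_l - F_L` (and reduces the total by `F_L`), which makes the strongly
forward-peaked kernel compatible with a low-order expansion; the default
solver path relies on this correction rather than differencing the
Fokker-Planck angular operator, so `alpha_g` is computed and stored but
not used by default.

**Bremsstrahlung** uses the Born-approximation Koch-Motz assembly
(3BN-class) with the analytic Elwert Coulomb correction and the nuclear
`Z^2` factor extended to `Z(Z+1)` for radiation in the atomic-electron
field.  The emitted photon is discarded at birth and its energy booked to
a radiated ledger (no photon transport); the electron continues with no
deflection, so all Legendre moments of this channel equal the l = 0
moment.  Photon energies below 1 keV are excluded (low-frequency cutoff),
as is the high-frequency tip where the residual electron falls below
1 keV: the Born formula misbehaves as the residual momentum vanishes and
the events are negligible.

**Atomic relaxation** produces isotropic Auger/Coster-Kronig electrons
after inner-shell impact ionization, with subshell cross sections
estimated from the Moller kernel above the binding-energy threshold and
radiationless yields `1 - omega` from embedded fluorescence-yield tables
(K, L1-L3 tracked; M kept as a level).  Emitted energies are booked at
the destination-group midpoint.  The channel feeds only the l = 0 moment
and does not contribute to the total reaction rate.  Transitions below
the 1 keV transport cutoff are dropped; their energy stays local.

**Stopping powers.** The collisional stopping power is the Bethe formula
with Bragg-additivity mean excitation energy and a Sternheimer density
effect driven purely by the plasma energy and `I` (no per-material fitted
constants); catalogue tissues carry their ICRU compound `I` values (75 eV
for water).  Below 10 keV a power law matched to the Bethe logarithmic
slope at 10 keV extends the curve to the 1 keV cutoff.  The radiative
stopping power is the integral of `k dsigma/dk` over the same analytic
bremsstrahlung kernel, which keeps the generator self-contained and, more
importantly, keeps the deterministic and Monte Carlo energy budgets
identical.  Against standard reference tables the Born-level radiative
stopping power runs ~10-15% high; this cancels in the BFP-vs-MC
comparison and contributes under 0.5% of the dose at 1 MeV.

## Group conventions and thresholds

Group 1 is the highest-energy group; boundaries decrease to the 1 keV
transport cutoff.  A *catastrophic* event down-scatters the electron into
a non-adjacent group: for a source in group `g` the soft/catastrophic
interface is the boundary `b[g+2]`, so the minimum catastrophic energy
loss is `W_c = E - b[g+2]`.  Two refinements matter in practice:

* **1 keV floor.**  `W_c` is floored at the transport cutoff: a delta ray
  below 1 keV cannot be tracked, so such losses stay in the soft channel.
  Without the floor the lowest groups integrate the `1/W^2` kernel into a
  divergence.
* **The threshold seam.**  Because the threshold steps with the group
  index, `beta(E)` jumps at every boundary (a sliver of events
  reclassifies between the CSD and transfer channels).  The dose books
  the CSD term as `beta_g * Phi_g` with `beta_g` the mean of the *two
  edge coefficients the discrete operator actually uses*; booking the
  both-edges-at-`t_g` average instead over-deposits by 1-2% of the beam
  energy, independent of the group count.

For the same reason the deposition cross sections book transferred-sink
energies at the flux-weighted group-average energy (what a discrete
electron actually carries), not at the exact kernel first moments: the
within-sink-group skew of the `1/W^2` kernel would otherwise leak into
the local dose.  With both choices the deterministic energy balance
closes to better than 0.1% at 300 groups, and exactly in the pure-CSD
limit.

Group averaging of the feed functions uses a flat within-group flux guess
(configurable in spirit; the midpoint `<E>_g` doubles as the
flux-weighted average energy).  Source-energy integration uses composite
4-point Gauss-Lobatto panels, split at the energies where a transfer
domain endpoint crosses a sink boundary when groups are wide (relative
width > 20%); sink integration uses 16-point Gauss-Legendre panels cut at
group boundaries and log-subdivided so no panel spans more than a factor
2.5.  Elastic moments are integrated with 128-point Gauss-Legendre in
`log(1 + 2 eta - mu)`, which resolves the screening peak (`eta ~ 1e-5`)
to ~1e-9 relative.

## Solver numerics

* **Angular quadrature:** Gauss-Legendre S_N on [-1, 1]; weights sum to 2,
  no zero direction.
* **Spatial scheme:** diamond differencing, swept per direction.  The
  set-to-zero negative-flux fixup exists but is *off by default*: the
  energy closure (below) carries a bounded, conservative oscillation at
  the spectral beam front, and rectifying negatives creates particles
  (observed as tens of percent of spurious energy).  Without the fixup
  the scheme is exactly conservative; `nfix` reports negative outflows.
* **Energy closure:** the CSD operator couples neighbouring groups through
  edge spectral fluxes with a theta-weighted diamond closure
  (`energy_theta = 0.5` is diamond, the default; `energy_closure = "step"`
  is the upwind scheme).  Upwind is robust but smears the slowing-down
  front by ~`1/sqrt(N_g)` of the range (an Erlang-residence artifact),
  which visibly distorts the dose falloff; diamond is second-order and
  non-diffusive.  Removal and downstream source share one edge
  coefficient, so the chain conserves particles exactly.
* **Beam injection:** the default is a first-collision treatment: the
  uncollided beam is marched *continuously* in (depth, energy) along the
  exact normal direction - no multigroup energy diffusion and no
  quadrature tilt - and its first-collision source feeds the S_N solve.
  The alternative boundary-condition injection (incoming flux on the most
  forward direction, current-preserving magnitude) is kept as an option;
  it tilts the beam to `mu_max(S_N)` (about 1% depth compression at S_16)
  and starts the energy cascade half a group low.
* **Iteration:** groups are solved in one top-down pass (no up-scatter);
  within a group, source iteration on the transport-corrected within-group
  scatter until the relative scalar-flux change is below `tol = 1e-5`.
* **Dose:** the production route folds the energy deposition cross
  sections with the scalar flux and adds the below-cutoff term - electrons
  crossing the 1 keV edge deposit their residual kinetic energy (1 keV
  each) locally.  A `"direct"` route reassembles the dose from totals,
  transfer moments, the radiated ledger and the restricted stopping
  powers; the two agree to rounding and guard the library wiring.

## The Monte Carlo reference

The sampler is multigroup in its *rates* (free flight to the next
catastrophic event uses the library's group-wise totals; continuous loss
uses the library's `beta_g`), but continuous in energy and angle: energy
losses are sampled from the analytic Moller and Koch-Motz kernels
restricted to the catastrophic domains, and elastic deflections from the
analytic screened-Mott cross section restricted to `mu <= 0.999999` by
inverse-CDF sampling with Mott rejection - never from truncated Legendre
reconstructions, which keeps the oracle numerically independent of the
Legendre and discrete-ordinates machinery it verifies.  Secondaries go on
a stack; electrons below 1 keV (and sub-cutoff deltas at birth) deposit
locally; photons are discarded to the radiated ledger.  The four ledger
components (deposited, radiated, leaked, below-cutoff) sum to
`histories * E0` to floating rounding by construction.  Batch means give
per-voxel standard errors; runs are bitwise reproducible at fixed seed.

What the shared library does and does not buy: sharing `Sigma_t,g` and
`beta_g` removes cross-section discrepancies from the comparison, so the
2% agreement statistic isolates the *discretisation* fidelity of the
deterministic chain (S_N, P_L, spatial and energy closures).  It does not
test the microscopic cross sections themselves against nature - that is
what the independent-recoding and quadrature oracles in the test suite
are for, and accuracy statements about real beams inherit the Born-level
approximations listed above.

## Phantoms and comparison

Four phantom families are built in: a homogeneous water slab; a thorax
stack (water 13%, cortical bone 7%, lung 22%, water 58%); a breast-IORT
stack (tumor 40%, aluminium 40%, steel 15%, breast tissue 5%); and an
11-slab high-heterogeneity patient-like stack
(adipose/muscle/bone/muscle/lung/muscle/bone/adipose/bone/muscle/adipose).
Slab thicknesses are fractions of the beam's CSDA range in the first
slab's material; the high-heterogeneity stack uses equal fractions — a documented default,
since its thickness split is not standardised; a YAML phantom definition
overrides it.
Tissue compositions are the ICRU-44 sets; tumor maps to soft tissue at
1.04 g/cm3 and steel to Fe:0.98/C:0.02, both documented surrogates.  Lung
defaults to the healthy inflated density 0.26 g/cm3 (configurable).

`compare_doses()` interpolates the reference profile onto the test grid
with a piecewise cubic Hermite interpolant whose node slopes come from
local 4-point cubic differentiation (it reproduces cubic polynomials
exactly), then reports the per-voxel error as a percentage of the maximum
dose, the mean absolute error, and the fraction of voxels within the
criterion (2% by default), overall and per material.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `E_max` | beam energy | top group boundary, <= 20 MeV |
| groups `N` | 100-300 | log-spaced to the 1 keV cutoff; falloff fidelity improves with `N` |
| `L` | 9 | Legendre order; 9 suffices at 1-6 MeV with the transport correction |
| `sn` | 16 | S_N order (Gauss-Legendre) |
| `tol` | 1e-5 | inner-iteration flux criterion |
| `energy_theta` | 0.5 | CSD closure weight (0.5 diamond ... 1 step) |
| `mu_star` | 0.999999 | forward-elastic boundary cosine |
| cutoff | 1 keV | transport cutoff and secondary-production floor |
| histories | 2e5 | MC histories for ~0.3-0.5% per-voxel errors |

## Problem sizes used by the tests

The unit suite runs on 8-40 group structures with small phantoms; the
oracle-equivalence tests use 300 groups (100 groups leaves ~2% of
within-group energy-quantisation smearing in the falloff; 300 brings the
maximum deviation comfortably under the criterion), P_9, S_16, 200 voxels
and 2e5 histories; the conservation and CSDA-limit checks use 300 groups
and 500 voxels.  The brute-force transfer oracle runs at 24 groups - the
coarsest structure at which non-adjacent catastrophic transfer is
possible, since the Moller `W <= E/2` cap meets the threshold only for
per-group ratios under sqrt(2); a literal 3-group ionization toy is
degenerate under this convention (the bremsstrahlung and elastic toys do
use 3 groups).

## Known limitations

* Born-level bremsstrahlung and the McKinley-Feshbach Mott factor degrade
  for high-Z targets; the elastic kernel below 256 keV is screened
  Rutherford only.  These are shared by both transport routes, so
  BFP-vs-MC comparisons remain meaningful for high-Z slabs, but absolute
  doses there carry the Born error.
* Photons are killed at birth: no fluorescence transport, no
  bremsstrahlung buildup; the radiated ledger quantifies what is ignored.
* 1-D slab geometry, normal-incidence monoenergetic beams, electrons only.
* The Fokker-Planck angular operator is folded into the extended
  transport correction; the stored `alpha_g` supports but the solver does
  not difference an angular diffusion term.
* Shell corrections and Barkas terms are absent from the Bethe formula;
  below 10 keV the power-law extrapolation is a pragmatic patch.

## A worked micro-example

```{r example, eval = FALSE}
gs  <- make_groups(1.0, 100)
lib <- assemble_library("water", gs, L = 9)
geom <- phantom_geometry(make_phantom("water", 1.0, 200))
src  <- beam_source(1.0)
sol  <- solve_bfp(geom, lib, src, sn = 16)
det  <- dose_profile(sol, lib, geom, src)
mc   <- run_mc(mc_config(2e5, seed = 1), geom, lib, src)
compare_doses(det, mc)
```
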