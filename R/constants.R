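## Physical constants (CODATA-2018 where it matters for reproducibility).
## Energies in MeV, lengths in cm, cross sections in barns unless stated.

#' Physical constants used by the dose engine
#'
#' A named list of the physical constants the cross-section kernels rely on:
#' electron rest energy (MeV), classical electron radius (cm), fine-structure
#' constant, Avogadro's number, barn-to-cm2 conversion and the MeV/g-to-Gy
#' dose conversion factor.
#'
#' @format Named list of scalars.
#' @export
bfp_constants <- list(
  me      = 0.51099895,        # electron rest energy [MeV]
  re      = 2.8179403262e-13,  # classical electron radius [cm]
  alpha   = 7.2973525693e-3,   # fine-structure constant
  navo    = 6.02214076e23,     # Avogadro [1/mol]
  barn    = 1e-24,             # [cm^2]
  mev_g_to_gy = 1.602176634e-10, # 1 MeV/g in Gy
  e_cutoff = 1e-3,             # transport cutoff [MeV]
  e_min_brems = 1e-3,          # low-frequency bremsstrahlung truncation [MeV]
  mu_forward = 0.999999        # forward-elastic boundary cosine
)

## 2*pi*re^2*me in barn*MeV: prefactor of the Moller and Rutherford kernels
.moller_pref <- function() {
  cc <- bfp_constants
  2 * pi * cc$re^2 / cc$barn * cc$me
}

## Lorentz kinematics helpers (E = kinetic energy in MeV)
.gamma_of <- function(E) 1 + E / bfp_constants$me
.beta2_of <- function(E) {
  g <- .gamma_of(E)
  1 - 1 / g^2
}
## (pc)^2 in MeV^2
.pc2_of <- function(E) E * (E + 2 * bfp_constants$me)
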