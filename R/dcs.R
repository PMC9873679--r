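## Analytic microscopic differential cross sections for the four
## electroatomic channels: Moller ionization (free-electron), screened Mott
## elastic scattering, Koch-Motz Born-approximation bremsstrahlung with an
## Elwert Coulomb correction, and the two-body deflection kinematics that
## make the ionization angular kernels Dirac distributions.

#' Moller ionization differential cross section
#'
#' Relativistic Moller cross section for collision of an electron of kinetic
#' energy `E` with a free electron, differential in the energy transfer `W`
#' (the delta-ray energy).  By the usual convention the delta ray is the
#' lower-energy outgoing electron, so `W <= E/2`; the principal scattered
#' electron carries `E - W`.
#'
#' @param E Incident kinetic energy (MeV).
#' @param W Energy transfer (MeV), in `(0, E/2]`.
#' @return dsigma/dW in barns/MeV per atomic electron (vectorised over `W`).
#' @export
moller_dcs <- function(E, W) {
  if (any(W <= 0) || any(W > E)) {
    stop("energy transfer W must lie in (0, E]", call. = FALSE)
  }
  if (any(W > E / 2 + 1e-12 * E)) {
    stop("W in (E/2, E] belongs to the primary-electron branch; ",
         "evaluate at E - W instead", call. = FALSE)
  }
  .moller_dcs_raw(E, W)
}

## unchecked kernel, used by quadrature over either branch
.moller_dcs_raw <- function(E, W) {
  me <- bfp_constants$me
  tau <- E / me
  b2 <- .beta2_of(E)
  eps <- W / E
  g1 <- (tau / (tau + 1))^2
  g2 <- (2 * tau + 1) / (tau + 1)^2
  br <- 1 / eps^2 + 1 / (1 - eps)^2 + g1 - g2 / (eps * (1 - eps))
  .moller_pref() / (b2 * E^2) * br
}

#' Deflection cosine from ionization two-body kinematics
#'
#' Cosine of the laboratory scattering angle of an outgoing electron of
#' kinetic energy `Eprime` produced by an incident electron of kinetic
#' energy `E`, from relativistic two-body energy-momentum conservation:
#' `mu^2 = (E'/E) (E + 2 m_e) / (E' + 2 m_e)`.
#'
#' @param E Incident kinetic energy (MeV).
#' @param Eprime Outgoing kinetic energy (MeV), `0 < Eprime <= E`.
#' @return Direction cosine in `[0, 1]` (vectorised over `Eprime`).
#' @export
moller_mu <- function(E, Eprime) {
  if (any(Eprime <= 0) || any(Eprime > E * (1 + 1e-12))) {
    stop("Eprime must lie in (0, E]", call. = FALSE)
  }
  me <- bfp_constants$me
  sqrt(pmin(1, (Eprime / E) * (E + 2 * me) / (Eprime + 2 * me)))
}

#' Moliere screening parameter
#'
#' Screening parameter `eta` of the screened-Rutherford/Mott elastic cross
#' section, from Moliere's Thomas-Fermi form:
#' `eta = (alpha^2 Z^(2/3) / (4 * 0.885^2)) * (m_e c^2)^2/(pc)^2 *
#'  (1.13 + 3.76 (alpha Z / beta)^2)`.
#'
#' @param E Kinetic energy (MeV).
#' @param Z Atomic number.
#' @return Dimensionless screening parameter (vectorised over `E`).
#' @export
moliere_eta <- function(E, Z) {
  cc <- bfp_constants
  b2 <- .beta2_of(E)
  pc2 <- .pc2_of(E)
  (cc$alpha^2 * Z^(2 / 3) / (4 * 0.885^2)) * (cc$me^2 / pc2) *
    (1.13 + 3.76 * (cc$alpha * Z)^2 / b2)
}

## McKinley-Feshbach Mott-to-Rutherford ratio factor
.mott_ratio <- function(E, mu, Z) {
  cc <- bfp_constants
  b <- sqrt(.beta2_of(E))
  s <- sqrt(pmax(0, (1 - mu) / 2))   # sin(theta/2)
  1 - b^2 * s^2 + pi * cc$alpha * Z * b * s * (1 - s)
}

#' Elastic (screened Mott) differential cross section
#'
#' Screened-Rutherford elastic cross section with Moliere screening,
#' optionally multiplied by the McKinley-Feshbach Mott ratio factor
#' (default: on above 256 keV, off below).  Differential in the deflection
#' cosine `mu`; azimuthally integrated (i.e. `2 pi dsigma/dOmega`).
#'
#' @param E Kinetic energy (MeV).
#' @param mu Deflection cosine in `[-1, 1]` (vectorised).
#' @param Z Atomic number.
#' @param mott `TRUE`, `FALSE` or `"auto"` (energy-switched default).
#' @return dsigma/dmu in barns per atom.
#' @export
elastic_dcs <- function(E, mu, Z, mott = "auto") {
  if (Z < 1) stop("Z must be >= 1", call. = FALSE)
  if (any(mu < -1 | mu > 1)) stop("mu must lie in [-1, 1]", call. = FALSE)
  cc <- bfp_constants
  b2 <- .beta2_of(E)
  eta <- moliere_eta(E, Z)
  pref <- 2 * pi * cc$re^2 / cc$barn * Z^2 * (1 - b2) / b2^2
  v <- pref / (1 + 2 * eta - mu)^2
  use_mott <- isTRUE(mott) || (identical(mott, "auto") && E > 0.256)
  if (use_mott) v <- v * .mott_ratio(E, mu, Z)
  v
}

## closed-form integral of the screened-Rutherford part over [mu1, mu2]
.elastic_sr_integral <- function(E, Z, mu1, mu2) {
  cc <- bfp_constants
  b2 <- .beta2_of(E)
  eta <- moliere_eta(E, Z)
  pref <- 2 * pi * cc$re^2 / cc$barn * Z^2 * (1 - b2) / b2^2
  a <- 1 + 2 * eta
  pref * (1 / (a - mu2) - 1 / (a - mu1))
}

#' Elwert Coulomb-correction factor for bremsstrahlung
#'
#' Ratio correction to the Born-approximation bremsstrahlung cross section,
#' `f = (beta_i/beta_f) (1 - exp(-2 pi alpha Z / beta_i)) /
#'      (1 - exp(-2 pi alpha Z / beta_f))`,
#' which tends to 1 as the photon energy vanishes (beta_f -> beta_i).
#'
#' @param E Incident kinetic energy (MeV).
#' @param k Photon energy (MeV), `k < E`.
#' @param Z Atomic number.
#' @return Dimensionless factor (vectorised over `k`).
#' @export
elwert_factor <- function(E, k, Z) {
  cc <- bfp_constants
  bi <- sqrt(.beta2_of(E))
  bf <- sqrt(.beta2_of(pmax(E - k, 1e-12)))
  x <- 2 * pi * cc$alpha * Z
  (bi / bf) * (1 - exp(-x / bi)) / (1 - exp(-x / bf))
}

#' Koch-Motz bremsstrahlung differential cross section
#'
#' Born-approximation bremsstrahlung cross section (Koch-Motz assembly,
#' formula 3BN class) differential in photon energy, with the analytic
#' Elwert factor, and the nuclear `Z^2` factor optionally extended to
#' `Z(Z+1)` to account for radiation in the field of the atomic electrons.
#'
#' @param E Incident kinetic energy (MeV).
#' @param k Photon energy (MeV), `0 < k < E` (vectorised).
#' @param Z Atomic number.
#' @param electron_field Include the atomic-electron field via `Z(Z+1)`
#'   (default `TRUE`).
#' @param elwert Apply the Elwert factor (default `TRUE`).
#' @return dsigma/dk in barns/MeV per atom.
#' @export
brems_dcs <- function(E, k, Z, electron_field = TRUE, elwert = TRUE) {
  if (any(k >= E)) stop("photon energy k must be below E", call. = FALSE)
  if (any(k <= 0)) stop("photon energy k must be positive", call. = FALSE)
  cc <- bfp_constants
  me <- cc$me
  ## total energies and momenta in units of me*c^2
  E0 <- (E + me) / me
  Ef <- (E - k + me) / me
  kk <- k / me
  p0 <- sqrt(E0^2 - 1)
  pf <- sqrt(pmax(Ef^2 - 1, 0))
  pf <- pmax(pf, 1e-10)
  eps0 <- 2 * log(E0 + p0)
  epsf <- 2 * log(Ef + pf)
  L <- 2 * log((E0 * Ef + p0 * pf - 1) / kk)
  t1 <- 4 / 3 - 2 * E0 * Ef * (pf^2 + p0^2) / (p0^2 * pf^2) +
    eps0 * Ef / p0^3 + epsf * E0 / pf^3 - epsf * eps0 / (p0 * pf)
  t2 <- 8 * E0 * Ef / (3 * p0 * pf) +
    kk^2 * (E0^2 * Ef^2 + p0^2 * pf^2) / (p0^3 * pf^3)
  t3 <- (kk / (2 * p0 * pf)) *
    ((E0 * Ef + p0^2) * eps0 / p0^3 -
     (E0 * Ef + pf^2) * epsf / pf^3 +
     2 * kk * E0 * Ef / (pf^2 * p0^2))
  zfac <- if (electron_field) Z * (Z + 1) else Z^2
  sig <- cc$alpha * cc$re^2 / cc$barn * zfac * (pf / p0) / kk *
    (t1 + L * (t2 + t3))
  sig <- sig / me                      # per MeV of photon energy
  if (elwert) sig <- sig * elwert_factor(E, k, Z)
  pmax(sig, 0)
}
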