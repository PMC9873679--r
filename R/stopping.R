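## Collisional (Bethe) and radiative stopping powers, Sternheimer density
## effect, sub-10-keV power-law extrapolation, catastrophic first moments
## and the restricted quantities beta_g (stopping power) and alpha_g
## (momentum transfer) of the Fokker-Planck operator.

## Sternheimer density-effect correction delta(E) from the general
## parameterisation driven by the plasma energy and I (no per-material
## fitted constants).  Insulator rules of the Sternheimer-Peierls recipe.
.sternheimer_delta <- function(material, E) {
  I_eV <- material$I * 1e6
  hwp <- 28.8159 * sqrt(material$rho * material$ZA_eff)   # plasma energy [eV]
  Cbar <- 2 * log(I_eV / hwp) + 1
  x <- 0.5 * log10(.pc2_of(E) / bfp_constants$me^2)       # log10(p/mc)
  if (I_eV < 100) {
    x1 <- 2.0
    x0 <- if (Cbar < 3.681) 0.2 else 0.326 * Cbar - 1.0
  } else {
    x1 <- 3.0
    x0 <- if (Cbar < 5.215) 0.2 else 0.326 * Cbar - 1.5
  }
  a <- (Cbar - 4.606 * x0) / (x1 - x0)^3
  d <- ifelse(x >= x1, 4.606 * x - Cbar,
       ifelse(x >= x0, 4.606 * x - Cbar + a * (x1 - x)^3, 0))
  pmax(d, 0)
}

## Bethe collisional mass stopping power, no low-E patch (E in MeV)
.bethe_sp <- function(material, E, density_effect = TRUE) {
  me <- bfp_constants$me
  tau <- E / me
  b2 <- .beta2_of(E)
  I <- material$I
  Ftau <- 1 - b2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  delta <- if (density_effect) .sternheimer_delta(material, E) else 0
  arg <- tau^2 * (tau + 2) / (2 * (I / me)^2)
  0.1535374 * material$ZA_eff / b2 * (log(arg) + Ftau - delta)
}

#' Collisional stopping power
#'
#' Bethe collisional mass stopping power with Bragg-additivity mean
#' excitation energy and Sternheimer density-effect correction.  Below
#' 10 keV, where the Bethe formula degrades, a power-law extrapolation
#' `S(E) = S(10 keV) (E/10 keV)^p` is used, with `p` matched to the Bethe
#' logarithmic slope just above 10 keV so the two branches join
#' continuously.
#'
#' @param material A [build_material()] object.
#' @param E Kinetic energy (MeV), `E >= 1 keV` (vectorised).
#' @param density_effect Apply the Sternheimer correction (default `TRUE`).
#' @return Mass stopping power in MeV cm2/g.
#' @export
collision_sp <- function(material, E, density_effect = TRUE) {
  if (any(E < bfp_constants$e_cutoff * (1 - 1e-9))) {
    stop("E below the 1 keV transport cutoff", call. = FALSE)
  }
  E10 <- 0.010
  lo <- E < E10
  out <- numeric(length(E))
  if (any(!lo)) out[!lo] <- .bethe_sp(material, E[!lo], density_effect)
  if (any(lo)) {
    s10 <- .bethe_sp(material, E10, density_effect)
    h <- 1e-4
    p <- (log(.bethe_sp(material, E10 + h, density_effect)) - log(s10)) /
      (log(E10 + h) - log(E10))
    out[lo] <- s10 * (E[lo] / E10)^p
  }
  out
}

#' Radiative stopping power
#'
#' Radiative mass stopping power obtained by integrating the photon-energy
#' weighted bremsstrahlung cross section, `integral of k dsigma/dk` over
#' `[1 keV, E - 1 keV]`, summed over the mixture's elements.  The 1 keV
#' truncations follow the low-frequency divergence cutoff and the exclusion
#' of the (negligible) high-frequency tip.
#'
#' @inheritParams collision_sp
#' @return Mass stopping power in MeV cm2/g (vectorised over `E`).
#' @export
radiative_sp <- function(material, E) {
  vapply(E, function(e) .radiative_sp1(material, e), numeric(1))
}

.radiative_sp1 <- function(material, E) {
  kmin <- bfp_constants$e_min_brems
  kmax <- E - bfp_constants$e_cutoff
  if (kmax <= kmin) return(0)
  ## high order: the near-tip region carries a square-root-type derivative
  gl <- .gl_cache(192)
  ## log-k substitution: integral k*dsig/dk dk = integral k^2*dsig/dk dlnk
  t <- log(kmin) + (gl$x + 1) / 2 * (log(kmax) - log(kmin))
  w <- gl$w / 2 * (log(kmax) - log(kmin))
  k <- exp(t)
  tot <- 0
  for (sym in names(material$atom_density)) {
    Z <- material$elements[[sym]]$Z
    sig <- brems_dcs(E, k, Z)
    tot <- tot + material$atom_density[[sym]] * sum(w * k^2 * sig)
  }
  tot * bfp_constants$barn / material$rho
}

## cached Gauss-Legendre rules on [-1,1]
.gl_env <- new.env(parent = emptyenv())
.gl_cache <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_env[[key]])) {
    r <- pracma::gaussLegendre(n, -1, 1)
    .gl_env[[key]] <- list(x = r$x, w = r$w)
  }
  .gl_env[[key]]
}

## Catastrophic first moments at a boundary energy E for soft/catastrophic
## threshold t (MeV): energy-loss moment of Moller (collisional) and photon
## moment of Koch-Motz (radiative).  Mass units, MeV cm2/g.
.cat_moment_coll <- function(material, E, t, nq = 64) {
  Wc <- max(E - t, bfp_constants$e_cutoff)
  Wmax <- E / 2
  if (Wc >= Wmax) return(0)
  gl <- .gl_cache(nq)
  u <- log(Wc) + (gl$x + 1) / 2 * (log(Wmax) - log(Wc))
  w <- gl$w / 2 * (log(Wmax) - log(Wc))
  W <- exp(u)
  ne_mass <- bfp_constants$navo * material$ZA_eff    # electrons per gram
  sum(w * W^2 * .moller_dcs_raw(E, W)) * ne_mass * bfp_constants$barn
}

.cat_moment_brems <- function(material, E, t) {
  kc <- max(E - t, bfp_constants$e_min_brems)
  kmax <- E - bfp_constants$e_cutoff
  if (kc >= kmax) return(0)
  ## same rule as the total radiative stopping power, so that when the
  ## catastrophic domain covers everything the two cancel exactly
  gl <- .gl_cache(192)
  u <- log(kc) + (gl$x + 1) / 2 * (log(kmax) - log(kc))
  w <- gl$w / 2 * (log(kmax) - log(kc))
  k <- exp(u)
  tot <- 0
  for (sym in names(material$atom_density)) {
    Z <- material$elements[[sym]]$Z
    tot <- tot + material$atom_density[[sym]] *
      sum(w * k^2 * brems_dcs(E, k, Z))
  }
  tot * bfp_constants$barn / material$rho
}

#' Restricted stopping powers for one energy group
#'
#' Restricted (soft) stopping powers `beta_g = S_g - M_g`: the total
#' collisional/radiative stopping power minus the first moment of the
#' catastrophic cross section over the catastrophic transfer domain.  Both
#' are evaluated at the two boundaries of group `g` and averaged.
#'
#' @param material A [build_material()] object.
#' @param g Group index (1 = highest energy).
#' @param gs A [make_groups()] structure.
#' @param density_effect Apply the Sternheimer correction to the collisional
#'   part (default `TRUE`).
#' @return Named vector `c(beta_c, beta_b)` in MeV cm2/g.
#' @export
restricted_sp <- function(material, g, gs, density_effect = TRUE) {
  b <- gs$boundaries
  t <- .soft_threshold(gs, g)
  eb <- c(b[g], b[g + 1])
  bc <- mean(collision_sp(material, eb, density_effect) -
               vapply(eb, function(e) .cat_moment_coll(material, e, t),
                      numeric(1)))
  bb <- mean(radiative_sp(material, eb) -
               vapply(eb, function(e) .cat_moment_brems(material, e, t),
                      numeric(1)))
  if (bc < 0 || bb < 0) {
    stop(sprintf(
      "negative restricted stopping power in group %d (beta_c=%.3e, beta_b=%.3e): inconsistent threshold/grid",
      g, bc, bb), call. = FALSE)
  }
  c(beta_c = bc, beta_b = bb)
}

#' Restricted momentum transfer for one energy group
#'
#' First angular moment of the forward-elastic spike,
#' `alpha_g = sum_i n_i integral_{mu*}^{1} (1 - mu) dsigma_i/dmu dmu / rho`,
#' evaluated in closed form for the screened-Rutherford kernel at the two
#' group boundaries and averaged.  This is the angular diffusion coefficient
#' of the Fokker-Planck continuous-scattering operator; the default solver
#' path folds forward scattering into the extended transport correction
#' instead, but `alpha_g` is computed and stored for the alternative path.
#'
#' @inheritParams restricted_sp
#' @param mu_star Forward-elastic boundary cosine (default 0.999999).
#' @return `alpha_g` in cm2/g.
#' @export
momentum_transfer <- function(material, g, gs,
                              mu_star = bfp_constants$mu_forward) {
  b <- gs$boundaries
  eb <- c(b[g], b[g + 1])
  val <- vapply(eb, function(E) {
    tot <- 0
    for (sym in names(material$atom_density)) {
      Z <- material$elements[[sym]]$Z
      cc <- bfp_constants
      b2 <- .beta2_of(E)
      eta <- moliere_eta(E, Z)
      pref <- 2 * pi * cc$re^2 * Z^2 * (1 - b2) / b2^2   # cm^2
      u1 <- 2 * eta                  # at mu = 1
      u2 <- 2 * eta + (1 - mu_star)  # at mu = mu_star
      iv <- (log(u2) - log(u1)) + 2 * eta * (1 / u2 - 1 / u1)
      tot <- tot + material$atom_density[[sym]] * pref * iv
    }
    tot / material$rho
  }, numeric(1))
  mean(val)
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range: path length from integrating
#' the reciprocal total stopping power from the 1 keV cutoff up to `E0`.
#'
#' @param material A [build_material()] object.
#' @param E0 Initial kinetic energy (MeV).
#' @return Range in cm.
#' @export
csda_range <- function(material, E0) {
  lo <- bfp_constants$e_cutoff
  if (E0 <= lo) return(0)
  gl <- .gl_cache(96)
  u <- log(lo) + (gl$x + 1) / 2 * (log(E0) - log(lo))
  w <- gl$w / 2 * (log(E0) - log(lo))
  E <- exp(u)
  S <- collision_sp(material, E) + radiative_sp(material, E)
  sum(w * E / S) / material$rho
}

#' Stopping-power table for a material
#'
#' Tabulates total collisional and radiative mass stopping powers and the
#' Sternheimer density-effect correction on an energy grid (for CSV export
#' and plotting).
#'
#' @param material A [build_material()] object or catalogue name.
#' @param E Energy grid in MeV (default: 60 log-spaced points over the
#'   library range).
#' @return A data.frame with columns `E_MeV`, `S_col_MeVcm2g`,
#'   `S_rad_MeVcm2g`, `delta`.
#' @export
stopping_table <- function(material,
                           E = exp(seq(log(1e-3), log(20),
                                       length.out = 60))) {
  if (is.character(material)) material <- nist_material(material)
  data.frame(E_MeV = E,
             S_col_MeVcm2g = collision_sp(material, E),
             S_rad_MeVcm2g = radiative_sp(material, E),
             delta = .sternheimer_delta(material, E))
}
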