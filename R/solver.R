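## 1-D slab discrete-ordinates Boltzmann-Fokker-Planck solver.
##
## Groups are solved in a single top-down pass (no up-scatter); within each
## group, source iteration on the transport-corrected within-group scatter
## until the scalar-flux change falls below the inner tolerance.  The
## continuous slowing-down operator is discretised conservatively: removal
## beta_g/dE_g from group g reappears, direction-preserving, as a source in
## group g+1 with the same coefficient (step/upwind closure in energy).

#' Gauss-Legendre angular quadrature
#'
#' Discrete-ordinates direction cosines and weights on `[-1, 1]`.
#'
#' @param N Even number of directions, at least 2.
#' @return An object of class `bfp_quadrature` with `mu`, `w`, `N`;
#'   weights sum to 2 and directions come in symmetric pairs.
#' @export
make_quadrature <- function(N) {
  if (N %% 2 != 0 || N < 2) stop("S_N order must be even, >= 2", call. = FALSE)
  r <- pracma::gaussLegendre(N, -1, 1)
  structure(list(mu = r$x, w = r$w, N = N), class = "bfp_quadrature")
}

#' 1-D voxelised slab phantom
#'
#' @param edges Voxel edges in cm, strictly increasing, starting at the
#'   entry face (depth 0); voxels are half-open `[x_i, x_{i+1})`.
#' @param material Material name per voxel (length `nvox` or 1).
#' @param rho Optional density override per voxel (g/cm3); `NA` entries keep
#'   the material's default density.
#' @return An object of class `bfp_geometry`.
#' @export
slab_geometry <- function(edges, material, rho = NULL) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing",
                                  call. = FALSE)
  nvox <- length(edges) - 1
  if (nvox < 1) stop("at least one voxel required", call. = FALSE)
  material <- rep_len(material, nvox)
  if (!is.null(rho)) rho <- rep_len(rho, nvox)
  structure(list(edges = edges, dx = diff(edges),
                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                 material = material, rho = rho, nvox = nvox),
            class = "bfp_geometry")
}

#' Monoenergetic unidirectional boundary beam
#'
#' @param E0 Beam kinetic energy (MeV), in `(1 keV, 20 MeV]`.
#' @param Q Intensity (electrons/cm2/s), default 1.
#' @param T Irradiation time (s), default 1.
#' @return An object of class `bfp_source`.
#' @export
beam_source <- function(E0, Q = 1, T = 1) {
  if (E0 <= bfp_constants$e_cutoff || E0 > 20) {
    stop("E0 must lie in (1 keV, 20 MeV]", call. = FALSE)
  }
  if (Q <= 0) stop("beam intensity must be positive", call. = FALSE)
  structure(list(E0 = E0, Q = Q, T = T), class = "bfp_source")
}

## per-voxel density scale factors relative to the library materials
.vox_scale <- function(geom, lib) {
  vapply(seq_len(geom$nvox), function(v) {
    mm <- lib$mat[[geom$material[v]]]
    if (is.null(mm)) stop("material not in library: ", geom$material[v],
                          call. = FALSE)
    if (!is.null(geom$rho) && !is.na(geom$rho[v])) {
      geom$rho[v] / mm$material$rho
    } else 1
  }, numeric(1))
}

.vox_rho <- function(geom, lib) {
  vapply(seq_len(geom$nvox), function(v) {
    if (!is.null(geom$rho) && !is.na(geom$rho[v])) geom$rho[v]
    else lib$mat[[geom$material[v]]]$material$rho
  }, numeric(1))
}

#' Scattering source for one sink group
#'
#' Azimuthally-symmetric Legendre reconstruction of the Boltzmann in-scatter
#' source, `sum_x sum_l (2l+1)/2 P_l(mu_n) Sigma^x_{l,g'->g} phi_{l,g'}`,
#' for every quadrature direction and voxel.
#'
#' @param phi Flux moment array `(L+1) x N x nvox`.
#' @param lib A `bfp_library`.
#' @param geom A [slab_geometry()].
#' @param g Sink group.
#' @param quad A [make_quadrature()].
#' @return Matrix `nang x nvox`.
#' @export
scattering_source <- function(phi, lib, geom, g, quad) {
  L <- lib$L
  Q <- .moment_source(phi, lib, geom, g, seq_len(g))
  PL <- .legendre_all(quad$mu, L)
  cl <- (2 * (0:L) + 1) / 2
  t(PL) %*% (cl * Q)
}

## moment-space in-scatter contributions Q_l[v] from source groups `from`
.moment_source <- function(phi, lib, geom, g, from) {
  L <- lib$L
  nvox <- geom$nvox
  scale <- .vox_scale(lib = lib, geom = geom)
  Q <- matrix(0, L + 1, nvox)
  for (nm in unique(geom$material)) {
    cols <- which(geom$material == nm)
    S <- lib$mat[[nm]]$S
    for (l in 0:L) {
      sl <- S[l + 1, from, g]
      Q[l + 1, cols] <- Q[l + 1, cols] +
        (matrix(phi[l + 1, from, cols], nrow = length(from)) * sl) |>
        colSums()
    }
  }
  sweep(Q, 2, scale, "*")
}

#' Continuous slowing-down coupling coefficients
#'
#' Conservative multigroup discretisation of the continuous slowing-down
#' operator: with the step (upwind) closure the removal rate
#' `beta_{g+1/2}/dE_g` from group `g` equals, exactly, the
#' direction-preserving source into group `g+1`.  The restricted stopping
#' power is evaluated at the group's lower boundary, so the same
#' coefficient appears on both sides of the edge.
#'
#' @param lib A `bfp_library`.
#' @param geom A [slab_geometry()].
#' @return Matrix `N x nvox` of removal coefficients (1/cm).
#' @export
csd_coupling <- function(lib, geom) {
  gs <- lib$groups
  .beta_edge_vox(lib, geom) / gs$dE
}

## lower-edge restricted stopping power per (group, voxel), MeV/cm
.beta_edge_vox <- function(lib, geom) {
  gs <- lib$groups
  scale <- .vox_scale(geom, lib)
  out <- matrix(0, gs$N, geom$nvox)
  for (nm in unique(geom$material)) {
    cols <- which(geom$material == nm)
    out[, cols] <- lib$mat[[nm]]$beta_lo %o% scale[cols]
  }
  out
}

#' One-group transport sweep
#'
#' Diamond-difference spatial sweep over all directions for given total
#' removal cross section and per-direction emission density; vacuum
#' boundaries plus optional incoming angular flux.
#'
#' @param quad A [make_quadrature()].
#' @param sig Total removal cross section per voxel (1/cm).
#' @param dx Voxel widths (cm).
#' @param q Emission density, matrix `nang x nvox`.
#' @param inc_left,inc_right Incoming angular flux at the faces.
#' @return List with `psi` (`nang x nvox` cell-average angular flux),
#'   `out_left`, `out_right`, `nfix` (negative-flux fixup count).
#' @export
sweep_slab <- function(quad, sig, dx, q,
                       inc_left = numeric(quad$N),
                       inc_right = numeric(quad$N), fixup = TRUE) {
  .sweep_slab_cpp(quad$mu, quad$w, sig, dx, q, inc_left, inc_right, fixup)
}

#' Solve the multigroup Boltzmann-Fokker-Planck equation in slab geometry
#'
#' @param geom A [slab_geometry()].
#' @param lib A `bfp_library` whose top boundary equals the beam energy.
#' @param src A [beam_source()].
#' @param sn S_N quadrature order (even).
#' @param tol Inner-iteration convergence criterion on the relative
#'   scalar-flux change (default 1e-5).
#' @param max_inner Maximum source iterations per group.
#' @param beam `"boundary"` injects the beam as incoming angular flux on the
#'   most-forward quadrature direction (current-preserving magnitude);
#'   `"first-collision"` transports the uncollided beam analytically along
#'   the exact normal direction and feeds the S_N solve with its
#'   first-collision source.
#' @param fixup Apply the set-to-zero negative-flux fixup in the spatial
#'   sweep.  Off by default: the diamond-in-energy slowing-down closure
#'   carries a bounded, conservative oscillation at the spectral beam
#'   front, and rectifying it with the fixup creates particles; without
#'   the fixup the scheme is exactly conservative and the negatives cancel.
#'   `nfix` then counts (but does not alter) negative outflows.
#' @param quiet Suppress non-convergence warnings.
#' @return An object of class `bfp_flux`: flux moments `phi`
#'   (`(L+1) x N x nvox`), uncollided flux `psi_u` (`N x nvox`, zero for
#'   boundary injection), iteration counts, residuals, fixup counts,
#'   below-cutoff removal rate, and particle/energy leakage tallies.
#' @export
solve_bfp <- function(geom, lib, src, sn = 16, tol = 1e-5, max_inner = 200,
                      beam = c("first-collision", "boundary"),
                      energy_closure = c("diamond", "step"),
                      energy_theta = 0.5, fixup = FALSE,
                      quiet = FALSE) {
  beam <- match.arg(beam)
  energy_closure <- match.arg(energy_closure)
  th <- if (energy_closure == "step") 1 else energy_theta
  if (th < 0.5 || th > 1) stop("energy_theta must lie in [0.5, 1]",
                               call. = FALSE)
  gs <- lib$groups
  N <- gs$N
  L <- lib$L
  nvox <- geom$nvox
  if (abs(gs$boundaries[1] - src$E0) > 1e-9 * src$E0) {
    stop("library top boundary must equal the beam energy", call. = FALSE)
  }
  quad <- make_quadrature(sn)
  nang <- quad$N
  PL <- .legendre_all(quad$mu, L)              # (L+1) x nang
  cl <- (2 * (0:L) + 1) / 2
  scale <- .vox_scale(geom, lib)
  ## per-voxel group constants
  Sig_t <- matrix(0, N, nvox)
  Sgg <- array(0, c(L + 1, N, nvox))           # within-group transfer moments
  for (nm in unique(geom$material)) {
    cols <- which(geom$material == nm)
    mm <- lib$mat[[nm]]
    Sig_t[, cols] <- mm$Sig_t %o% scale[cols]
    for (l in 0:L) {
      diagS <- mm$S[l + 1, , ][cbind(1:N, 1:N)]
      Sgg[l + 1, , cols] <- diagS %o% scale[cols]
    }
  }
  blo <- .beta_edge_vox(lib, geom)             # edge beta, N x nvox [MeV/cm]
  csd <- blo / gs$dE
  ## uncollided beam (first-collision mode): exact continuous-energy march
  psi_u <- matrix(0, N, nvox)
  unc <- NULL
  if (beam == "first-collision") {
    bmean <- matrix(0, N, nvox)
    for (nm in unique(geom$material)) {
      cols <- which(geom$material == nm)
      bmean[, cols] <- (lib$mat[[nm]]$beta_c + lib$mat[[nm]]$beta_b) %o%
        scale[cols]
    }
    unc <- .uncollided_flux(geom, lib, src, Sig_t, bmean)
    psi_u <- unc$psi
  }
  phi <- array(0, c(L + 1, N, nvox))
  chi <- matrix(0, nang, nvox)    # spectral flux at the upper energy edge
  iters <- integer(N)
  resid <- numeric(N)
  nfix <- 0L
  nfix_E <- 0L
  leak_p <- 0; leak_E <- 0
  n_fwd <- which.max(quad$mu)
  for (g in seq_len(N)) {
    ## theta-weighted diamond closure in energy: psi_g/dE = th*chi_lower +
    ## (1-th)*chi_upper; th = 1/2 is diamond, th = 1 the step scheme
    sig_r <- Sig_t[g, ] + csd[g, ] / th
    ## fixed source: down-scatter from solved groups + slowing-down inflow
    ## through the upper energy edge
    q_fix <- matrix(0, nang, nvox)
    if (g > 1) {
      Qdown <- .moment_source(phi, lib, geom, g, seq_len(g - 1))
      q_fix <- t(PL) %*% (cl * Qdown)
      bsrc <- blo[g, ] * (1 - th) / th + blo[g - 1, ]
      q_fix <- q_fix + sweep(chi, 2, bsrc, "*")
    }
    if (beam == "first-collision") {
      ## first-collision source from the uncollided beam (phi_l,u = psi_u)
      Qu <- matrix(0, L + 1, nvox)
      for (nm in unique(geom$material)) {
        cols <- which(geom$material == nm)
        S <- lib$mat[[nm]]$S
        for (l in 0:L) {
          Qu[l + 1, cols] <- (S[l + 1, seq_len(g), g] %*%
            matrix(psi_u[seq_len(g), cols], nrow = g)) * scale[cols]
        }
      }
      q_fix <- q_fix + t(PL) %*% (cl * Qu)
      ## CSD feed from the uncollided flux of group g-1 enters the
      ## uncollided solve itself, not the collided one
    }
    inc_left <- numeric(nang)
    if (beam == "boundary" && g == 1) {
      inc_left[n_fwd] <- src$Q / (quad$w[n_fwd] * quad$mu[n_fwd])
    }
    phi_g <- matrix(0, L + 1, nvox)
    swp <- NULL
    for (it in seq_len(max_inner)) {
      q_in <- q_fix + t(PL) %*% (cl * (Sgg[, g, , drop = TRUE] * phi_g))
      swp <- .sweep_slab_cpp(quad$mu, quad$w, sig_r, geom$dx, q_in,
                             inc_left, numeric(nang), fixup)
      phi_new <- PL %*% sweep(swp$psi, 1, quad$w, "*")
      denom <- pmax(abs(phi_new[1, ]), max(abs(phi_new[1, ])) * 1e-12)
      err <- if (max(abs(phi_new[1, ])) == 0) 0 else
        max(abs(phi_new[1, ] - phi_g[1, ]) / denom)
      phi_g <- phi_new
      if (err <= tol) break
    }
    if (err > tol && !quiet) {
      warning(sprintf("group %d: inner iterations not converged (%.2e)",
                      g, err), call. = FALSE)
    }
    iters[g] <- it
    resid[g] <- err
    nfix <- nfix + swp$nfix
    phi[, g, ] <- phi_g
    ## energy-edge closure update: spectral flux at the group's lower edge
    chi <- (swp$psi / gs$dE[g] - (1 - th) * chi) / th
    nfix_E <- nfix_E + sum(chi < 0)
    ## leakage tallies (collided)
    pos <- quad$mu > 0
    jr <- sum(quad$w[pos] * quad$mu[pos] * swp$out_right[pos])
    jl <- sum(quad$w[!pos] * abs(quad$mu[!pos]) * swp$out_left[!pos])
    leak_p <- leak_p + jr + jl
    leak_E <- leak_E + gs$Eavg[g] * (jr + jl)
  }
  ## electrons/s/cm3 crossing the 1 keV cutoff edge
  below <- blo[N, ] * as.numeric(quad$w %*% chi)
  if (beam == "first-collision") {
    ## add the uncollided component to the flux moments (all P_l(1) = 1)
    for (l in 0:L) phi[l + 1, , ] <- phi[l + 1, , ] + psi_u
    below <- below + unc$below
    leak_p <- leak_p + unc$leak_p
    leak_E <- leak_E + unc$leak_E
  }
  structure(list(phi = phi, psi_u = psi_u, iterations = iters,
                 residuals = resid, nfix = nfix, nfix_energy = nfix_E,
                 tol = tol, energy_closure = energy_closure,
                 below_cutoff_rate = below,
                 leak_particles = leak_p, leak_energy = leak_E,
                 quad = quad, beam = beam, geom = geom, src = src),
            class = "bfp_flux")
}

## Uncollided beam transport along the exact normal direction: the beam
## slows continuously (piecewise group-mean restricted stopping power) and
## attenuates with the catastrophic total; energy and position are marched
## jointly, so the uncollided component carries no multigroup energy
## diffusion at all.  Returns per-(group, voxel) track-length flux, the
## below-cutoff stopping rate per voxel, and leakage tallies.
.uncollided_flux <- function(geom, lib, src, Sig_t, bmean) {
  gs <- lib$groups
  N <- gs$N
  nvox <- geom$nvox
  b <- gs$boundaries
  psi <- matrix(0, N, nvox)
  below <- numeric(nvox)
  w <- src$Q                      # surviving current (per cm2)
  E <- src$E0
  g <- 1L; v <- 1L; x <- 0
  leak_p <- 0; leak_E <- 0
  while (v <= nvox && g <= N && w > 1e-300) {
    beta <- bmean[g, v]
    sig <- Sig_t[g, v]
    s_vox <- geom$edges[v + 1] - x
    s_grp <- (E - b[g + 1]) / beta
    s <- min(s_vox, s_grp)
    ## attenuation-averaged track length density in this (group, voxel)
    watt <- if (sig * s > 1e-12) w * (1 - exp(-sig * s)) / (sig * s) else w
    psi[g, v] <- psi[g, v] + watt * s / geom$dx[v]
    w <- w * exp(-sig * s)
    x <- x + s
    E <- E - beta * s
    if (s_grp <= s_vox) {
      g <- g + 1L
      if (g > N) below[v] <- below[v] + w / geom$dx[v]
    }
    if (s_vox <= s_grp) v <- v + 1L
  }
  if (v > nvox && g <= N) {       # beam escapes the far face
    leak_p <- w
    leak_E <- w * E
  }
  list(psi = psi, below = below, leak_p = leak_p, leak_E = leak_E)
}

#' @export
print.bfp_flux <- function(x, ...) {
  cat(sprintf(
    "<bfp_flux> %d groups x %d voxels, beam=%s, max residual %.2e, fixups %d\n",
    dim(x$phi)[2], dim(x$phi)[3], x$beam, max(x$residuals), x$nfix))
  invisible(x)
}
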