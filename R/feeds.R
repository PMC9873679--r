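## Group-to-group feed functions: the per-incident-energy kernels whose
## group averages (flat within-group flux guess) give the multigroup
## Legendre transfer matrices and catastrophic totals.
##
## Conventions: group 1 = highest energy.  "Catastrophic" = down-scatter
## into non-adjacent groups; the soft remainder lives in the restricted
## stopping power.  Sink index N+1 is the below-cutoff bucket (energy
## deposited locally).  All tables are macroscopic (1/cm * MeV^m).

## split [lo, hi] at group boundaries and (additionally) in log-equal
## subpanels so no panel spans more than a factor `ratio`; returns nodes,
## weights and the sink-group index of each node
.sink_quad <- function(gs, lo, hi, nq = 16, ratio = 2.0) {
  b <- gs$boundaries
  cuts <- b[b > lo & b < hi]
  edges <- sort(unique(c(lo, hi, cuts)))
  ## log-subdivide wide panels (integrands carry 1/W^2-type steepness)
  full <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; bb <- edges[i + 1]
    ns <- max(1L, ceiling(log(bb / a) / log(ratio)))
    full <- c(full, exp(seq(log(a), log(bb), length.out = ns + 1)))
  }
  edges <- sort(unique(full))
  gl <- .gl_cache(nq)
  n_pan <- length(edges) - 1
  a <- edges[-(n_pan + 1)]; bb <- edges[-1]
  halfw <- (bb - a) / 2
  x <- as.vector(outer(gl$x, halfw) + rep((a + bb) / 2, each = nq))
  w <- as.vector(outer(gl$w, halfw))
  list(x = x, w = w, sink = .group_of(gs, x))
}

## flat-flux source-energy nodes for group g: composite 4-point
## Gauss-Lobatto panels, split where the transfer-domain endpoints cross a
## sink-group boundary (kinks of the feed function in E): E = 2*b_j (the
## E/2 split point) and E = t_g + b_j (the catastrophic threshold).
.src_nodes <- function(gs, g, n = 4) {
  a <- gs$boundaries[g + 1]; b <- gs$boundaries[g]
  t <- .soft_threshold(gs, g)
  ## kink panels matter only for wide (coarse-structure) groups; for fine
  ## grids the feed function is smooth across the group and plain Lobatto
  ## nodes integrate it to quadrature accuracy.  Wide groups additionally
  ## get higher-order nodes and log-capped panels so coarse toy structures
  ## reach ~1e-7 relative accuracy.
  wide <- b / a - 1 > 0.2
  if (wide) {
    n <- max(n, 6)
    kinks <- c(2 * gs$boundaries, t + gs$boundaries,
               t + bfp_constants$e_cutoff, 2 * bfp_constants$e_cutoff)
    kinks <- kinks[kinks > a & kinks < b]
  } else {
    kinks <- numeric(0)
  }
  lob <- gauss_lobatto(n)
  edges <- sort(unique(c(a, b, kinks)))
  if (wide) {
    full <- numeric(0)
    for (i in seq_len(length(edges) - 1)) {
      ns <- max(1L, ceiling(log(edges[i + 1] / edges[i]) / log(1.1)))
      full <- c(full, exp(seq(log(edges[i]), log(edges[i + 1]),
                              length.out = ns + 1)))
    }
    edges <- sort(unique(full))
  }
  E <- w <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    E <- c(E, (lob$x + 1) / 2 * (hi - lo) + lo)
    w <- c(w, lob$w / 2 * (hi - lo) / (b - a))
  }
  list(E = E, w = w)
}

#' Ionization (Moller) feed table
#'
#' Group-to-group catastrophic ionization transfer moments in the
#' free-electron Moller mode.  Each catastrophic event feeds two electrons:
#' the principal scattered electron (energies above `E/2`) and the delta ray
#' (below `E/2`); their angular kernels are Dirac distributions at the
#' two-body kinematics cosine, so the Legendre moments are evaluated
#' analytically as `P_l(mu(E, E'))` inside the energy integrals.
#'
#' @param material A [build_material()] object.
#' @param gs A [make_groups()] structure.
#' @param L Maximum Legendre order (Gauss-Lobatto panels stored up to 10).
#' @return A `bfp_feed` list: arrays `F0_ee`, `F0_ed`, `F1_ee`, `F1_ed` of
#'   dimension `(L+1) x N x (N+1)` (source group, sink group; sink `N+1` is
#'   the below-cutoff bucket) in 1/cm (m=0) and MeV/cm (m=1), plus the
#'   catastrophic total `T` (1/cm).
#' @export
ionization_feed <- function(material, gs, L = 9) {
  N <- gs$N
  ne <- material$electron_density * bfp_constants$barn   # barns -> 1/cm
  F0_ee <- F0_ed <- F1_ee <- F1_ed <- array(0, c(L + 1, N, N + 1))
  for (g in seq_len(N)) {
    t <- .soft_threshold(gs, g)
    src <- .src_nodes(gs, g)
    for (i in seq_along(src$E)) {
      E <- src$E[i]; sw <- src$w[i]
      ## minimum catastrophic transfer floored at the 1 keV cutoff: a delta
      ## ray below 1 keV cannot be tracked, so those losses stay soft
      Wc <- max(E - t, bfp_constants$e_cutoff)
      if (Wc >= E / 2) next
      ## delta-ray branch: sinks at W in [Wc, E/2]
      qd <- .sink_quad(gs, Wc, E / 2)
      base <- sw * ne * qd$w * .moller_dcs_raw(E, qd$x)
      PLt <- t(.legendre_all(moller_mu(E, qd$x), L))   # npts x (L+1)
      a0 <- rowsum(base * PLt, qd$sink)
      a1 <- rowsum(base * qd$x * PLt, qd$sink)
      ids <- as.integer(rownames(a0))
      F0_ed[, g, ids] <- F0_ed[, g, ids] + t(a0)
      F1_ed[, g, ids] <- F1_ed[, g, ids] + t(a1)
      ## primary branch: sinks at E' in [E/2, E - Wc]; same kernel at
      ## W = E - E' (mirrored domain of the delta branch)
      qp <- .sink_quad(gs, E / 2, E - Wc)
      basep <- sw * ne * qp$w * .moller_dcs_raw(E, pmax(E - qp$x, 1e-15))
      PLp <- t(.legendre_all(moller_mu(E, qp$x), L))
      b0 <- rowsum(basep * PLp, qp$sink)
      b1 <- rowsum(basep * qp$x * PLp, qp$sink)
      idp <- as.integer(rownames(b0))
      F0_ee[, g, idp] <- F0_ee[, g, idp] + t(b0)
      F1_ee[, g, idp] <- F1_ee[, g, idp] + t(b1)
    }
  }
  structure(list(x = "c", L = L,
                 F0_ee = F0_ee, F0_ed = F0_ed,
                 F1_ee = F1_ee, F1_ed = F1_ed,
                 T = rowSums(F0_ee[1, , ])),
            class = "bfp_feed")
}

## sum values v into a length-(N+1) sink vector
.accum_sink <- function(v, sink, N) {
  out <- numeric(N + 1)
  s <- rowsum(v, sink)
  out[as.integer(rownames(s))] <- s
  out
}

#' Bremsstrahlung feed table
#'
#' Catastrophic bremsstrahlung transfers: the electron is fed into the group
#' of its residual energy `E - k` with no angular deflection (forward Dirac
#' kernel, so all Legendre moments equal the l = 0 entry and are stored
#' once), and the photon is discarded; its energy is accumulated in the
#' radiated moment `R`.  Photon energies below the 1 keV low-frequency
#' cutoff are excluded, as is the high-frequency tip where the electron
#' residual falls below 1 keV.
#'
#' @inheritParams ionization_feed
#' @return A `bfp_feed` list with `F0`, `F1` (`N x (N+1)`), catastrophic
#'   total `T` (1/cm) and radiated-energy moment `R` (MeV/cm).
#' @export
brems_feed <- function(material, gs) {
  N <- gs$N
  F0 <- F1 <- matrix(0, N, N + 1)
  R <- numeric(N)
  ad <- material$atom_density * bfp_constants$barn
  Zs <- vapply(material$elements, `[[`, numeric(1), "Z")
  emin <- bfp_constants$e_min_brems
  ecut <- bfp_constants$e_cutoff
  for (g in seq_len(N)) {
    t <- .soft_threshold(gs, g)
    src <- .src_nodes(gs, g)
    for (i in seq_along(src$E)) {
      E <- src$E[i]; sw <- src$w[i]
      kc <- max(E - t, emin)
      kmax <- E - ecut
      if (kc >= kmax) next
      ## integrate over electron residual energy E' = E - k in [ecut, t']
      lo <- E - kmax  # = ecut
      hi <- E - kc
      q <- .sink_quad(gs, lo, hi)
      k <- E - q$x
      sig <- numeric(length(k))
      for (j in seq_along(ad)) {
        sig <- sig + ad[[j]] * brems_dcs(E, k, Zs[[j]])
      }
      base <- sw * q$w * sig
      F0[g, ] <- F0[g, ] + .accum_sink(base, q$sink, N)
      F1[g, ] <- F1[g, ] + .accum_sink(base * q$x, q$sink, N)
      R[g] <- R[g] + sum(base * k)
    }
  }
  structure(list(x = "b", L = 0, F0 = F0, F1 = F1,
                 T = rowSums(F0), R = R,
                 forward_dirac = TRUE),
            class = "bfp_feed")
}

#' Elastic feed table (within-group)
#'
#' Legendre moments of the large-angle elastic kernel (screened Mott) over
#' `mu` in `[-1, 0.999999]`, by high-order quadrature in a logarithmic
#' variable that resolves the screening peak; the scattered electron keeps
#' its energy, so transfers are strictly within-group.  The extended
#' transport correction subtracts the order-`L` moment from every moment
#' (and from the total), making the forward-peaked kernel compatible with a
#' low-order Legendre expansion.
#'
#' @inheritParams ionization_feed
#' @param mott Mott-ratio switch passed to [elastic_dcs()].
#' @return A `bfp_feed` list with `F` (`(L+1) x N`, uncorrected moments),
#'   `F_corr` (transport-corrected), `T` (uncorrected total, 1/cm) and
#'   `T_corr` (1/cm).
#' @export
elastic_feed <- function(material, gs, L = 9, mott = "auto") {
  stopifnot(L >= 1)
  N <- gs$N
  Fm <- matrix(0, L + 1, N)
  ad <- material$atom_density * bfp_constants$barn
  Zs <- vapply(material$elements, `[[`, numeric(1), "Z")
  gl <- .gl_cache(128)
  mu_star <- bfp_constants$mu_forward
  for (g in seq_len(N)) {
    src <- .src_nodes(gs, g)
    for (i in seq_along(src$E)) {
      E <- src$E[i]; sw <- src$w[i]
      for (j in seq_along(ad)) {
        eta <- moliere_eta(E, Zs[[j]])
        a <- 1 + 2 * eta
        ## v = log(a - mu), mu in [-1, mu_star]
        v1 <- log(a - mu_star); v2 <- log(a + 1)
        v <- (gl$x + 1) / 2 * (v2 - v1) + v1
        wv <- gl$w / 2 * (v2 - v1)
        u <- exp(v)            # a - mu
        mu <- a - u
        sig <- elastic_dcs(E, mu, Zs[[j]], mott = mott)
        PL <- .legendre_all(mu, L)
        Fm[, g] <- Fm[, g] + sw * ad[[j]] * (PL %*% (wv * u * sig))
      }
    }
  }
  Fc <- sweep(Fm, 2, Fm[L + 1, ], "-")
  structure(list(x = "e", L = L, F = Fm, F_corr = Fc,
                 T = Fm[1, ], T_corr = Fc[1, ]),
            class = "bfp_feed")
}

#' Auger relaxation feed table
#'
#' Isotropic Auger/Coster-Kronig electron production following inner-shell
#' impact ionization: for each subshell `k` with radiationless transition
#' efficiencies `eta_kj`, the production cross section
#' `sigma_k(E_g) eta_kj` is deposited in the group containing the emitted
#' electron energy, with the destination-group midpoint energy used for the
#' energy bookkeeping.  Moments of order l >= 1 are identically zero, and
#' the production does not contribute to the total reaction rate.  Subshell
#' ionization cross sections are estimated from the Moller kernel with the
#' binding energy as threshold.  Transitions with emitted energy below the
#' 1 keV cutoff are dropped (their energy stays local) and counted in
#' `n_subcutoff`.
#'
#' @inheritParams ionization_feed
#' @return A `bfp_feed` list with `F0` (`N x N`, 1/cm), `F1` (MeV/cm),
#'   production total `P` and `n_subcutoff`.
#' @export
relaxation_feed <- function(material, gs) {
  N <- gs$N
  F0 <- F1 <- matrix(0, N, N)
  nsub <- 0L
  occ <- c(K = 2, L1 = 2, L2 = 2, L3 = 4, M1 = 2)
  for (g in seq_len(N)) {
    E <- gs$mid[g]
    for (sym in names(material$atom_density)) {
      el <- material$elements[[sym]]
      nd <- material$atom_density[[sym]] * bfp_constants$barn
      for (sh in el$shells) {
        if (length(sh$transitions) == 0) next
        U <- sh$be
        if (U >= E / 2) next
        sk <- .shell_ion_xs(E, U, occ[[sh$label]])
        for (tr in sh$transitions) {
          if (tr$e < bfp_constants$e_cutoff) { nsub <- nsub + 1L; next }
          gj <- .group_of(gs, tr$e)
          if (gj > N) { nsub <- nsub + 1L; next }
          F0[g, gj] <- F0[g, gj] + nd * sk * tr$eta
          F1[g, gj] <- F1[g, gj] + nd * sk * tr$eta * gs$mid[gj]
        }
      }
    }
  }
  structure(list(x = "a", L = 0, F0 = F0, F1 = F1,
                 P = rowSums(F0), n_subcutoff = nsub),
            class = "bfp_feed")
}

## Moller-estimate impact ionization cross section of a subshell with
## binding energy U and occupancy nocc (barns per atom)
.shell_ion_xs <- function(E, U, nocc) {
  if (U >= E / 2) return(0)
  gl <- .gl_cache(32)
  u <- log(U) + (gl$x + 1) / 2 * (log(E / 2) - log(U))
  w <- gl$w / 2 * (log(E / 2) - log(U))
  W <- exp(u)
  nocc * sum(w * W * .moller_dcs_raw(E, W))
}
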