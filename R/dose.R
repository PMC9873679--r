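## Dose tally: deposition-cross-section route (the production path) and the
## direct route assembled from totals, transfer first moments and restricted
## stopping powers (algebraically equivalent; kept as a cross-check).

#' Depth-dose profile from a converged flux solution
#'
#' Folds the energy deposition cross sections with the scalar flux and adds
#' the below-cutoff term: electrons removed through the 1 keV cutoff
#' deposit their residual energy locally.  The `"direct"` route reassembles
#' the same dose from the catastrophic totals, the transfer first moments,
#' the radiated moment and the restricted stopping powers.
#'
#' @param sol A [solve_bfp()] solution.
#' @param lib The `bfp_library` used for the solve.
#' @param geom The [slab_geometry()].
#' @param src The [beam_source()].
#' @param route `"deposition"` (default) or `"direct"`.
#' @return An object of class `bfp_dose`: depth midpoints (cm), dose in
#'   MeV/g per source electron/cm2 and in Gy (using `Q*T`), plus the
#'   radiated-energy density per voxel.
#' @export
dose_profile <- function(sol, lib, geom, src,
                         route = c("deposition", "direct")) {
  route <- match.arg(route)
  gs <- lib$groups
  N <- gs$N
  nvox <- geom$nvox
  scale <- .vox_scale(geom, lib)
  rho <- .vox_rho(geom, lib)
  phi0 <- matrix(sol$phi[1, , ], nrow = N)      # N x nvox scalar flux
  dep <- rad <- numeric(nvox)
  for (nm in unique(geom$material)) {
    cols <- which(geom$material == nm)
    mm <- lib$mat[[nm]]
    ev <- switch(route,
      deposition = mm$E_dep,
      direct = gs$Eavg * (mm$T_c + mm$T_b) - mm$f1_groups - mm$R +
        mm$beta_c + mm$beta_b - mm$A1)
    dep[cols] <- colSums(phi0[, cols, drop = FALSE] * ev) * scale[cols]
    rad[cols] <- colSums(phi0[, cols, drop = FALSE] * mm$R) * scale[cols]
  }
  ## electrons slowing past the cutoff deposit the cutoff energy locally
  dep <- dep + sol$below_cutoff_rate * gs$boundaries[N + 1]
  mev_per_g <- dep / rho                        # per unit source current
  structure(list(depth = geom$mid, dx = geom$dx,
                 dose = mev_per_g,
                 dose_gy = mev_per_g * src$T * bfp_constants$mev_g_to_gy,
                 radiated = rad, rho = rho, route = route,
                 stderr = NULL),
            class = "bfp_dose")
}

#' @export
print.bfp_dose <- function(x, ...) {
  cat(sprintf("<bfp_dose> %d voxels, depth [0, %.4g] cm, max %.4g MeV/g%s\n",
              length(x$depth), max(x$depth + x$dx / 2), max(x$dose),
              if (is.null(x$stderr)) "" else " (MC)"))
  invisible(x)
}

#' @export
plot.bfp_dose <- function(x, ..., add = FALSE, col = 1, type = "l",
                          xlab = "depth [cm]", ylab = "dose [MeV/g]") {
  if (add) {
    graphics::lines(x$depth, x$dose, col = col, ...)
  } else {
    plot(x$depth, x$dose, type = type, col = col, xlab = xlab, ylab = ylab,
         ...)
  }
  invisible(x)
}

#' @export
as.data.frame.bfp_dose <- function(x, ...) {
  d <- data.frame(depth_cm = x$depth, dose_MeV_per_g = x$dose,
                  dose_Gy = x$dose_gy)
  if (!is.null(x$stderr)) d$stderr_MeV_per_g <- x$stderr
  d
}

## energy balance summary for a deterministic solve (per source electron)
.energy_balance_det <- function(sol, lib, geom, src, dose = NULL) {
  if (is.null(dose)) dose <- dose_profile(sol, lib, geom, src)
  deposited <- sum(dose$dose * dose$rho * geom$dx)
  radiated <- sum(dose$radiated * geom$dx)
  leaked <- sol$leak_energy
  injected <- src$Q * src$E0
  c(deposited = deposited, radiated = radiated, leaked = leaked,
    injected = injected,
    closure = (deposited + radiated + leaked) / injected)
}
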