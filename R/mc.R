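## Monte Carlo verification reference: configuration, driver and energy
## ledger.  The sampler shares the multigroup library's catastrophic totals
## and restricted stopping powers with the deterministic solver, but its
## angular and spatial treatment is continuous and independent of the
## Legendre/discrete-ordinates machinery it verifies.

#' Monte Carlo run configuration
#'
#' @param histories Number of primary histories (>= 1).
#' @param seed RNG seed (integer); runs are bitwise reproducible at fixed
#'   seed.
#' @param batches Number of statistical batches (>= 2 for error bars).
#' @param elastic Elastic sampling mode: `"analytic-dsc"` (default) or
#'   `"off"`.
#' @param ionization,brems Enable the catastrophic ionization /
#'   bremsstrahlung channels (both default `TRUE`; disabling every discrete
#'   channel gives pure continuous-slowing-down transport).
#' @param record_first Record the depth of the first catastrophic event for
#'   up to this many histories (0 = off), for interaction-free-path checks.
#' @return An object of class `bfp_mc_config`.
#' @export
mc_config <- function(histories, seed = 1L, batches = 20L,
                      elastic = c("analytic-dsc", "off"),
                      ionization = TRUE, brems = TRUE,
                      record_first = 0L) {
  elastic <- match.arg(elastic)
  if (histories < 1) stop("histories must be >= 1", call. = FALSE)
  if (batches < 2) stop("at least 2 batches needed for error bars",
                        call. = FALSE)
  structure(list(histories = as.integer(histories), seed = as.integer(seed),
                 batches = as.integer(batches), elastic = elastic,
                 ionization = isTRUE(ionization), brems = isTRUE(brems),
                 record_first = as.integer(record_first)),
            class = "bfp_mc_config")
}

## element-selection tables for the MC sub-sampling
.mc_matdata <- function(lib) {
  gs <- lib$groups
  N <- gs$N
  lapply(lib$mat, function(mm) {
    m <- mm$material
    Zs <- vapply(m$elements, `[[`, numeric(1), "Z")
    nd <- as.numeric(m$atom_density)
    nel <- length(Zs)
    ## elastic element selection: screened-Rutherford totals at midpoints
    elw <- matrix(0, N, nel)
    for (j in seq_len(nel)) {
      elw[, j] <- nd[j] * vapply(gs$mid, function(E) {
        .elastic_sr_integral(E, Zs[j], -1, bfp_constants$mu_forward)
      }, numeric(1))
    }
    el_cdf <- t(apply(elw, 1, function(r) cumsum(r) / sum(r)))
    if (nel == 1) el_cdf <- matrix(1, N, 1)
    brw <- nd * Zs * (Zs + 1)
    list(sig_ion = mm$T_c, sig_brems = mm$T_b, sig_el = mm$T_e,
         beta = mm$beta_c + mm$beta_b,
         Z = Zs, br_cdf = cumsum(brw) / sum(brw),
         el_cdf = as.numeric(t(el_cdf)))
  })
}

#' Run the Monte Carlo reference calculation
#'
#' Transports `histories` primary electrons from the boundary beam through
#' the slab phantom, tallying energy deposition per voxel with batch-based
#' standard errors and an exact energy ledger (deposited, radiated, leaked,
#' below-cutoff; the four components sum to `histories * E0` to floating
#' round-off).
#'
#' @param cfg An [mc_config()].
#' @param geom A [slab_geometry()].
#' @param lib A `bfp_library` covering the beam energy.
#' @param src A [beam_source()].
#' @return A `bfp_dose` with per-voxel standard errors; the ledger and
#'   first-event depths are attached as attributes `ledger` and
#'   `first_depth`.
#' @export
run_mc <- function(cfg, geom, lib, src) {
  stopifnot(inherits(cfg, "bfp_mc_config"))
  gs <- lib$groups
  if (abs(gs$boundaries[1] - src$E0) > 1e-9 * src$E0) {
    stop("library top boundary must equal the beam energy", call. = FALSE)
  }
  if (geom$edges[length(geom$edges)] <= geom$edges[1]) {
    stop("zero-range geometry", call. = FALSE)
  }
  mat_id <- match(geom$material, names(lib$mat)) - 1L
  if (anyNA(mat_id)) stop("geometry material missing from library",
                          call. = FALSE)
  scale <- .vox_scale(geom, lib)
  rho <- .vox_rho(geom, lib)
  set.seed(cfg$seed)
  res <- .run_mc_cpp(gs$boundaries, geom$edges, mat_id, scale,
                     .mc_matdata(lib), src$E0, 1.0,
                     cfg$histories, cfg$batches,
                     cfg$ionization, cfg$brems,
                     cfg$elastic == "analytic-dsc",
                     identical(lib$mott, "auto") || isTRUE(lib$mott),
                     cfg$record_first)
  mass <- rho * geom$dx                       # g/cm2 per voxel
  nb <- cfg$batches
  per_b <- res$dep_batch / (cfg$histories / nb)  # MeV per history, per batch
  mean_b <- colMeans(per_b)
  se_b <- apply(per_b, 2, stats::sd) / sqrt(nb)
  dose <- mean_b / mass
  stderr <- se_b / mass
  out <- structure(list(depth = geom$mid, dx = geom$dx, dose = dose,
                        dose_gy = dose * src$Q * src$T *
                          bfp_constants$mev_g_to_gy,
                        radiated = NULL, rho = rho, route = "mc",
                        stderr = stderr),
                   class = "bfp_dose")
  attr(out, "ledger") <- c(deposited = res$deposited,
                           radiated = res$radiated,
                           leaked = res$leaked,
                           below_cutoff = res$below_cutoff,
                           injected = cfg$histories * src$E0)
  if (cfg$record_first > 0) {
    attr(out, "first_depth") <- res$first_depth[seq_len(res$n_first)]
  }
  attr(out, "config") <- cfg
  out
}

#' Energy ledger of a Monte Carlo run
#'
#' @param run A [run_mc()] result.
#' @return Named vector `(deposited, radiated, leaked, below_cutoff,
#'   injected)` in MeV; the first four sum to `injected` exactly (floating
#'   round-off).
#' @export
mc_energy_ledger <- function(run) {
  led <- attr(run, "ledger")
  if (is.null(led)) stop("not a completed Monte Carlo run", call. = FALSE)
  led
}
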