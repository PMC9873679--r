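## Benchmark phantoms, beam-range sizing, grid unification and the
## 2%-of-maximum-dose agreement statistics.

#' Beam range in a material
#'
#' CSDA range of the beam: reciprocal total stopping power integrated from
#' the 1 keV cutoff to the beam energy, divided by density.
#'
#' @param material A [build_material()] object or catalogue name.
#' @param E0 Beam energy (MeV).
#' @return Range in cm.
#' @export
beam_range <- function(material, E0) {
  if (is.character(material)) material <- nist_material(material)
  csda_range(material, E0)
}

.phantom_defs <- list(
  water = list(materials = "water", fractions = 1),
  thorax = list(
    materials = c("water", "cortical bone", "lung", "water"),
    fractions = c(0.13, 0.07, 0.22, 0.58)),
  iort = list(
    materials = c("tumor", "aluminium", "steel", "breast tissue"),
    fractions = c(0.40, 0.40, 0.15, 0.05)),
  hh = list(
    materials = c("adipose", "muscle", "cortical bone", "muscle", "lung",
                  "muscle", "cortical bone", "adipose", "cortical bone",
                  "muscle", "adipose"),
    fractions = rep(1 / 11, 11))
)

#' Benchmark phantom specifications
#'
#' Ordered slabs as fractions of the incident beam's range: `water` (single
#' slab), `thorax` (water 13%, bone 7%, lung 22%, water 58%), `iort`
#' (tumor 40%, aluminium 40%, steel 15%, breast tissue 5%) and `hh`, the
#' 11-slab high-heterogeneity patient-like stack
#' (adipose/muscle/bone/muscle/lung/muscle/bone/adipose/bone/muscle/adipose,
#' equal fractions).  The total depth is the CSDA range of the beam in the
#' first slab's material.
#'
#' @param name One of `"water"`, `"thorax"`, `"iort"`, `"hh"`, or the path
#'   of a YAML file with fields `materials` and `fractions`.
#' @param E0 Beam energy (MeV).
#' @param nvox Number of voxels.
#' @return An object of class `bfp_phantom`.
#' @export
make_phantom <- function(name, E0 = 1.0, nvox = 200) {
  if (name %in% names(.phantom_defs)) {
    def <- .phantom_defs[[name]]
  } else if (file.exists(name)) {
    y <- yaml::read_yaml(name)
    def <- list(materials = as.character(y$materials),
                fractions = as.numeric(y$fractions))
    name <- if (is.null(y$name)) basename(name) else y$name
  } else {
    stop("unknown phantom: ", name, call. = FALSE)
  }
  if (abs(sum(def$fractions) - 1) > 1e-9) {
    stop("phantom slab fractions must sum to 1", call. = FALSE)
  }
  for (m in def$materials) nist_material(m)   # validate catalogue names
  structure(list(name = name, materials = def$materials,
                 fractions = def$fractions, E0 = E0, nvox = nvox),
            class = "bfp_phantom")
}

#' Voxelised geometry of a phantom
#'
#' @param phantom A [make_phantom()] spec.
#' @return A [slab_geometry()] with (approximately) equal-width voxels;
#'   slab interfaces are snapped to voxel edges.
#' @export
phantom_geometry <- function(phantom) {
  depth <- beam_range(phantom$materials[1], phantom$E0)
  edges <- seq(0, depth, length.out = phantom$nvox + 1)
  cum <- cumsum(phantom$fractions) * depth
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  slab <- findInterval(mid, c(0, cum), rightmost.closed = TRUE)
  slab <- pmin(pmax(slab, 1L), length(phantom$materials))
  geom <- slab_geometry(edges, phantom$materials[slab])
  geom$slab <- slab
  geom
}

#' Piecewise cubic Hermite interpolation
#'
#' Hermite interpolant with node slopes from local 4-point cubic (Lagrange)
#' differentiation, which reproduces cubic polynomials exactly.  Used for
#' unifying dose grids before comparison.
#'
#' @param x,y Sample points (x strictly increasing) and values.
#' @param xout Evaluation points.
#' @return Interpolated values.
#' @export
cubic_hermite <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n, all(diff(x) > 0))
  if (n < 4) {
    return(stats::spline(x, y, xout = xout, method = "natural")$y)
  }
  ## slope at node i from the cubic through a 4-point stencil around i
  d <- numeric(n)
  for (i in seq_len(n)) {
    j0 <- min(max(i - 2, 0), n - 4)
    idx <- j0 + 1:4
    xi <- x[idx]; yi <- y[idx]
    s <- 0
    for (k in 1:4) {
      ## derivative of the k-th Lagrange basis at x[i]
      others <- xi[-k]
      dk <- 0
      for (q in 1:3) {
        dk <- dk + prod(x[i] - others[-q])
      }
      s <- s + yi[k] * dk / prod(xi[k] - others)
    }
    d[i] <- s
  }
  iv <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  h <- x[iv + 1] - x[iv]
  t <- (xout - x[iv]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[iv] + h10 * h * d[iv] + h01 * y[iv + 1] + h11 * h * d[iv + 1]
}

#' Compare two depth-dose profiles
#'
#' Interpolates profile `b` onto profile `a`'s grid by piecewise cubic
#' Hermite interpolation and evaluates the relative error normalised to the
#' maximum of `a` (in percent), with the fraction of voxels meeting the
#' agreement criterion, overall and per material.
#'
#' @param dose_a,dose_b `bfp_dose` profiles with overlapping depth ranges
#'   (`a` is the reference grid).
#' @param criterion_pct Agreement criterion as percent of the maximum dose
#'   (default 2).
#' @param materials Optional material name per voxel of `a`'s grid for the
#'   per-material breakdown.
#' @param exclude_entrance Drop the entrance voxel from the statistics.
#' @return An object of class `bfp_comparison`: `depth`, `err_pct`,
#'   `mean_abs_err`, `max_abs_err`, `frac_within`, `per_material`.
#' @export
compare_doses <- function(dose_a, dose_b, criterion_pct = 2.0,
                          materials = NULL, exclude_entrance = FALSE) {
  lo <- max(min(dose_a$depth), min(dose_b$depth))
  hi <- min(max(dose_a$depth), max(dose_b$depth))
  if (lo >= hi) stop("non-overlapping depth grids", call. = FALSE)
  keep <- which(dose_a$depth >= lo & dose_a$depth <= hi)
  if (exclude_entrance) keep <- setdiff(keep, 1L)
  xa <- dose_a$depth[keep]
  a <- dose_a$dose[keep]
  b <- cubic_hermite(dose_b$depth, dose_b$dose, xa)
  dmax <- max(dose_a$dose)
  err <- (a - b) / dmax * 100
  within <- abs(err) < criterion_pct
  per_mat <- NULL
  if (!is.null(materials)) {
    mm <- materials[keep]
    per_mat <- do.call(rbind, lapply(split(seq_along(err), mm), function(ii) {
      data.frame(n = length(ii),
                 mean_abs_err = mean(abs(err[ii])),
                 frac_within = mean(within[ii]))
    }))
    per_mat <- cbind(material = rownames(per_mat), per_mat)
    rownames(per_mat) <- NULL
  }
  structure(list(depth = xa, err_pct = err,
                 criterion_pct = criterion_pct,
                 mean_abs_err = mean(abs(err)),
                 max_abs_err = max(abs(err)),
                 frac_within = mean(within),
                 within = within,
                 per_material = per_mat),
            class = "bfp_comparison")
}

#' @export
print.bfp_comparison <- function(x, ...) {
  cat(sprintf(
    "<bfp_comparison> %d voxels: %.2f%% within %.3g%% of max dose; mean |err| %.3f%%, max %.3f%%\n",
    length(x$err_pct), 100 * x$frac_within, x$criterion_pct,
    x$mean_abs_err, x$max_abs_err))
  if (!is.null(x$per_material)) {
    print(x$per_material, digits = 4)
  }
  invisible(x)
}

#' Run a full deterministic-vs-Monte-Carlo benchmark
#'
#' Builds (or reuses) the multigroup library for the phantom's materials,
#' solves the Boltzmann-Fokker-Planck equation, runs the Monte Carlo
#' reference on the same library and geometry, unifies the dose grids and
#' computes the agreement report.  Optionally writes dose CSVs, a JSON
#' report and a depth-dose figure.
#'
#' @param phantom A [make_phantom()] spec or phantom name.
#' @param E0 Beam energy (MeV), used when `phantom` is a name.
#' @param groups,sn,legendre,nvox Deterministic discretisation parameters.
#' @param histories,seed,batches Monte Carlo parameters.
#' @param lib Optional prebuilt `bfp_library` (must cover the materials and
#'   have top boundary `E0`).
#' @param beam Beam injection mode passed to [solve_bfp()].
#' @param outdir Optional output directory for artifacts.
#' @param verbose Progress messages.
#' @return A list with `report` (`bfp_comparison`), `dose_det`, `dose_mc`,
#'   `lib`, `geom`, `energy_balance`.
#' @export
run_benchmark <- function(phantom, E0 = 1.0, groups = 100, sn = 16,
                          legendre = 9, nvox = 200, histories = 2e5,
                          seed = 1, batches = 20, lib = NULL,
                          beam = "first-collision", outdir = NULL,
                          verbose = FALSE) {
  if (is.character(phantom)) phantom <- make_phantom(phantom, E0, nvox)
  phantom$nvox <- nvox
  gs <- if (is.null(lib)) make_groups(phantom$E0, groups) else lib$groups
  if (is.null(lib)) {
    lib <- assemble_library(unique(phantom$materials), gs, L = legendre,
                            verbose = verbose)
  }
  geom <- phantom_geometry(phantom)
  src <- beam_source(phantom$E0)
  if (verbose) message("deterministic solve")
  sol <- solve_bfp(geom, lib, src, sn = sn, beam = beam)
  dd <- dose_profile(sol, lib, geom, src)
  if (verbose) message("Monte Carlo reference")
  dm <- run_mc(mc_config(histories, seed = seed, batches = batches),
               geom, lib, src)
  rep <- compare_doses(dd, dm, materials = geom$material)
  eb <- .energy_balance_det(sol, lib, geom, src, dd)
  out <- list(report = rep, dose_det = dd, dose_mc = dm, lib = lib,
              geom = geom, phantom = phantom, energy_balance = eb)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(dd),
                     file.path(outdir, "dose_det.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(dm),
                     file.path(outdir, "dose_mc.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      phantom = phantom$name, E0 = phantom$E0,
      groups = gs$N, sn = sn, legendre = lib$L, nvox = nvox,
      histories = histories, seed = seed,
      frac_within = rep$frac_within, mean_abs_err = rep$mean_abs_err,
      max_abs_err = rep$max_abs_err,
      per_material = rep$per_material,
      energy_balance = as.list(eb)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(outdir, "depthdose.png"), width = 900,
                   height = 600)
    plot(dd, main = sprintf("%s, %g MeV", phantom$name, phantom$E0))
    graphics::points(dm$depth, dm$dose, col = 2, pch = 1, cex = 0.5)
    graphics::legend("topright", c("BFP", "MC"), col = 1:2,
                     lty = c(1, NA), pch = c(NA, 1))
    grDevices::dev.off()
  }
  out
}
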