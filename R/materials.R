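## Material mixtures: mass fractions, Bragg-additivity mean excitation
## energy, atom and electron densities.  Catalogue compositions follow the
## NIST/ICRU-44 tissue definitions.

#' Build a material from element mass fractions
#'
#' Constructs a `bfp_material`: element composition with bulk density and
#' the derived quantities the cross-section generator needs (atoms/cm3 per
#' element, electrons/cm3, effective mean excitation energy via Bragg
#' additivity).
#'
#' @param components Named numeric vector of mass fractions, names are
#'   element symbols (e.g. `c(H = 0.1119, O = 0.8881)`).
#' @param rho Bulk density in g/cm3.
#' @param name Optional material name.
#' @param I_override Optional compound mean excitation energy in eV (used for
#'   condensed-phase ICRU values, e.g. 75 eV for water); when `NULL` the
#'   Bragg-additivity value from the elemental I's is used.
#' @param normalise If `TRUE` (default) mass fractions are renormalised to
#'   sum to one; if `FALSE`, fractions off by more than 1e-6 raise an error.
#' @return An object of class `bfp_material`.
#' @examples
#' w <- build_material(c(H = 0.111894, O = 0.888106), rho = 1.0)
#' w$electron_density  # ~3.343e23 e/cm3
#' @export
build_material <- function(components, rho, name = "custom",
                           I_override = NULL, normalise = TRUE) {
  if (!is.numeric(components) || is.null(names(components)) ||
      any(!nzchar(names(components)))) {
    stop("components must be a named numeric vector of mass fractions",
         call. = FALSE)
  }
  if (any(components <= 0)) stop("mass fractions must be positive", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    stop("density must be a positive scalar (g/cm3)", call. = FALSE)
  }
  s <- sum(components)
  if (normalise) {
    components <- components / s
  } else if (abs(s - 1) > 1e-6) {
    stop(sprintf("mass fractions sum to %.8f, not 1 (strict mode)", s),
         call. = FALSE)
  }
  elements <- lapply(names(components), get_element)
  names(elements) <- names(components)
  Z <- vapply(elements, `[[`, numeric(1), "Z")
  A <- vapply(elements, `[[`, numeric(1), "A")
  I <- vapply(elements, `[[`, numeric(1), "I")
  w <- as.numeric(components)
  navo <- bfp_constants$navo
  n_atom <- navo * rho * w / A              # atoms/cm3 per element
  n_elec <- sum(n_atom * Z)                 # electrons/cm3
  ## Bragg additivity: ln I = sum(w Z/A ln I_i) / sum(w Z/A)
  zw <- w * Z / A
  lnI <- sum(zw * log(I)) / sum(zw)
  I_eff <- if (is.null(I_override)) exp(lnI) else I_override * 1e-6
  structure(list(
    name = name,
    rho = rho,
    mass_fractions = stats::setNames(w, names(components)),
    elements = elements,
    atom_density = stats::setNames(n_atom, names(components)),
    electron_density = n_elec,
    I = I_eff,
    I_bragg = exp(lnI),
    ZA_eff = sum(zw)                        # <Z/A> per gram
  ), class = "bfp_material")
}

#' @export
print.bfp_material <- function(x, ...) {
  cat(sprintf("<bfp_material> %s  rho = %g g/cm3\n", x$name, x$rho))
  cat(sprintf("  electrons/cm3 = %.4e   I = %.2f eV\n",
              x$electron_density, x$I * 1e6))
  comp <- paste(sprintf("%s:%.4f", names(x$mass_fractions), x$mass_fractions),
                collapse = "  ")
  cat("  ", comp, "\n", sep = "")
  invisible(x)
}

## Catalogue: name -> list(rho, I_eV (compound override, NA = Bragg), comp)
.material_catalogue <- list(
  water = list(rho = 1.0, I = 75.0,
    comp = c(H = 0.111894, O = 0.888106),
    note = "liquid water"),
  lung = list(rho = 0.26, I = 75.3,
    comp = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
             P = 0.002, S = 0.003, Cl = 0.003, K = 0.002),
    note = "ICRU-44 lung tissue, healthy inflated density (configurable)"),
  `cortical bone` = list(rho = 1.92, I = 106.4,
    comp = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001,
             Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225),
    note = "ICRU-44 cortical bone"),
  adipose = list(rho = 0.95, I = 63.2,
    comp = c(H = 0.114, C = 0.598, N = 0.007, O = 0.278, Na = 0.001,
             S = 0.001, Cl = 0.001),
    note = "ICRU-44 adipose tissue"),
  muscle = list(rho = 1.05, I = 75.3,
    comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.710, Na = 0.001,
             P = 0.002, S = 0.003, Cl = 0.001, K = 0.004),
    note = "ICRU-44 skeletal muscle"),
  `soft tissue` = list(rho = 1.06, I = 74.7,
    comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002,
             P = 0.003, S = 0.003, Cl = 0.002, K = 0.003),
    note = "ICRU-44 average soft tissue"),
  tumor = list(rho = 1.04, I = 74.7,
    comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002,
             P = 0.003, S = 0.003, Cl = 0.002, K = 0.003),
    note = "surrogate: ICRU-44 soft tissue at 1.04 g/cm3"),
  `breast tissue` = list(rho = 1.02, I = 70.3,
    comp = c(H = 0.106, C = 0.332, N = 0.030, O = 0.527, Na = 0.001,
             P = 0.001, S = 0.002, Cl = 0.001),
    note = "ICRU-44 breast tissue"),
  aluminium = list(rho = 2.699, I = NA,
    comp = c(Al = 1.0), note = "elemental Al"),
  steel = list(rho = 7.87, I = NA,
    comp = c(Fe = 0.98, C = 0.02),
    note = "plain carbon steel surrogate Fe:0.98/C:0.02"),
  carbon = list(rho = 1.70, I = NA,
    comp = c(C = 1.0), note = "graphite"),
  copper = list(rho = 8.96, I = NA,
    comp = c(Cu = 1.0), note = "elemental Cu"),
  gold = list(rho = 19.32, I = NA,
    comp = c(Au = 1.0), note = "elemental Au"),
  uranium = list(rho = 18.95, I = NA,
    comp = c(U = 1.0), note = "elemental U")
)

#' Catalogue materials with NIST/ICRU compositions
#'
#' Returns a catalogue material (composition, default density and compound
#' mean excitation energy) as a [build_material()] object.  The catalogue can
#' be extended or overridden from a YAML file mapping
#' `name: {density: g/cm3, I: eV (optional), composition: {symbol: fraction}}`.
#'
#' @param name Catalogue name, one of [list_materials()].
#' @param rho Optional density override in g/cm3.
#' @param yaml_file Optional YAML catalogue override file.
#' @return A `bfp_material`.
#' @examples
#' nist_material("water")
#' @export
nist_material <- function(name, rho = NULL, yaml_file = NULL) {
  cat_ <- .material_catalogue
  if (!is.null(yaml_file)) {
    ovr <- yaml::read_yaml(yaml_file)
    for (nm in names(ovr)) {
      cat_[[nm]] <- list(
        rho = ovr[[nm]]$density,
        I = if (is.null(ovr[[nm]]$I)) NA else ovr[[nm]]$I,
        comp = unlist(ovr[[nm]]$composition),
        note = "user YAML override")
    }
  }
  entry <- cat_[[name]]
  if (is.null(entry)) {
    stop("unknown catalogue material: ", name,
         " (see list_materials())", call. = FALSE)
  }
  build_material(entry$comp,
                 rho = if (is.null(rho)) entry$rho else rho,
                 name = name,
                 I_override = if (is.na(entry$I)) NULL else entry$I)
}

#' @rdname nist_material
#' @export
list_materials <- function() names(.material_catalogue)
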