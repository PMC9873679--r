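## Embedded atomic constants for the benchmark element set.
##
## Z, A (g/mol), I (mean excitation energy, eV, ICRU-37), subshell binding
## energies (eV) and radiationless (Auger/Coster-Kronig) relaxation entries.
## Binding energies are standard X-ray tabulated values; fluorescence yields
## omega_K/omega_L drive the Auger efficiencies eta = 1 - omega.  Elements
## with Z < 11 carry K-shell data only; L vacancies are tracked from Z >= 11
## and an M1 level from Z >= 20.  Radiative (fluorescence) transitions emit
## photons, which this engine kills at birth, so only radiationless entries
## appear in the relaxation tables.

.make_shell <- function(label, be_eV, transitions = list()) {
  list(label = label, be = be_eV * 1e-6, transitions = transitions)
}

## one Auger entry: efficiency eta and emitted electron energy (MeV)
.tr <- function(eta, e_eV) list(eta = eta, e = e_eV * 1e-6)

.build_element <- function(Z, A, I_eV, symbol, name,
                           be = NULL, omega_K = 0, omega_L = 0) {
  shells <- list()
  if (!is.null(be)) {
    ## be: named vector K, L1, L2, L3, M1 (eV); entries may be missing
    bk <- be[["K"]]
    if (!is.na(bk)) {
      ## KLL Auger: E = U_K - 2*U_L23 (fallback: 0.9 U_K for light atoms)
      ul <- if ("L3" %in% names(be) && !is.na(be[["L3"]])) be[["L3"]] else 0.05 * bk
      eA <- max(bk - 2 * ul, 0.1 * bk)
      shells$K <- .make_shell("K", bk, list(.tr(1 - omega_K, eA)))
    }
    for (ls in c("L1", "L2", "L3")) {
      if (ls %in% names(be) && !is.na(be[[ls]])) {
        ul <- be[[ls]]
        um <- if ("M1" %in% names(be) && !is.na(be[["M1"]])) be[["M1"]] else 0.08 * ul
        eA <- max(ul - 2 * um, 0.1 * ul)
        shells[[ls]] <- .make_shell(ls, ul, list(.tr(1 - omega_L, eA)))
      }
    }
    if ("M1" %in% names(be) && !is.na(be[["M1"]])) {
      ## M vacancies relax with electrons below the transport cutoff for the
      ## whole element set; keep the level (binding energy) with no entries.
      shells$M1 <- .make_shell("M1", be[["M1"]], list())
    }
  }
  ## invariant: binding energies strictly decreasing K -> outer
  if (length(shells) > 1) {
    bes <- vapply(shells, `[[`, numeric(1), "be")
    stopifnot(all(diff(bes) < 0))
  }
  list(Z = Z, A = A, I = I_eV * 1e-6, symbol = symbol, name = name,
       shells = shells)
}

.element_table <- local({
  e <- list()
  e$H  <- .build_element(1, 1.008, 19.2, "H", "hydrogen",
                         be = c(K = 13.6))
  e$C  <- .build_element(6, 12.011, 78.0, "C", "carbon",
                         be = c(K = 284.2), omega_K = 0.0028)
  e$N  <- .build_element(7, 14.007, 82.0, "N", "nitrogen",
                         be = c(K = 409.9), omega_K = 0.0052)
  e$O  <- .build_element(8, 15.999, 95.0, "O", "oxygen",
                         be = c(K = 543.1), omega_K = 0.0083)
  e$Na <- .build_element(11, 22.990, 149.0, "Na", "sodium",
                         be = c(K = 1070.8, L1 = 63.5, L2 = 30.81, L3 = 30.65),
                         omega_K = 0.023)
  e$Mg <- .build_element(12, 24.305, 156.0, "Mg", "magnesium",
                         be = c(K = 1303.0, L1 = 88.7, L2 = 49.78, L3 = 49.50),
                         omega_K = 0.030)
  e$Al <- .build_element(13, 26.982, 166.0, "Al", "aluminium",
                         be = c(K = 1559.6, L1 = 117.8, L2 = 72.95, L3 = 72.55),
                         omega_K = 0.039)
  e$P  <- .build_element(15, 30.974, 173.0, "P", "phosphorus",
                         be = c(K = 2145.5, L1 = 189.0, L2 = 136.0, L3 = 135.0),
                         omega_K = 0.063)
  e$S  <- .build_element(16, 32.06, 180.0, "S", "sulfur",
                         be = c(K = 2472.0, L1 = 230.9, L2 = 163.6, L3 = 162.5),
                         omega_K = 0.078)
  e$Cl <- .build_element(17, 35.45, 174.0, "Cl", "chlorine",
                         be = c(K = 2822.4, L1 = 270.0, L2 = 202.0, L3 = 200.0),
                         omega_K = 0.097)
  e$K  <- .build_element(19, 39.098, 190.0, "K", "potassium",
                         be = c(K = 3608.4, L1 = 378.6, L2 = 297.3, L3 = 294.6),
                         omega_K = 0.140)
  e$Ca <- .build_element(20, 40.078, 191.0, "Ca", "calcium",
                         be = c(K = 4038.5, L1 = 438.4, L2 = 349.7, L3 = 346.2,
                                M1 = 44.3),
                         omega_K = 0.163, omega_L = 0.003)
  e$Fe <- .build_element(26, 55.845, 286.0, "Fe", "iron",
                         be = c(K = 7112.0, L1 = 844.6, L2 = 719.9, L3 = 706.8,
                                M1 = 91.3),
                         omega_K = 0.340, omega_L = 0.009)
  e$Cu <- .build_element(29, 63.546, 322.0, "Cu", "copper",
                         be = c(K = 8978.9, L1 = 1096.7, L2 = 952.3, L3 = 932.7,
                                M1 = 122.5),
                         omega_K = 0.440, omega_L = 0.013)
  e$Au <- .build_element(79, 196.967, 790.0, "Au", "gold",
                         be = c(K = 80724.9, L1 = 14352.8, L2 = 13733.6,
                                L3 = 11918.7, M1 = 2743.0),
                         omega_K = 0.960, omega_L = 0.33)
  e$U  <- .build_element(92, 238.029, 890.0, "U", "uranium",
                         be = c(K = 115606.1, L1 = 21757.4, L2 = 20947.6,
                                L3 = 17166.3, M1 = 5548.0),
                         omega_K = 0.970, omega_L = 0.46)
  e
})

#' Look up an embedded element
#'
#' Returns the embedded atomic constants (Z, A in g/mol, mean excitation
#' energy I in MeV, subshell binding energies and Auger relaxation entries)
#' for one of the elements used by the benchmark materials.
#'
#' @param symbol Element symbol, e.g. `"O"`.
#' @return A list with fields `Z`, `A`, `I`, `symbol`, `name`, `shells`.
#' @export
get_element <- function(symbol) {
  el <- .element_table[[symbol]]
  if (is.null(el)) {
    stop("unknown element symbol: ", symbol, call. = FALSE)
  }
  el
}

#' @rdname get_element
#' @export
list_elements <- function() names(.element_table)
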