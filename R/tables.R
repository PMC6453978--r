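## Element reference tables used throughout the package.
## vdW radii: Bondi (1964) set, extended with common values for elements
## Bondi did not tabulate (Zn from Batsanov-style consensus). Angstrom.
## Atomic weights: CIAAW 2021 conventional values, g/mol.

.BONDI_VDW <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80,
  Cl = 1.75, Ar = 1.88,
  K = 2.75, Ca = 2.31, Ni = 1.63, Cu = 1.40, Zn = 1.39,
  Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02,
  Pd = 1.63, Ag = 1.72, Cd = 1.58, In = 1.93, Sn = 2.17,
  Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16,
  Pt = 1.75, Au = 1.66, Hg = 1.55, Tl = 1.96, Pb = 2.02, Bi = 2.07
)

.ATOMIC_WEIGHTS <- c(
  H = 1.008, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Ag = 107.87, Cd = 112.41, Sn = 118.71, I = 126.90,
  Xe = 131.29, Pt = 195.08, Au = 196.97, Hg = 200.59, Pb = 207.2
)

#' Van der Waals radius lookup
#'
#' Returns Bondi van der Waals radii for chemical symbols. A user-supplied
#' named vector overrides or extends the bundled table (the radius set used
#' by grid void calculations is deliberately configurable).
#'
#' @param elements character vector of chemical symbols (case-sensitive,
#'   e.g. "Zn").
#' @param override optional named numeric vector of radii in Angstrom that
#'   takes precedence over the bundled table.
#' @return numeric vector of radii in Angstrom, same length as `elements`.
#' @examples
#' vdwRadius(c("C", "N", "O"))
#' vdwRadius("C", override = c(C = 1.77))
#' @export
vdwRadius <- function(elements, override = NULL) {
  tab <- .BONDI_VDW
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    tab[names(override)] <- override
  }
  r <- unname(tab[elements])
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' Standard atomic weight lookup
#'
#' @param elements character vector of chemical symbols.
#' @return numeric vector of atomic weights in g/mol.
#' @examples
#' atomicWeight(c("Zn", "C"))
#' @export
atomicWeight <- function(elements) {
  w <- unname(.ATOMIC_WEIGHTS[elements])
  if (anyNA(w)) {
    bad <- unique(elements[is.na(w)])
    stop("no atomic weight for element(s): ", paste(bad, collapse = ", "))
  }
  w
}

.known_element <- function(elements) elements %in% names(.BONDI_VDW) |
  elements %in% names(.ATOMIC_WEIGHTS)

#' Avogadro constant (1/mol)
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23
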