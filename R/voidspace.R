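## voidspace: grid-based probe-accessible void volume, framework density,
## gravimetric pore volume and guest-capacity arithmetic.

## Wrap sites into the cell and replicate over -1..1 lattice shifts along the
## periodic axes, so every image whose inflated sphere can intersect the cell
## is present (valid while inflation radii stay below the cell edges).
.periodic_images <- function(structure) {
  cell <- structure@cell
  M <- cellMatrix(cell)
  frac <- cartesianToFractional(structure@coords, cell)
  per <- structure@periodic
  frac[, per] <- frac[, per] - floor(frac[, per])
  shifts <- as.matrix(expand.grid(if (per[1]) -1:1 else 0,
                                  if (per[2]) -1:1 else 0,
                                  if (per[3]) -1:1 else 0))
  n <- nrow(frac)
  idx <- rep(seq_len(n), times = nrow(shifts))
  fall <- frac[idx, , drop = FALSE] +
    shifts[rep(seq_len(nrow(shifts)), each = n), , drop = FALSE]
  list(cart = fall %*% M, site = idx)
}

## Grid of fractional points (i/n) covering one unit cell, origin at the
## cell origin.
.grid_dims <- function(cell, gridSpacing) {
  len <- c(cell@a, cell@b, cell@c)
  if (gridSpacing > max(len))
    stop("grid_spacing (", gridSpacing, " A) exceeds every cell edge")
  pmax(1L, as.integer(ceiling(len / gridSpacing)))
}

#' Probe-accessible void fraction of a periodic structure
#'
#' Grid calculation over one unit cell (grid origin fixed at the cell
#' origin). Two accessibility conventions are implemented:
#' \describe{
#'   \item{probe-center}{a grid point is accessible iff its minimum-image
#'     distance to every atom is at least `r_vdw + probeRadius` (the locus of
#'     allowed probe centers).}
#'   \item{contact-surface}{the free space left after morphologically
#'     opening the van der Waals complement with the probe: a point is
#'     accessible iff it lies within `probeRadius` of some allowed probe
#'     center. This is the convention of Mercury-style void calculations and
#'     is the default.}
#' }
#' The fraction is (accessible grid points) / (total grid points) and is
#' deterministic for a fixed spec.
#'
#' @param structure a [PeriodicStructure-class].
#' @param probeRadius probe radius in Angstrom (default 1.2, a typical
#'   solvent probe).
#' @param gridSpacing approximate grid spacing in Angstrom (default 0.7).
#' @param mode "contact-surface" or "probe-center".
#' @return fraction in [0, 1].
#' @examples
#' empty <- PeriodicStructure(UnitCell(10, 10, 10), character(0),
#'                            matrix(numeric(0), 0, 3))
#' accessibleVolumeFraction(empty)  # 1
#' @export
accessibleVolumeFraction <- function(structure, probeRadius = 1.2,
                                     gridSpacing = 0.7,
                                     mode = c("contact-surface",
                                              "probe-center")) {
  mode <- match.arg(mode)
  stopifnot(probeRadius >= 0, gridSpacing > 0)
  cell <- structure@cell
  nd <- .grid_dims(cell, gridSpacing)
  if (length(structure@elements) == 0L) return(1)

  blocked <- .blocked_mask(structure, structure@vdw + probeRadius, nd)
  centers <- !blocked
  if (mode == "probe-center") return(mean(centers))
  mean(.dilate_mask(centers, cell, nd, probeRadius, structure@periodic))
}

## Logical [n1,n2,n3] array: TRUE where a grid point lies strictly inside an
## inflated sphere of radius `radii[site]` around any periodic atom image.
.blocked_mask <- function(structure, radii, nd) {
  cell <- structure@cell
  M <- cellMatrix(cell)
  Minv <- solve(M)
  colnorm <- sqrt(colSums(Minv^2))
  img <- .periodic_images(structure)
  blocked <- array(FALSE, dim = nd)
  step <- 1 / nd
  for (k in seq_len(nrow(img$cart))) {
    R <- radii[img$site[k]]
    pos <- img$cart[k, ]
    fpos <- as.numeric(pos %*% Minv)
    lo <- ceiling((fpos - R * colnorm) / step)
    hi <- floor((fpos + R * colnorm) / step)
    if (any(hi < 0) || any(lo > nd - 1)) next
    lo <- pmax(lo, 0); hi <- pmin(hi, nd - 1)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(ii, jj, kk)) * rep(step, each = length(ii) *
                                                    length(jj) * length(kk))
    d2 <- rowSums((g %*% M - rep(pos, each = nrow(g)))^2)
    hitidx <- cbind(expand.grid(ii + 1L, jj + 1L, kk + 1L))[d2 < R^2, ]
    blocked[as.matrix(hitidx)] <- TRUE
  }
  blocked
}

## Periodic morphological dilation of a grid mask by `radius` (Angstrom).
.dilate_mask <- function(mask, cell, nd, radius, periodic) {
  if (radius <= 0) return(mask)
  M <- cellMatrix(cell)
  step <- 1 / nd
  reach <- pmin(nd - 1L, as.integer(floor(radius / (c(cell@a, cell@b, cell@c) * step))) + 1L)
  offs <- as.matrix(expand.grid(-reach[1]:reach[1], -reach[2]:reach[2],
                                -reach[3]:reach[3]))
  d2 <- rowSums((sweep(offs, 2, step, "*") %*% M)^2)
  offs <- offs[d2 <= radius^2, , drop = FALSE]
  out <- array(FALSE, dim = nd)
  ax <- lapply(1:3, function(k) 0:(nd[k] - 1L))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (any(o != 0 & !periodic)) next
    out <- out | mask[((ax[[1]] - o[1]) %% nd[1]) + 1L,
                      ((ax[[2]] - o[2]) %% nd[2]) + 1L,
                      ((ax[[3]] - o[3]) %% nd[3]) + 1L, drop = FALSE]
  }
  out
}

#' Crystallographic density of a framework
#'
#' \eqn{\rho = Z \, M_{FU} / (N_A V_{cell})}, with the formula-unit molar
#' mass from the bundled standard atomic weights.
#'
#' @param formula named numeric vector: element -> stoichiometric count per
#'   formula unit (fractional counts allowed).
#' @param z formula units per unit cell.
#' @param cell a [UnitCell-class].
#' @return density in g/cm^3.
#' @examples
#' frameworkDensity(c(C = 1), z = 1, cell = UnitCell(10, 10, 10))
#' @export
frameworkDensity <- function(formula, z, cell) {
  stopifnot(is.numeric(formula), !is.null(names(formula)), z > 0)
  mfu <- sum(formula * atomicWeight(names(formula)))
  z * mfu / (.N_AVOGADRO * cellVolume(cell) * 1e-24)
}

#' Gravimetric pore volume
#'
#' Converts an accessible volume fraction to specific pore volume:
#' fraction / density (cm^3 void per gram of framework).
#'
#' @param fraction accessible volume fraction in [0, 1].
#' @param density framework density, g/cm^3 (> 0).
#' @return pore volume in cm^3/g.
#' @export
gravimetricPoreVolume <- function(fraction, density) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (density <= 0) stop("density must be positive")
  fraction / density
}

#' Accessible volume per formula unit
#'
#' @param vCellFree free (probe-accessible) volume of one unit cell, A^3.
#' @param z formula units per unit cell (>= 1).
#' @return volume per formula unit in A^3, rounded to 1 decimal.
#' @examples
#' perFUAccessibleVolume(3872.11, 16)  # 242.0
#' @export
perFUAccessibleVolume <- function(vCellFree, z) {
  stopifnot(vCellFree > 0)
  if (z < 1) stop("z must be >= 1")
  round(vCellFree / z, 1)
}

#' Theoretical guest capacity per formula unit
#'
#' Molecules of guest that fit in the per-formula-unit accessible volume,
#' `vFU / vGuest`, reported to 2 decimals (round-half-away-from-zero).
#' Optionally maps loading percentages to molecules per formula unit.
#'
#' @param vFU accessible volume per formula unit, A^3.
#' @param vGuest molecular volume of the guest, A^3 (> 0).
#' @param loadings optional numeric vector of loading percentages.
#' @return list with `capacity` (molecules/FU, 2 decimals) and, when
#'   `loadings` is given, `moleculesPerFU` (named vector, 2 decimals).
#' @examples
#' maxGuestCapacity(242.0, 142.219, loadings = c(25, 44, 56, 74, 100))
#' @export
maxGuestCapacity <- function(vFU, vGuest, loadings = NULL) {
  if (vGuest <= 0) stop("vGuest must be positive")
  cap <- vFU / vGuest
  round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
  out <- list(capacity = round2(cap))
  if (!is.null(loadings))
    out$moleculesPerFU <- stats::setNames(round2(loadings / 100 * cap),
                                          paste0(loadings, "%"))
  out
}

#' Monte-Carlo rolling-probe surface area
#'
#' Samples points uniformly on each atom's inflated sphere (radius
#' `r_vdw + probeRadius`) and rejects samples falling inside any other
#' inflated sphere (minimum image). The exposed-area fraction times the full
#' sphere area, summed over atoms, gives the probe-accessible surface per
#' cell; dividing by the cell mass gives m^2/g.
#'
#' @param structure a [PeriodicStructure-class].
#' @param probeRadius probe radius, Angstrom.
#' @param nSamples Monte-Carlo samples per atom.
#' @param seed integer RNG seed (the estimate is stochastic).
#' @return list with `areaA2` (A^2 per cell) and `m2PerG` (surface area in
#'   m^2 per gram of framework).
#' @export
probeSurfaceArea <- function(structure, probeRadius = 1.2, nSamples = 500,
                             seed = 1) {
  stopifnot(nSamples >= 1)
  if (length(structure@elements) == 0L) return(list(areaA2 = 0, m2PerG = 0))
  ## exactly coincident sites of equal radius are one atom, not two
  key <- paste(round(structure@coords[, 1], 6), round(structure@coords[, 2], 6),
               round(structure@coords[, 3], 6), round(structure@vdw, 6))
  structure <- PeriodicStructure(structure@cell,
                                 structure@elements[!duplicated(key)],
                                 structure@coords[!duplicated(key), ,
                                                  drop = FALSE],
                                 labels = structure@labels[!duplicated(key)],
                                 vdw = structure@vdw[!duplicated(key)],
                                 periodic = structure@periodic)
  n <- length(structure@elements)
  rng <- .seeded_rng(seed)
  Ri <- structure@vdw + probeRadius
  img <- .periodic_images(structure)
  imgR <- Ri[img$site]
  tot <- 0
  for (i in seq_len(n)) {
    u <- matrix(rng$norm(3L * nSamples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * Ri[i], 2, structure@coords[i, ], "+")
    inside <- rep(FALSE, nSamples)
    for (k in seq_len(nrow(img$cart))) {
      if (img$site[k] == i &&
          max(abs(img$cart[k, ] - structure@coords[i, ])) < 1e-9) next
      d2 <- rowSums(sweep(pts, 2, img$cart[k, ])^2)
      inside <- inside | d2 < (imgR[k]^2 - 1e-9)
    }
    tot <- tot + 4 * pi * Ri[i]^2 * mean(!inside)
  }
  massg <- sum(atomicWeight(structure@elements)) / .N_AVOGADRO
  list(areaA2 = tot, m2PerG = tot * 1e-20 / massg)
}

## Local RNG stream so package randomness never disturbs the global
## .Random.seed: returns closures over an isolated Mersenne state.
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    f(...)
  }
  list(unif = with_state(stats::runif),
       norm = with_state(stats::rnorm),
       sample = with_state(function(x, size, replace = FALSE)
         sample(x, size, replace = replace)))
}
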