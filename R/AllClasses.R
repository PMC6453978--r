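#' @import methods
NULL

#' Unit cell of a periodic crystal
#'
#' Cell edge lengths in Angstrom and cell angles in degrees. The Cartesian
#' frame convention is the standard lower-triangular cell matrix: the a axis
#' lies along x, the b axis in the xy plane (see [cellMatrix()]).
#'
#' @slot a,b,c cell edge lengths, Angstrom (> 0).
#' @slot alpha,beta,gamma cell angles, degrees, each in (0, 180).
#' @examples
#' UnitCell(10.7402, 30.6236, 42.6282)
#' @export UnitCell
#' @exportClass UnitCell
UnitCell <- setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  len <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (length(len) != 3L || length(ang) != 3L || !all(is.finite(c(len, ang))))
    return("a, b, c, alpha, beta, gamma must each be a single finite number")
  if (any(len <= 0)) return("cell lengths must be positive")
  if (any(ang <= 0 | ang >= 180)) return("cell angles must lie in (0, 180) degrees")
  ar <- ang * pi / 180
  arg <- 1 - sum(cos(ar)^2) + 2 * prod(cos(ar))
  if (arg <= 0) return("cell angles do not define a positive cell volume")
  TRUE
})

#' @rdname UnitCell-class
#' @param a,b,c,alpha,beta,gamma cell parameters (lengths in Angstrom,
#'   angles in degrees; angles default to 90).
#' @export
UnitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.1f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, cellVolume(object)))
})

#' Periodic crystal structure
#'
#' A unit cell together with an ordered list of atom sites. Coordinates are
#' stored Cartesian (Angstrom); fractional coordinates are derived through
#' the lower-triangular cell matrix ([cartesianToFractional()]).
#'
#' @slot cell a [UnitCell-class].
#' @slot elements character vector of chemical symbols, one per site.
#' @slot labels free-text site labels (e.g. CIF `_atom_site_label`).
#' @slot coords numeric matrix, one row per site, columns x, y, z in Angstrom.
#' @slot vdw numeric vector of per-site van der Waals radii, Angstrom.
#' @slot periodic logical length-3 vector of per-axis periodicity flags.
#' @export PeriodicStructure
#' @exportClass PeriodicStructure
PeriodicStructure <- setClass("PeriodicStructure",
  representation(cell = "UnitCell", elements = "character",
                 labels = "character", coords = "matrix",
                 vdw = "numeric", periodic = "logical"))

setValidity("PeriodicStructure", function(object) {
  n <- length(object@elements)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric matrix with 3 columns")
  if (nrow(object@coords) != n || length(object@labels) != n ||
      length(object@vdw) != n)
    return("elements, labels, coords and vdw must agree in length")
  if (n > 0 && any(object@vdw <= 0))
    return("van der Waals radii must be positive")
  if (length(object@periodic) != 3L)
    return("periodic must be a logical vector of length 3")
  TRUE
})

#' @rdname PeriodicStructure-class
#' @param cell a [UnitCell-class].
#' @param elements chemical symbols, one per site.
#' @param coords numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param labels optional site labels; default `element` + running index.
#' @param vdw optional per-site radii; default from [vdwRadius()].
#' @param periodic per-axis periodicity flags.
#' @param radiusOverride optional named radius overrides passed to
#'   [vdwRadius()].
#' @export
PeriodicStructure <- function(cell, elements, coords,
                              labels = NULL, vdw = NULL,
                              periodic = c(TRUE, TRUE, TRUE),
                              radiusOverride = NULL) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  if (length(elements) > 0 && !all(.known_element(elements))) {
    bad <- unique(elements[!.known_element(elements)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(labels))
    labels <- if (length(elements)) paste0(elements, seq_along(elements)) else character(0)
  if (is.null(vdw))
    vdw <- if (length(elements)) vdwRadius(elements, override = radiusOverride) else numeric(0)
  dimnames(coords) <- NULL
  new("PeriodicStructure", cell = cell, elements = elements,
      labels = as.character(labels), coords = coords, vdw = as.numeric(vdw),
      periodic = as.logical(periodic))
}

setMethod("show", "PeriodicStructure", function(object) {
  cat(sprintf("PeriodicStructure: %d site(s), elements: %s\n",
              length(object@elements),
              paste(unique(object@elements), collapse = " ")))
  show(object@cell)
})

#' Nucleobase instance with resolved atom roles
#'
#' One guest (or framework) nucleobase whose chemically named atoms
#' (conventional nucleobase numbering) have been resolved to atom indices of
#' a structure or trajectory frame. Adenine requires at least N1 and N6
#' (the Watson-Crick face); thymine requires N3, O4, C5 and C6 (the
#' Watson-Crick face plus the photoreactive double bond).
#'
#' @slot baseKind "adenine" or "thymine".
#' @slot moleculeId integer molecule identifier.
#' @slot roleMap named integer vector, role name -> atom index (1-based).
#' @export NucleobaseInstance
#' @exportClass NucleobaseInstance
NucleobaseInstance <- setClass("NucleobaseInstance",
  representation(baseKind = "character", moleculeId = "integer",
                 roleMap = "integer"))

.REQUIRED_ROLES <- list(adenine = c("N1", "N6"),
                        thymine = c("N3", "O4", "C5", "C6"))

setValidity("NucleobaseInstance", function(object) {
  if (!object@baseKind %in% c("adenine", "thymine"))
    return("baseKind must be 'adenine' or 'thymine'")
  req <- .REQUIRED_ROLES[[object@baseKind]]
  missing <- setdiff(req, names(object@roleMap))
  if (length(missing))
    return(sprintf("molecule %d (%s): role %s unresolved", object@moleculeId,
                   object@baseKind, paste(missing, collapse = ", ")))
  if (anyDuplicated(object@roleMap))
    return("atom indices in roleMap must be distinct")
  if (any(object@roleMap < 1L))
    return("atom indices must be >= 1")
  TRUE
})

#' @rdname NucleobaseInstance-class
#' @param baseKind "adenine" or "thymine".
#' @param moleculeId integer molecule id.
#' @param roleMap named integer vector mapping role names to atom indices.
#' @export
NucleobaseInstance <- function(baseKind, moleculeId, roleMap) {
  rm <- as.integer(roleMap)
  names(rm) <- names(roleMap)
  new("NucleobaseInstance", baseKind = baseKind,
      moleculeId = as.integer(moleculeId), roleMap = rm)
}

setMethod("show", "NucleobaseInstance", function(object) {
  cat(sprintf("NucleobaseInstance %s #%d: %s\n", object@baseKind,
              object@moleculeId,
              paste(names(object@roleMap), object@roleMap,
                    sep = "=", collapse = " ")))
})

#' Guest-in-host trajectory
#'
#' Ordered coordinate frames sampled at a fixed time interval, plus a
#' topology of [NucleobaseInstance-class] objects whose atom indices refer
#' to the frame coordinate rows. The cell is fixed across frames (NVT-like
#' sampling); a changing cell is rejected at construction.
#'
#' @slot frames list of n x 3 numeric matrices, one per frame (equal n).
#' @slot frameInterval time between frames, picoseconds (> 0).
#' @slot topology list of [NucleobaseInstance-class].
#' @slot cell a [UnitCell-class].
#' @slot elements chemical symbols for the frame atoms (length n).
#' @export Trajectory
#' @exportClass Trajectory
Trajectory <- setClass("Trajectory",
  representation(frames = "list", frameInterval = "numeric",
                 topology = "list", cell = "UnitCell",
                 elements = "character"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) < 1L) return("trajectory must contain >= 1 frame")
  ns <- vapply(object@frames, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    return("every frame must have an identical atom count")
  if (length(object@elements) && length(object@elements) != ns[1])
    return("elements must match the per-frame atom count")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  idx <- unlist(lapply(object@topology, function(nb) nb@roleMap))
  if (length(idx) && max(idx) > ns[1])
    return("topology atom index out of range for frame atom count")
  TRUE
})

#' @rdname Trajectory-class
#' @param frames list of n x 3 coordinate matrices (Angstrom).
#' @param frameInterval frame spacing in picoseconds.
#' @param topology list of [NucleobaseInstance-class].
#' @param cell a [UnitCell-class].
#' @param elements optional chemical symbols for frame atoms.
#' @export
Trajectory <- function(frames, frameInterval, topology, cell,
                       elements = character(0)) {
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); dimnames(f) <- NULL; f
  })
  new("Trajectory", frames = frames, frameInterval = as.numeric(frameInterval),
      topology = topology, cell = cell, elements = as.character(elements))
}

setMethod("show", "Trajectory", function(object) {
  kinds <- vapply(object@topology, function(nb) nb@baseKind, character(1))
  cat(sprintf("Trajectory: %d frame(s) x %d atom(s), dt=%g ps; %d adenine, %d thymine\n",
              length(object@frames), nrow(object@frames[[1]]),
              object@frameInterval, sum(kinds == "adenine"),
              sum(kinds == "thymine")))
  show(object@cell)
})

#' @describeIn Trajectory-class number of frames.
#' @param x a Trajectory.
#' @export
nFrames <- function(x) length(x@frames)

#' @describeIn Trajectory-class frame spacing in ps.
#' @export
frameInterval <- function(x) x@frameInterval

#' @describeIn Trajectory-class topology (list of nucleobase instances).
#' @export
topology <- function(x) x@topology

#' @describeIn Trajectory-class one frame's coordinate matrix.
#' @param i frame index.
#' @export
getFrame <- function(x, i) x@frames[[i]]

#' @describeIn PeriodicStructure-class Cartesian coordinate matrix.
#' @param x a PeriodicStructure.
#' @export
siteCoords <- function(x) x@coords

#' @describeIn PeriodicStructure-class chemical symbols of the sites.
#' @export
siteElements <- function(x) x@elements

#' @describeIn PeriodicStructure-class site labels.
#' @export
siteLabels <- function(x) x@labels

#' @describeIn PeriodicStructure-class per-site van der Waals radii.
#' @export
siteRadii <- function(x) x@vdw

#' @describeIn PeriodicStructure-class the unit cell.
#' @export
structureCell <- function(x) x@cell

#' @describeIn Trajectory-class the (fixed) unit cell of a trajectory.
#' @export
trajectoryCell <- function(x) x@cell

#' @describeIn NucleobaseInstance-class the role -> atom-index map.
#' @param nb a NucleobaseInstance.
#' @export
roleMap <- function(nb) nb@roleMap

#' @describeIn NucleobaseInstance-class "adenine" or "thymine".
#' @export
baseKind <- function(nb) nb@baseKind

#' @describeIn NucleobaseInstance-class the molecule id.
#' @export
moleculeId <- function(nb) nb@moleculeId
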