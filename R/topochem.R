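## topochem: Schmidt / Woodward-Hoffmann screening of thymine pairs for
## [2+2] photodimerization readiness and readiness-vs-loading statistics.

#' Folded alignment angle between two bond vectors
#'
#' Angle between the lines carrying the two vectors, folded into [0, 90]
#' degrees so parallel and antiparallel bonds both give 0 — the orientation
#' of a C=C double bond has no head or tail for a [2+2] cycloaddition.
#'
#' @param v1,v2 length-3 (or 2) numeric bond vectors, e.g. C5 to C6.
#' @return angle in degrees in [0, 90].
#' @examples
#' alignmentAngle(c(1, 0, 0), c(-2, 0, 0))  # 0
#' alignmentAngle(c(1, 0, 0), c(0, 1, 0))   # 90
#' @export
alignmentAngle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length bond vector")
  acos(pmin(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

## 4-atom torsion C5-C6...C6'-C5', folded to [0,90]; the optional variant of
## the alignment criterion.
.folded_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) == 0 || sum(n2^2) == 0) return(0)
  ang <- acos(pmin(1, pmax(-1, sum(n1 * n2) /
                             sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  min(ang, 180 - ang)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Detect photodimerization-ready thymine pairs in one frame
#'
#' Screens every unordered thymine pair against the two topochemical rules
#' for [2+2] cycloaddition of the C5=C6 double bonds:
#' \itemize{
#'   \item Schmidt distance rule: the bond centers (C5-C6 midpoints,
#'     minimum image) lie strictly within `maxCenterDistance`;
#'   \item alignment (orbital-symmetry proxy): the bonds are nearly
#'     parallel, folded angle strictly below `maxAlignmentAngle`.
#' }
#'
#' @param coords n x 3 Cartesian coordinates of the frame, Angstrom.
#' @param thymines list of [NucleobaseInstance-class] with C5 and C6
#'   resolved.
#' @param cell a [UnitCell-class].
#' @param maxCenterDistance Angstrom, strict upper bound (default 4.2).
#' @param maxAlignmentAngle degrees, strict upper bound (default 30).
#' @param distanceMode "midpoint" (bond-center to bond-center, default) or
#'   "closest-atom" (nearest C5/C6 atom pair).
#' @param angleMode "line" (folded line-line angle of the bond vectors,
#'   default) or "torsion" (folded 4-atom C5-C6-C6'-C5' torsion; defined
#'   only up to the arbitrary atom pairing of non-bonded fragments).
#' @param periodic per-axis periodicity flags.
#' @return data.frame with columns `thyIdLow`, `thyIdHigh`, `centerDistance`,
#'   `alignmentAngle`; one row per ready pair, each unordered pair once.
#' @export
detectDimerizablePairs <- function(coords, thymines, cell,
                                   maxCenterDistance = 4.2,
                                   maxAlignmentAngle = 30,
                                   distanceMode = c("midpoint", "closest-atom"),
                                   angleMode = c("line", "torsion"),
                                   periodic = c(TRUE, TRUE, TRUE)) {
  distanceMode <- match.arg(distanceMode)
  angleMode <- match.arg(angleMode)
  stopifnot(maxCenterDistance > 0, maxAlignmentAngle > 0)
  empty <- data.frame(thyIdLow = integer(0), thyIdHigh = integer(0),
                      centerDistance = numeric(0), alignmentAngle = numeric(0))
  nt <- length(thymines)
  if (nt < 2L) return(empty)
  c5 <- t(vapply(thymines, function(x) coords[x@roleMap[["C5"]], ], numeric(3)))
  c6 <- t(vapply(thymines, function(x) coords[x@roleMap[["C6"]], ], numeric(3)))
  ids <- vapply(thymines, function(x) x@moleculeId, integer(1))
  bad <- which(rowSums((c6 - c5)^2) == 0)
  if (length(bad))
    stop("zero-length C5-C6 bond in thymine molecule ", ids[bad[1]])
  mid <- (c5 + c6) / 2
  out <- empty
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    d <- if (distanceMode == "midpoint")
      minimumImageDistance(mid[i, ], mid[j, ], cell, periodic)
    else min(minimumImageDistance(c5[i, ], c5[j, ], cell, periodic),
             minimumImageDistance(c5[i, ], c6[j, ], cell, periodic),
             minimumImageDistance(c6[i, ], c5[j, ], cell, periodic),
             minimumImageDistance(c6[i, ], c6[j, ], cell, periodic))
    if (d >= maxCenterDistance) next
    ang <- if (angleMode == "line")
      alignmentAngle(c6[i, ] - c5[i, ], c6[j, ] - c5[j, ])
    else .folded_torsion(c5[i, ], c6[i, ], c6[j, ], c5[j, ])
    if (ang >= maxAlignmentAngle) next
    out <- rbind(out, data.frame(thyIdLow = min(ids[i], ids[j]),
                                 thyIdHigh = max(ids[i], ids[j]),
                                 centerDistance = d, alignmentAngle = ang))
  }
  out
}

#' Dimerization-readiness frequency over a trajectory
#'
#' Fraction of (frame, thymine) combinations in which the thymine
#' participates in at least one topochemically ready pair; the
#' per-frame-pair count (ready pairs over frames x thymine pairs) is
#' reported alongside.
#'
#' @param trajectory a [Trajectory-class].
#' @inheritParams detectDimerizablePairs
#' @param loadingLabel numeric loading percentage attached to the profile.
#' @return one-row data.frame: `loading`, `statistic` (per-frame-guest),
#'   `statisticPerPair`, `nFrames`, `nGuests`, `nReadyPairs`.
#' @export
dimerizabilityFrequency <- function(trajectory, maxCenterDistance = 4.2,
                                    maxAlignmentAngle = 30,
                                    distanceMode = c("midpoint", "closest-atom"),
                                    angleMode = c("line", "torsion"),
                                    loadingLabel = NA_real_) {
  distanceMode <- match.arg(distanceMode)
  angleMode <- match.arg(angleMode)
  if (nFrames(trajectory) < 1L) stop("trajectory has zero frames")
  thy <- .split_bases(trajectory@topology)$thymines
  if (!length(thy)) stop("trajectory topology contains no thymine")
  nf <- nFrames(trajectory); nt <- length(thy)
  nready <- 0L; npairs <- 0L
  for (i in seq_len(nf)) {
    cand <- detectDimerizablePairs(trajectory@frames[[i]], thy,
                                   trajectory@cell, maxCenterDistance,
                                   maxAlignmentAngle, distanceMode, angleMode)
    nready <- nready + length(unique(c(cand$thyIdLow, cand$thyIdHigh)))
    npairs <- npairs + nrow(cand)
  }
  data.frame(loading = loadingLabel,
             statistic = nready / (nf * nt),
             statisticPerPair = if (nt > 1) npairs / (nf * choose(nt, 2)) else 0,
             nFrames = nf, nGuests = nt, nReadyPairs = npairs)
}

#' Dimerization readiness across a loading series
#' @param trajectories named list (names = loading percentages).
#' @inheritParams dimerizabilityFrequency
#' @return data.frame of profiles sorted by loading with attribute
#'   `"peakLoading"`.
#' @export
dimerizabilityVsLoading <- function(trajectories, maxCenterDistance = 4.2,
                                    maxAlignmentAngle = 30) {
  loadings <- as.numeric(names(trajectories))
  if (anyNA(loadings)) stop("trajectory list names must be numeric loadings")
  if (anyDuplicated(loadings)) stop("duplicate loading labels")
  prof <- do.call(rbind, lapply(seq_along(trajectories), function(i)
    dimerizabilityFrequency(trajectories[[i]], maxCenterDistance,
                            maxAlignmentAngle, loadingLabel = loadings[i])))
  prof <- prof[order(prof$loading), ]
  rownames(prof) <- NULL
  attr(prof, "peakLoading") <- prof$loading[which.max(prof$statistic)]
  prof
}

#' Predict the loading window where photodimerization is enabled
#'
#' The mechanistic picture is a joint condition: guests must be locked by
#' Watson-Crick pairing to the host adenines AND sit in a topochemically
#' ready arrangement. This returns the loadings at which both frequency
#' profiles exceed their thresholds.
#'
#' @param pairingProfiles,readinessProfiles data.frames from
#'   [pairingVsLoading()] / [dimerizabilityVsLoading()]; must cover
#'   identical loadings.
#' @param minPairing,minReadiness thresholds on the per-frame-guest
#'   statistics.
#' @return numeric vector of loadings (possibly empty), sorted.
#' @export
predictDimerizationWindow <- function(pairingProfiles, readinessProfiles,
                                      minPairing, minReadiness) {
  lp <- sort(pairingProfiles$loading); lr <- sort(readinessProfiles$loading)
  if (length(lp) != length(lr) || any(lp != lr))
    stop("pairing and readiness profiles cover different loadings")
  p <- pairingProfiles[order(pairingProfiles$loading), ]
  r <- readinessProfiles[order(readinessProfiles$loading), ]
  sort(p$loading[p$statistic > minPairing & r$statistic > minReadiness])
}
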