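## synthdata: seeded synthetic channel structures and guest trajectories
## with planted, recoverable ground truth for every statistic the pipeline
## computes. Stands in for an MD engine at the statistical level only:
## frames are independent draws, guests are rigid bodies with ideal internal
## geometry.

## Ideal planar heavy-atom geometries (Angstrom, best-fit plane projection
## of an MMFF-optimized gas-phase structure). Columns x, y.
.ADE_RAW <- list(
  atoms = c("N6", "C6", "N1", "C2", "N3", "C4", "N9", "C8", "N7", "C5"),
  elements = c("N", "C", "N", "C", "N", "C", "N", "C", "N", "C"),
  xy = matrix(c(-1.7218, 2.0387, -1.1647, 0.7662, -1.9996, -0.2990,
                -1.4594, -1.5388, -0.1553, -1.8864, 0.6207, -0.7936,
                1.9843, -0.7530, 2.3580, 0.5639, 1.3174, 1.3710,
                0.2203, 0.5310), ncol = 2, byrow = TRUE))
.THY_RAW <- list(
  atoms = c("C7", "C5", "C6", "N1", "C2", "O2", "N3", "C4", "O4"),
  elements = c("C", "C", "C", "N", "C", "O", "N", "C", "O"),
  xy = matrix(c(-2.6314, 0.7805, -1.1578, 0.5442, -0.2327, 1.5121,
                1.1022, 1.2208, 1.6010, -0.0527, 2.8063, -0.2779,
                0.6689, -1.0496, -0.6862, -0.8671, -1.4702, -1.8103),
              ncol = 2, byrow = TRUE))

.rot2 <- function(phi) matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)

## Canonical in-plane frames:
##  adenine: Watson-Crick edge midpoint (N1+N6)/2 at the origin, N1->N6
##    along +x, ring body at -y so the W-C face normal points +y.
##  thymine: (N3+O4)/2 at the origin, N3->O4 along +x, ring body at +y so
##    the W-C face normal points -y (facing an adenine in canonical A-T
##    arrangement).
.canonical_base <- function(kind) {
  raw <- if (kind == "adenine") .ADE_RAW else .THY_RAW
  xy <- raw$xy
  pick <- function(a) xy[match(a, raw$atoms), ]
  edge <- if (kind == "adenine") c("N1", "N6") else c("N3", "O4")
  p1 <- pick(edge[1]); p2 <- pick(edge[2])
  xy <- sweep(xy, 2, (p1 + p2) / 2)
  v <- p2 - p1
  xy <- xy %*% .rot2(atan2(v[2], v[1]))
  want <- if (kind == "adenine") -1 else +1
  if (sign(mean(xy[, 2])) != want) xy[, 2] <- -xy[, 2]
  list(atoms = raw$atoms, elements = raw$elements, xy = xy)
}

#' Build a synthetic 1-D adenine-lined channel
#'
#' A periodic channel along the x axis whose two walls carry rigid adenine
#' templates with their Watson-Crick faces pointing into the channel, on
#' alternating walls: site j sits at `x = j * axisRepeat / adeSpacing`, on
#' the +y wall for even j and the -y wall for odd j. The cell is padded in
#' y and z so only the x axis is structurally periodic.
#'
#' @param axisRepeat channel period along x, Angstrom (default 10.74, a
#'   typical a-axis of an adeninate framework).
#' @param adeSpacing adenine sites per period (default 2, alternating
#'   walls).
#' @param wallSeparation distance between the two Watson-Crick edge lines,
#'   Angstrom (default 8.2, chosen so that guests locked at the two sites
#'   of one period satisfy the topochemical rules; see the package
#'   vignette).
#' @param nPeriods number of periods in the cell (>= 1).
#' @return list with `structure` (a [PeriodicStructure-class] of the
#'   adenine walls), `topology` (adenine [NucleobaseInstance-class] list),
#'   `sites` (data.frame: site, x, side), and the geometry parameters.
#' @export
buildChannel <- function(axisRepeat = 10.74, adeSpacing = 2,
                         wallSeparation = 8.2, nPeriods = 6) {
  stopifnot(axisRepeat > 0, adeSpacing >= 1, nPeriods >= 1)
  if (wallSeparation < 7.5)
    stop("wall separation ", wallSeparation,
         " A too small for guest insertion (need >= 7.5 A)")
  ade <- .canonical_base("adenine")
  pad <- 7  # ring extent behind the W-C edge plus clearance
  a <- nPeriods * axisRepeat
  b <- wallSeparation + 2 * pad
  cc <- 14
  y0 <- b / 2; z0 <- cc / 2
  nSites <- as.integer(adeSpacing * nPeriods)
  sites <- data.frame(site = seq_len(nSites) - 1L,
                      x = (seq_len(nSites) - 1L) * axisRepeat / adeSpacing,
                      side = ifelse((seq_len(nSites) - 1L) %% 2L == 0L, 1L, -1L))
  coords <- NULL; elements <- character(0); labels <- character(0)
  topo <- list()
  for (k in seq_len(nSites)) {
    s <- sites$side[k]
    ## face must point into the channel (-s * y): canonical face is +y, so
    ## rotate by 180 degrees for +y-wall sites
    xy <- if (s > 0) -ade$xy else ade$xy
    xy <- sweep(xy, 2, c(sites$x[k], y0 + s * wallSeparation / 2), "+")
    idx0 <- nrow(coords %||% matrix(0, 0, 3))
    coords <- rbind(coords, cbind(xy, z0))
    elements <- c(elements, ade$elements)
    labels <- c(labels, ade$atoms)
    rm <- stats::setNames(idx0 + seq_along(ade$atoms), ade$atoms)
    topo[[k]] <- NucleobaseInstance("adenine", k, rm)
  }
  cell <- UnitCell(a, b, cc)
  list(structure = PeriodicStructure(cell, elements, coords, labels = labels),
       topology = topo, sites = sites, axisRepeat = axisRepeat,
       adeSpacing = adeSpacing, wallSeparation = wallSeparation,
       nPeriods = nPeriods, y0 = y0, z0 = z0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Analytic placement of a rigid thymine Watson-Crick-locked to an adenine
## site: N3 is placed at distance d1 from adenine N1 along the face normal;
## the in-plane rotation is solved in closed form so that |O4 - N6| = d2.
## `mirror` flips the template over (both in-plane enantiomers of the planar
## molecule); `preferDir` (+1/-1) picks the mirror whose C5-C6 midpoint is
## offset toward the motif partner site.
.place_locked_thymine <- function(thy, N1a, N6a, faceDir, d1, d2,
                                  preferDir = 1) {
  u <- c(0, faceDir)
  N3t <- N1a + d1 * u
  phi0 <- if (faceDir > 0) 0 else pi
  best <- NULL
  for (m in c(1, -1)) {
    v <- sweep(thy$xy, 2, thy$xy[match("N3", thy$atoms), ])
    v[, 1] <- m * v[, 1]
    vO4 <- v[match("O4", thy$atoms), ]
    cvec <- N3t - N6a
    K <- (d2^2 - sum(cvec^2) - sum(vO4^2)) / (2 * sqrt(sum(cvec^2) * sum(vO4^2)))
    base <- atan2(cvec[2], cvec[1]) - atan2(vO4[2], vO4[1])
    phis <- if (abs(K) <= 1) base + c(acos(K), -acos(K))
    else base + ifelse(K > 1, 0, pi)
    dphi <- function(p) abs(((p - phi0 + pi) %% (2 * pi)) - pi)
    phi <- phis[which.min(dphi(phis))]
    xy <- sweep(v %*% t(.rot2(phi)), 2, N3t, "+")
    mid <- (xy[match("C5", thy$atoms), ] + xy[match("C6", thy$atoms), ]) / 2
    cand <- list(xy = xy, mid = mid, offx = mid[1] - N1a[1], mirror = m,
                 closeness = dphi(phi))
    if (is.null(best) ||
        (sign(cand$offx) == preferDir && sign(best$offx) != preferDir))
      best <- if (is.null(best)) cand else cand
    else if (sign(best$offx) != preferDir && cand$closeness < best$closeness)
      best <- cand
  }
  best$xy
}

## Uniform random 3D rotation matrix from four N(0,1) draws (quaternion).
.random_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

## Truncated-normal draw on [lo, hi] by inverse-CDF.
.rtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), length(u)))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate a guest trajectory with planted ground truth
#'
#' Per frame, each thymine guest is independently Watson-Crick-locked with
#' probability `pPair` at an unoccupied adenine site chosen uniformly (its
#' two donor-acceptor distances drawn from a normal truncated to the
#' near-ideal band 2.7-3.0 Angstrom, which doubles as the thermal noise on
#' locked guests); otherwise it is placed uniformly in the channel interior
#' with a uniform random orientation and Gaussian positional jitter. Frames
#' are independent draws (no autocorrelation). All randomness flows from
#' `seed`; output is bit-reproducible.
#'
#' The returned ground truth records every planted pairing and every
#' planted dimer-ready pair (two guests locked at the two sites of one
#' period, whose construction geometry satisfies the Schmidt distance and
#' alignment rules).
#'
#' @param channel a channel from [buildChannel()].
#' @param loadingPercent loading as percent of theoretical capacity.
#' @param pPair probability a guest is locked in a given frame, in [0, 1].
#' @param nFrames number of frames (>= 1).
#' @param frameIntervalPs frame spacing, ps (default 2).
#' @param wcDistanceMean,wcDistanceSd donor-acceptor distance distribution
#'   for locked guests, Angstrom (defaults 2.85, 0.08; truncated to
#'   [2.7, 3.0]).
#' @param jitterTranslationSd Cartesian jitter on free guests, Angstrom.
#' @param capacityPerPeriod theoretical guests per period at 100% loading
#'   (default 1.70 molecules per formula unit, one formula unit per
#'   period).
#' @param seed integer RNG seed.
#' @return list with `trajectory` (a [Trajectory-class]: adenine walls plus
#'   guests) and `truth` (list: `pPair`, `nGuests`, per-frame `pairs` and
#'   `readyPairs` id matrices, `plantedPairingFraction`,
#'   `plantedReadinessFraction`).
#' @export
simulateTrajectory <- function(channel, loadingPercent = 44, pPair = 0.75,
                               nFrames = 200, frameIntervalPs = 2,
                               wcDistanceMean = 2.85, wcDistanceSd = 0.08,
                               jitterTranslationSd = 0.25,
                               capacityPerPeriod = 1.70, seed = 1) {
  stopifnot(pPair >= 0, pPair <= 1, nFrames >= 1, loadingPercent > 0)
  thy <- .canonical_base("thymine")
  nSites <- nrow(channel$sites)
  nGuests <- max(1L, as.integer(round(loadingPercent / 100 *
                                        capacityPerPeriod * channel$nPeriods)))
  if (nGuests > nSites)
    stop("over-capacity request: ", nGuests, " guests for ", nSites,
         " adenine sites")
  rng <- .seeded_rng(seed)
  host <- channel$structure
  nHost <- length(host@elements)
  nThyAtoms <- length(thy$atoms)
  cell <- host@cell
  a <- cell@a; y0 <- channel$y0; z0 <- channel$z0
  wsep <- channel$wallSeparation

  ## adenine site anchor coordinates (2D, in the base plane)
  adeN1 <- t(vapply(channel$topology, function(nb)
    host@coords[nb@roleMap[["N1"]], 1:2], numeric(2)))
  adeN6 <- t(vapply(channel$topology, function(nb)
    host@coords[nb@roleMap[["N6"]], 1:2], numeric(2)))
  faceDir <- -channel$sites$side  # into the channel

  ## motif partner: sites (2k, 2k+1) form the dimer-ready pair; the C5-C6
  ## offset is steered toward the partner
  partnerDir <- ifelse(channel$sites$site %% 2L == 0L, +1, -1)

  topoGuests <- lapply(seq_len(nGuests), function(g)
    NucleobaseInstance("thymine", nSites + g,
                       stats::setNames(nHost + (g - 1L) * nThyAtoms +
                                         seq_len(nThyAtoms), thy$atoms)))
  topo <- c(channel$topology, topoGuests)
  elements <- c(host@elements, rep(thy$elements, nGuests))

  thyCentered <- sweep(cbind(thy$xy, 0), 2,
                       colMeans(cbind(thy$xy, 0)))
  frames <- vector("list", nFrames)
  pairsList <- vector("list", nFrames)
  readyList <- vector("list", nFrames)
  nLockedTot <- 0L; nReadyTot <- 0L
  for (f in seq_len(nFrames)) {
    locked <- rng$unif(nGuests) < pPair
    siteOf <- rep(NA_integer_, nGuests)
    if (any(locked))
      siteOf[locked] <- rng$sample(seq_len(nSites), sum(locked))
    g3 <- matrix(0, nGuests * nThyAtoms, 3)
    for (g in seq_len(nGuests)) {
      rows <- (g - 1L) * nThyAtoms + seq_len(nThyAtoms)
      if (locked[g]) {
        k <- siteOf[g]
        d1 <- .rtruncnorm(rng$unif(1), wcDistanceMean, wcDistanceSd, 2.7, 3.0)
        d2 <- .rtruncnorm(rng$unif(1), wcDistanceMean, wcDistanceSd, 2.7, 3.0)
        xy <- .place_locked_thymine(thy, adeN1[k, ], adeN6[k, ], faceDir[k],
                                    d1, d2, preferDir = partnerDir[k])
        g3[rows, ] <- cbind(xy, z0)
      } else {
        R <- .random_rotation(rng$norm(4))
        center <- c(rng$unif(1) * a,
                    y0 + (rng$unif(1) - 0.5) * (wsep - 7),
                    z0 + (rng$unif(1) - 0.5) * 2) +
          rng$norm(3) * jitterTranslationSd
        g3[rows, ] <- sweep(thyCentered %*% t(R), 2, center, "+")
      }
    }
    frames[[f]] <- rbind(host@coords, g3)
    lk <- which(locked)
    pairsList[[f]] <- cbind(adeId = siteOf[lk], thyId = nSites + lk)
    nLockedTot <- nLockedTot + length(lk)
    ## planted ready pairs: both sites of one period simultaneously locked
    rp <- NULL
    if (length(lk) >= 2L) {
      occ <- stats::setNames(nSites + lk, siteOf[lk])  # site -> thy id
      for (k2 in seq_len(floor(nSites / 2))) {
        s1 <- as.character(2L * k2 - 1L); s2 <- as.character(2L * k2)
        if (!is.na(occ[s1]) && !is.na(occ[s2]))
          rp <- rbind(rp, sort(c(occ[[s1]], occ[[s2]])))
      }
    }
    readyList[[f]] <- rp %||% matrix(integer(0), 0, 2)
    nReadyTot <- nReadyTot + 2L * nrow(readyList[[f]])
  }
  traj <- Trajectory(frames, frameIntervalPs, topo, cell, elements = elements)
  list(trajectory = traj,
       truth = list(pPair = pPair, nGuests = nGuests, nFrames = nFrames,
                    pairs = pairsList, readyPairs = readyList,
                    plantedPairingFraction = nLockedTot / (nFrames * nGuests),
                    plantedReadinessFraction = nReadyTot / (nFrames * nGuests)))
}

#' Default locking-probability schedule across loadings
#'
#' The study conditions the generator emulates: base-pair locking peaks at
#' 44% loading and deteriorates at higher loadings where dense packing
#' disfavors pairing, and stays low at 25% where guests are sparse.
#'
#' @return named numeric vector, loading percent -> pPair.
#' @export
defaultPPairSchedule <- function() {
  c(`25` = 0.30, `44` = 0.75, `56` = 0.60, `74` = 0.50, `100` = 0.40)
}

#' Generate the five-loading synthetic trajectory suite
#'
#' One seeded trajectory per loading with the locking probability taken
#' from `pPairSchedule` (linearly interpolated for unlisted loadings). With
#' the default channel geometry and schedule the suite is constructed so
#' that base pairing peaks at 44% loading and the joint pairing+readiness
#' condition singles out 44% — a planted, testable property.
#'
#' @param channel a channel from [buildChannel()].
#' @param loadings distinct loading percentages (default
#'   c(25, 44, 56, 74, 100)).
#' @param pPairSchedule named vector, loading -> pPair.
#' @param nFrames frames per trajectory.
#' @param seed integer master seed; per-loading streams are derived from it.
#' @param ... further arguments to [simulateTrajectory()].
#' @return named list: loading -> list(trajectory, truth).
#' @export
makeLoadingSuite <- function(channel, loadings = c(25, 44, 56, 74, 100),
                             pPairSchedule = defaultPPairSchedule(),
                             nFrames = 400, seed = 1, ...) {
  if (!length(loadings)) stop("empty loading list")
  if (anyDuplicated(loadings)) stop("loadings must be distinct")
  sched_l <- as.numeric(names(pPairSchedule))
  pp <- stats::approx(sched_l, pPairSchedule, xout = loadings, rule = 2)$y
  out <- lapply(seq_along(loadings), function(i)
    simulateTrajectory(channel, loadingPercent = loadings[i], pPair = pp[i],
                       nFrames = nFrames,
                       seed = (as.integer(seed) + i * 1009L) %% .Machine$integer.max,
                       ...))
  names(out) <- loadings
  out
}
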