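## pairing: Watson-Crick Ade-Thy base-pair detection by heavy-atom distance
## criteria and pairing-frequency statistics over trajectories.

## Vectorized minimum-image distances between matched rows of P and Q.
.mi_dist_rows <- function(P, Q, M, Minv, periodic = c(TRUE, TRUE, TRUE)) {
  df <- (Q - P) %*% Minv
  for (k in 1:3) if (periodic[k]) df[, k] <- df[, k] - round(df[, k])
  shifts <- as.matrix(expand.grid(if (periodic[1]) -1:1 else 0,
                                  if (periodic[2]) -1:1 else 0,
                                  if (periodic[3]) -1:1 else 0))
  best <- rep(Inf, nrow(df))
  for (s in seq_len(nrow(shifts))) {
    d <- sweep(df, 2, shifts[s, ], "+") %*% M
    best <- pmin(best, rowSums(d * d))
  }
  sqrt(best)
}

#' Detect Watson-Crick adenine-thymine pairs in one frame
#'
#' A thymine is paired with an adenine when the two canonical heavy-atom
#' contacts of the A-T Watson-Crick face are both within the cutoff
#' (inclusive): adenine N1 to thymine N3 (`dNN`) and adenine N6 to thymine
#' O4 (`dNO`). Distances use the minimum-image convention. Each thymine is
#' matched to at most one adenine: the one with the smallest `dNN`
#' (ties broken by lower adenine molecule id). The thymine O2 contact is
#' reported when resolvable but never required.
#'
#' @param coords n x 3 Cartesian coordinate matrix of the frame, Angstrom.
#' @param adenines,thymines lists of [NucleobaseInstance-class] whose role
#'   indices refer to rows of `coords`.
#' @param cell a [UnitCell-class].
#' @param maxHeavyDistance heavy-atom donor-acceptor cutoff, Angstrom
#'   (default 3.0, inclusive).
#' @param requireBothBonds require both contacts within the cutoff
#'   (default TRUE); when FALSE, either contact suffices.
#' @param periodic per-axis periodicity flags.
#' @return data.frame with columns `adeId`, `thyId`, `dNN`, `dNO`, `dNO2`
#'   (NA when the thymine O2 role is unresolved); zero rows when nothing
#'   pairs.
#' @export
detectWCPairs <- function(coords, adenines, thymines, cell,
                          maxHeavyDistance = 3.0, requireBothBonds = TRUE,
                          periodic = c(TRUE, TRUE, TRUE)) {
  stopifnot(maxHeavyDistance > 0)
  empty <- data.frame(adeId = integer(0), thyId = integer(0),
                      dNN = numeric(0), dNO = numeric(0), dNO2 = numeric(0))
  if (!length(adenines) || !length(thymines)) return(empty)
  M <- cellMatrix(cell); Minv <- solve(M)
  na <- length(adenines); nt <- length(thymines)
  aN1 <- coords[vapply(adenines, function(x) x@roleMap[["N1"]], integer(1)), ,
                drop = FALSE]
  aN6 <- coords[vapply(adenines, function(x) x@roleMap[["N6"]], integer(1)), ,
                drop = FALSE]
  tN3 <- coords[vapply(thymines, function(x) x@roleMap[["N3"]], integer(1)), ,
                drop = FALSE]
  tO4 <- coords[vapply(thymines, function(x) x@roleMap[["O4"]], integer(1)), ,
                drop = FALSE]
  o2i <- vapply(thymines, function(x)
    if ("O2" %in% names(x@roleMap)) x@roleMap[["O2"]] else NA_integer_,
    integer(1))
  ai <- rep(seq_len(na), times = nt)
  ti <- rep(seq_len(nt), each = na)
  dNN <- .mi_dist_rows(aN1[ai, , drop = FALSE], tN3[ti, , drop = FALSE],
                       M, Minv, periodic)
  dNO <- .mi_dist_rows(aN6[ai, , drop = FALSE], tO4[ti, , drop = FALSE],
                       M, Minv, periodic)
  ok <- if (requireBothBonds) dNN <= maxHeavyDistance & dNO <= maxHeavyDistance
  else dNN <= maxHeavyDistance | dNO <= maxHeavyDistance
  if (!any(ok)) return(empty)
  cand <- data.frame(a = ai[ok], t = ti[ok], dNN = dNN[ok], dNO = dNO[ok])
  aid <- vapply(adenines, function(x) x@moleculeId, integer(1))
  ## one adenine per thymine: smallest dNN, then lowest adenine molecule id
  cand <- cand[order(cand$t, cand$dNN, aid[cand$a]), ]
  cand <- cand[!duplicated(cand$t), ]
  dNO2 <- rep(NA_real_, nrow(cand))
  has2 <- !is.na(o2i[cand$t])
  if (any(has2))
    dNO2[has2] <- .mi_dist_rows(aN6[cand$a[has2], , drop = FALSE],
                                coords[o2i[cand$t[has2]], , drop = FALSE],
                                M, Minv, periodic)
  data.frame(adeId = aid[cand$a],
             thyId = vapply(thymines, function(x) x@moleculeId,
                            integer(1))[cand$t],
             dNN = cand$dNN, dNO = cand$dNO, dNO2 = dNO2,
             row.names = NULL)
}

.split_bases <- function(topo) {
  kinds <- vapply(topo, function(x) x@baseKind, character(1))
  list(adenines = topo[kinds == "adenine"], thymines = topo[kinds == "thymine"])
}

#' Pairing frequency over a trajectory
#'
#' Fraction of (frame, thymine) combinations found in a Watson-Crick pairing
#' event — the per-frame-guest occupancy statistic. The per-possible-pair
#' normalization (events over frames x adenines x thymines) is reported
#' alongside; the per-frame-guest form is the default summary because it
#' reads directly as "the probability that a thymine is base-paired at any
#' instant".
#'
#' @param trajectory a [Trajectory-class] with >= 1 thymine in its topology.
#' @param maxHeavyDistance,requireBothBonds see [detectWCPairs()].
#' @param loadingLabel numeric loading percentage attached to the profile.
#' @return one-row data.frame (a frequency profile): `loading`, `statistic`
#'   (per-frame-guest), `statisticPerPair`, `nFrames`, `nGuests`, `nEvents`.
#' @export
pairingFrequency <- function(trajectory, maxHeavyDistance = 3.0,
                             requireBothBonds = TRUE, loadingLabel = NA_real_) {
  if (nFrames(trajectory) < 1L) stop("trajectory has zero frames")
  b <- .split_bases(trajectory@topology)
  if (!length(b$thymines)) stop("trajectory topology contains no thymine")
  nf <- nFrames(trajectory)
  nt <- length(b$thymines); na <- length(b$adenines)
  nevent <- 0L
  for (i in seq_len(nf)) {
    ev <- detectWCPairs(trajectory@frames[[i]], b$adenines, b$thymines,
                        trajectory@cell, maxHeavyDistance, requireBothBonds)
    nevent <- nevent + nrow(ev)
  }
  data.frame(loading = loadingLabel,
             statistic = nevent / (nf * nt),
             statisticPerPair = if (na > 0) nevent / (nf * na * nt) else 0,
             nFrames = nf, nGuests = nt, nEvents = nevent)
}

#' Pairing frequency across a loading series
#'
#' @param trajectories named list, names are loading percentages, values
#'   [Trajectory-class] objects.
#' @param maxHeavyDistance,requireBothBonds see [detectWCPairs()].
#' @return data.frame of frequency profiles sorted by loading, with the
#'   argmax loading in attribute `"peakLoading"`.
#' @export
pairingVsLoading <- function(trajectories, maxHeavyDistance = 3.0,
                             requireBothBonds = TRUE) {
  loadings <- as.numeric(names(trajectories))
  if (anyNA(loadings)) stop("trajectory list names must be numeric loadings")
  if (anyDuplicated(loadings)) stop("duplicate loading labels")
  prof <- do.call(rbind, lapply(seq_along(trajectories), function(i)
    pairingFrequency(trajectories[[i]], maxHeavyDistance, requireBothBonds,
                     loadingLabel = loadings[i])))
  prof <- prof[order(prof$loading), ]
  rownames(prof) <- NULL
  attr(prof, "peakLoading") <- prof$loading[which.max(prof$statistic)]
  prof
}
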