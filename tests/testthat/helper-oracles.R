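## Independent brute-force oracles and random-frame builders shared across
## the suite. The oracles deliberately avoid the package's vectorized
## minimum-image code path: distances come from exhaustive enumeration of
## lattice images.

## Exhaustive minimum-image distance over all images in -2..2.
oracle_min_dist <- function(p, q, cell, range = 4) {
  M <- cellMatrix(cell)
  sh <- as.matrix(expand.grid(-range:range, -range:range, -range:range))
  min(sqrt(rowSums((matrix(q - p, nrow(sh), 3, byrow = TRUE) + sh %*% M)^2)))
}

## All-pairs Watson-Crick detector: no matching acceleration, exhaustive
## image search, then the same one-adenine-per-thymine rule applied naively.
oracle_wc_pairs <- function(coords, adenines, thymines, cell, cutoff = 3.0) {
  out <- NULL
  for (t in thymines) {
    best <- NULL
    for (a in adenines) {
      dNN <- oracle_min_dist(coords[a@roleMap[["N1"]], ],
                             coords[t@roleMap[["N3"]], ], cell, range = 2)
      dNO <- oracle_min_dist(coords[a@roleMap[["N6"]], ],
                             coords[t@roleMap[["O4"]], ], cell, range = 2)
      if (dNN <= cutoff && dNO <= cutoff) {
        if (is.null(best) || dNN < best$dNN ||
            (dNN == best$dNN && a@moleculeId < best$adeId))
          best <- list(adeId = a@moleculeId, dNN = dNN, dNO = dNO)
      }
    }
    if (!is.null(best))
      out <- rbind(out, data.frame(adeId = best$adeId,
                                   thyId = t@moleculeId,
                                   dNN = best$dNN, dNO = best$dNO))
  }
  out
}

## All-pairs Schmidt/alignment screen with exhaustive image midpoints.
oracle_dimer_pairs <- function(coords, thymines, cell, dmax = 4.2,
                               amax = 30) {
  out <- NULL
  n <- length(thymines)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- thymines[[i]]; tj <- thymines[[j]]
    mi <- (coords[ti@roleMap[["C5"]], ] + coords[ti@roleMap[["C6"]], ]) / 2
    mj <- (coords[tj@roleMap[["C5"]], ] + coords[tj@roleMap[["C6"]], ]) / 2
    d <- oracle_min_dist(mi, mj, cell, range = 2)
    vi <- coords[ti@roleMap[["C6"]], ] - coords[ti@roleMap[["C5"]], ]
    vj <- coords[tj@roleMap[["C6"]], ] - coords[tj@roleMap[["C5"]], ]
    ang <- acos(min(1, abs(sum(vi * vj)) /
                      sqrt(sum(vi^2) * sum(vj^2)))) * 180 / pi
    if (d < dmax && ang < amax)
      out <- rbind(out, data.frame(
        thyIdLow = min(ti@moleculeId, tj@moleculeId),
        thyIdHigh = max(ti@moleculeId, tj@moleculeId),
        centerDistance = d, alignmentAngle = ang))
  }
  out
}

## Random frame of skeletal bases: each "adenine" is two atoms (N1, N6
## 2.34 A apart), each "thymine" four atoms (N3, O4 2.27 A apart plus a
## C5-C6 bond) at uniform positions/orientations in the cell. Chemically
## minimal but exercises every code path of the detectors, including
## wraparound.
random_base_frame <- function(nAde, nThy, cell, seed) {
  set.seed(seed)
  M <- cellMatrix(cell)
  randdir <- function() {
    v <- rnorm(3); v / sqrt(sum(v^2))
  }
  coords <- NULL; topo <- list(); mid <- 0L
  for (i in seq_len(nAde)) {
    p <- as.numeric(runif(3) %*% M); u <- randdir()
    coords <- rbind(coords, p, p + 2.34 * u)
    mid <- mid + 1L
    topo[[mid]] <- NucleobaseInstance("adenine", mid,
                                      c(N1 = nrow(coords) - 1L,
                                        N6 = nrow(coords)))
  }
  for (i in seq_len(nThy)) {
    p <- as.numeric(runif(3) %*% M); u <- randdir(); w <- randdir()
    coords <- rbind(coords, p, p + 2.27 * u, p + 1.5 * w, p + 1.5 * w +
                      1.34 * randdir())
    mid <- mid + 1L
    n <- nrow(coords)
    topo[[mid]] <- NucleobaseInstance("thymine", mid,
                                      c(N3 = n - 3L, O4 = n - 2L,
                                        C5 = n - 1L, C6 = n))
  }
  kinds <- vapply(topo, baseKind, character(1))
  list(coords = coords, adenines = topo[kinds == "adenine"],
       thymines = topo[kinds == "thymine"])
}

## Standard role templates matching the generator's atom labels.
role_templates <- function() {
  list(adenine = c(N1 = "N1", N6 = "N6", N3 = "N3", N7 = "N7", N9 = "N9"),
       thymine = c(N3 = "N3", O4 = "O4", O2 = "O2", C5 = "C5", C6 = "C6"))
}
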