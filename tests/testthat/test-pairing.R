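## A frame holding one adenine/thymine pair at prescribed contact
## distances: adenine W-C edge along +x, thymine stacked above it.
fixed_pair_frame <- function(dNN, dNO, cell = UnitCell(30, 30, 30)) {
  coords <- rbind(c(10, 10, 10),            # ade N1
                  c(12.34, 10, 10),         # ade N6
                  c(10, 10 + dNN, 10),      # thy N3
                  c(12.34, 10 + dNO, 10),   # thy O4
                  c(8.5, 11, 10), c(8.5, 12.3, 10))  # thy C5, C6
  list(coords = coords,
       adenines = list(NucleobaseInstance("adenine", 1L, c(N1 = 1L, N6 = 2L))),
       thymines = list(NucleobaseInstance("thymine", 2L,
                                          c(N3 = 3L, O4 = 4L, C5 = 5L,
                                            C6 = 6L))),
       cell = cell)
}

test_that("Watson-Crick detection accepts measured and DFT pair geometries", {
  ## experimentally measured A-T contact distances
  fr <- fixed_pair_frame(2.82, 2.95)
  ev <- detectWCPairs(fr$coords, fr$adenines, fr$thymines, fr$cell)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$dNN, 2.82, tolerance = 1e-9)
  expect_equal(ev$dNO, 2.95, tolerance = 1e-9)
  ## DFT-optimized geometry sits exactly on the inclusive cutoff
  ev2 <- detectWCPairs(fixed_pair_frame(2.72, 3.00)$coords, fr$adenines,
                       fr$thymines, fr$cell)
  expect_equal(nrow(ev2), 1L)
  ## just beyond the cutoff: rejected
  ev3 <- detectWCPairs(fixed_pair_frame(2.72, 3.001)$coords, fr$adenines,
                       fr$thymines, fr$cell)
  expect_equal(nrow(ev3), 0L)
  ## far thymine: no event
  ev4 <- detectWCPairs(fixed_pair_frame(10, 10)$coords, fr$adenines,
                       fr$thymines, fr$cell)
  expect_equal(nrow(ev4), 0L)
})

test_that("detection matches the all-pairs brute-force oracle", {
  cell <- UnitCell(9, 8, 10, 85, 95, 90)
  for (seed in 1:200) {
    fr <- random_base_frame(3, 3, cell, seed)
    got <- detectWCPairs(fr$coords, fr$adenines, fr$thymines, cell)
    want <- oracle_wc_pairs(fr$coords, fr$adenines, fr$thymines, cell)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      got <- got[order(got$thyId), c("adeId", "thyId", "dNN", "dNO")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("enlarging the cutoff never removes events", {
  cell <- UnitCell(9, 9, 9)
  for (seed in 1:40) {
    fr <- random_base_frame(2, 3, cell, seed)
    n1 <- nrow(detectWCPairs(fr$coords, fr$adenines, fr$thymines, cell,
                             maxHeavyDistance = 3.0))
    n2 <- nrow(detectWCPairs(fr$coords, fr$adenines, fr$thymines, cell,
                             maxHeavyDistance = 4.5))
    expect_gte(n2, n1)
  }
})

test_that("pairing frequency hits the deterministic limits", {
  ch <- buildChannel(nPeriods = 2)
  ## every guest ideally locked in every frame
  sim <- simulateTrajectory(ch, loadingPercent = 100, pPair = 1,
                            nFrames = 20, wcDistanceSd = 0,
                            jitterTranslationSd = 0, seed = 5)
  expect_equal(pairingFrequency(sim$trajectory)$statistic, 1.0)
  ## no guest ever locked: guests drift freely, essentially never pairing
  sim0 <- simulateTrajectory(ch, loadingPercent = 100, pPair = 0,
                             nFrames = 50, seed = 6)
  expect_lte(pairingFrequency(sim0$trajectory)$statistic, 0.02)
  expect_error(pairingFrequency(Trajectory(list(matrix(0, 1, 3)), 2,
                                           list(), UnitCell(5, 5, 5))),
               "no thymine")
})

test_that("planted locking probability is recovered from the trajectory", {
  ch <- buildChannel(nPeriods = 3)
  sim <- simulateTrajectory(ch, loadingPercent = 74, pPair = 0.6,
                            nFrames = 400, seed = 21)
  pf <- pairingFrequency(sim$trajectory, loadingLabel = 74)
  nDraws <- pf$nFrames * pf$nGuests
  se <- sqrt(0.6 * 0.4 / nDraws)
  expect_lt(abs(pf$statistic - 0.6), 3 * se + 1e-12)
  ## and the detector reproduces the generator's own planted fraction
  expect_equal(pf$statistic, sim$truth$plantedPairingFraction,
               tolerance = 0.01)
})

test_that("frequencies are invariant under molecule relabeling", {
  cell <- UnitCell(9, 9, 9)
  fr <- random_base_frame(3, 3, cell, 77)
  relab <- c(fr$adenines, fr$thymines)
  perm <- c(5L, 3L, 9L, 2L, 8L, 1L)
  relab <- lapply(seq_along(relab), function(i)
    NucleobaseInstance(baseKind(relab[[i]]), perm[i], roleMap(relab[[i]])))
  kinds <- vapply(relab, baseKind, character(1))
  a <- nrow(detectWCPairs(fr$coords, fr$adenines, fr$thymines, cell))
  b <- nrow(detectWCPairs(fr$coords, relab[kinds == "adenine"],
                          relab[kinds == "thymine"], cell))
  expect_equal(a, b)
})

test_that("pairing across loadings reports sorted profiles and the peak", {
  ch <- buildChannel(nPeriods = 2)
  trajs <- list(`56` = simulateTrajectory(ch, 56, 0.2, nFrames = 40,
                                          seed = 2)$trajectory,
                `25` = simulateTrajectory(ch, 25, 0.7, nFrames = 40,
                                          seed = 3)$trajectory)
  prof <- pairingVsLoading(trajs)
  expect_equal(prof$loading, c(25, 56))
  expect_equal(attr(prof, "peakLoading"), 25)
  expect_true(all(prof$statistic >= 0 & prof$statistic <= 1))
  expect_error(pairingVsLoading(list(`25` = trajs[[1]], `25` = trajs[[2]])),
               "duplicate")
})
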