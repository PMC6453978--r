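test_that("alignment angle folds parallel and antiparallel to zero", {
  expect_equal(alignmentAngle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(alignmentAngle(c(1, 0, 0), c(-3, 0, 0)), 0)
  expect_equal(alignmentAngle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(alignmentAngle(c(1, 0, 0), c(1, 1, 0)), 45)
  ## symmetry under negation and argument swap
  v <- c(0.3, -1.2, 0.5); w <- c(1.1, 0.2, -0.4)
  expect_equal(alignmentAngle(v, w), alignmentAngle(-v, w))
  expect_equal(alignmentAngle(v, w), alignmentAngle(w, v))
  expect_error(alignmentAngle(c(0, 0, 0), v), "zero-length")
})

## Two skeletal thymines with prescribed bond-midpoint separation and
## alignment angle.
two_thymine_frame <- function(midDist, angleDeg, cell = UnitCell(30, 30, 30)) {
  a <- angleDeg * pi / 180
  c5a <- c(10, 10, 10); c6a <- c5a + c(1.34, 0, 0)
  mid2 <- (c5a + c6a) / 2 + c(0, 0, midDist)
  half <- 0.67 * c(cos(a), sin(a), 0)
  coords <- rbind(c5a, c6a, mid2 - half, mid2 + half,
                  c(10, 12.3, 10), c(12, 14, 10))  # N3/O4 stand-ins
  list(coords = coords,
       thymines = list(
         NucleobaseInstance("thymine", 1L, c(N3 = 5L, O4 = 6L, C5 = 1L,
                                             C6 = 2L)),
         NucleobaseInstance("thymine", 2L, c(N3 = 6L, O4 = 5L, C5 = 3L,
                                             C6 = 4L))),
       cell = cell)
}

test_that("Schmidt and alignment rules gate dimerizable pairs", {
  fr <- two_thymine_frame(3.5, 10)
  got <- detectDimerizablePairs(fr$coords, fr$thymines, fr$cell)
  expect_equal(nrow(got), 1L)
  expect_equal(got$centerDistance, 3.5, tolerance = 1e-9)
  expect_equal(got$alignmentAngle, 10, tolerance = 1e-6)
  ## Schmidt distance violated despite perfect alignment
  expect_equal(nrow(detectDimerizablePairs(two_thymine_frame(5.0, 0)$coords,
                                           fr$thymines, fr$cell)), 0L)
  ## alignment violated inside the distance window
  expect_equal(nrow(detectDimerizablePairs(two_thymine_frame(3.0, 45)$coords,
                                           fr$thymines, fr$cell)), 0L)
  ## thresholds are strict: a pair sitting exactly on either threshold is
  ## rejected (the computed values themselves are used as the thresholds)
  expect_equal(nrow(detectDimerizablePairs(
    fr$coords, fr$thymines, fr$cell,
    maxCenterDistance = got$centerDistance)), 0L)
  expect_equal(nrow(detectDimerizablePairs(
    fr$coords, fr$thymines, fr$cell,
    maxAlignmentAngle = got$alignmentAngle)), 0L)
})

test_that("candidate screening matches the brute-force oracle", {
  cell <- UnitCell(8, 9, 10, 95, 85, 92)
  for (seed in 1:500) {
    fr <- random_base_frame(0, 2, cell, seed + 5000)
    got <- detectDimerizablePairs(fr$coords, fr$thymines, cell)
    want <- oracle_dimer_pairs(fr$coords, fr$thymines, cell)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("candidates survive thymine swap and lattice translation", {
  cell <- UnitCell(12, 12, 12)
  fr <- two_thymine_frame(3.2, 15, cell)
  got <- detectDimerizablePairs(fr$coords, fr$thymines, cell)
  swapped <- detectDimerizablePairs(fr$coords, rev(fr$thymines), cell)
  expect_equal(got, swapped)
  shifted <- detectDimerizablePairs(sweep(fr$coords, 2, c(12, -24, 12), "+"),
                                    fr$thymines, cell)
  expect_equal(got$centerDistance, shifted$centerDistance, tolerance = 1e-9)
  expect_equal(got$alignmentAngle, shifted$alignmentAngle, tolerance = 1e-9)
})

test_that("relaxing either threshold never removes a candidate", {
  cell <- UnitCell(9, 9, 9)
  for (seed in 1:40) {
    fr <- random_base_frame(0, 3, cell, seed + 900)
    tight <- detectDimerizablePairs(fr$coords, fr$thymines, cell, 4.2, 30)
    wide <- detectDimerizablePairs(fr$coords, fr$thymines, cell, 6.0, 60)
    expect_gte(nrow(wide), nrow(tight))
    key <- function(d) paste(d$thyIdLow, d$thyIdHigh)
    expect_true(all(key(tight) %in% key(wide)))
  }
})

test_that("readiness frequency hits its deterministic limits", {
  ## two guests frozen in the ready motif every frame
  ch <- buildChannel(nPeriods = 1)
  sim <- simulateTrajectory(ch, loadingPercent = 100, pPair = 1,
                            nFrames = 15, wcDistanceSd = 0,
                            jitterTranslationSd = 0, seed = 9,
                            capacityPerPeriod = 2)
  expect_equal(sim$truth$nGuests, 2L)
  expect_equal(dimerizabilityFrequency(sim$trajectory)$statistic, 1.0)
  ## a single isolated guest can never form a pair
  one <- simulateTrajectory(ch, loadingPercent = 50, pPair = 0,
                            nFrames = 10, seed = 10)
  expect_equal(one$truth$nGuests, 1L)
  expect_equal(dimerizabilityFrequency(one$trajectory)$statistic, 0.0)
})

test_that("the joint pairing+readiness window recovers the planted peak", {
  ch <- buildChannel(nPeriods = 4)
  suite <- makeLoadingSuite(ch, nFrames = 120, seed = 11)
  trajs <- lapply(suite, `[[`, "trajectory")
  pair <- pairingVsLoading(trajs)
  ready <- dimerizabilityVsLoading(trajs)
  expect_equal(attr(pair, "peakLoading"), 44)
  win <- predictDimerizationWindow(pair, ready, minPairing = 0.65,
                                   minReadiness = 0.06)
  expect_equal(win, 44)
  ## degenerate thresholds
  expect_equal(predictDimerizationWindow(pair, ready, 0, 0),
               c(25, 44, 56, 74, 100))
  expect_equal(length(predictDimerizationWindow(pair, ready, 1.1, 1.1)), 0L)
  expect_error(predictDimerizationWindow(pair, ready[-1, ], 0, 0),
               "different loadings")
})
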