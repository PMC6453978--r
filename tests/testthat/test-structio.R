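test_that("cell volume matches the triclinic formula and printed constants", {
  expect_equal(round(cellVolume(UnitCell(10.7402, 30.6236, 42.6282)), 1),
               14020.6)
  expect_equal(cellVolume(UnitCell(1, 1, 1)), 1.0)
  ## independent oracle: triple product of explicitly constructed lattice
  ## vectors
  cl <- UnitCell(2, 3, 4, 60, 70, 80)
  M <- cellMatrix(cl)
  expect_equal(cellVolume(cl), abs(det(M)), tolerance = 1e-12)
  ## invariant under cyclic permutation of (a,alpha),(b,beta),(c,gamma)
  expect_equal(cellVolume(UnitCell(3, 4, 2, 70, 80, 60)), cellVolume(cl),
               tolerance = 1e-12)
  expect_equal(cellVolume(UnitCell(4, 2, 3, 80, 60, 70)), cellVolume(cl),
               tolerance = 1e-12)
})

test_that("unit cell validity rejects degenerate parameters", {
  expect_error(UnitCell(-1, 1, 1), "positive")
  expect_error(UnitCell(1, 1, 1, 0, 90, 90), "angles")
  expect_error(UnitCell(1, 1, 1, 179, 179, 179), "volume")
})

test_that("minimum-image distance agrees with exhaustive image search", {
  cube <- UnitCell(10, 10, 10)
  expect_equal(minimumImageDistance(c(1, 2, 3), c(1, 2, 3), cube), 0)
  expect_equal(minimumImageDistance(c(1, 0, 0), c(9, 0, 0), cube), 2.0)
  tric <- UnitCell(7, 9, 8, 75, 100, 85)
  M <- cellMatrix(tric)
  set.seed(11)
  for (i in 1:50) {
    p <- as.numeric(runif(3, -1, 2) %*% M)
    q <- as.numeric(runif(3, -1, 2) %*% M)
    d <- minimumImageDistance(p, q, tric)
    expect_equal(d, oracle_min_dist(p, q, tric), tolerance = 1e-10)
    ## symmetric, bounded by the direct distance
    expect_equal(minimumImageDistance(q, p, tric), d, tolerance = 1e-12)
    expect_lte(d, sqrt(sum((p - q)^2)) + 1e-12)
  }
})

test_that("CIF read expands symmetry and round-trips coordinates", {
  cif <- tempfile(fileext = ".cif")
  writeLines(c("data_test",
               "_cell_length_a 10.0", "_cell_length_b 10.0",
               "_cell_length_c 10.0", "_cell_angle_alpha 90",
               "_cell_angle_beta 90", "_cell_angle_gamma 90",
               "loop_", "_symmetry_equiv_pos_as_xyz", "'x, y, z'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z",
               "Zn1 Zn 0.0 0.0 0.0"), cif)
  s <- readStructure(cif)
  expect_equal(length(siteElements(s)), 1L)
  expect_equal(cellVolume(structureCell(s)), 1000)
  expect_equal(siteElements(s), "Zn")

  ## a twofold operator doubles the site count
  cif2 <- tempfile(fileext = ".cif")
  writeLines(c("data_test",
               "_cell_length_a 10.0", "_cell_length_b 10.0",
               "_cell_length_c 10.0", "_cell_angle_alpha 90",
               "_cell_angle_beta 90", "_cell_angle_gamma 90",
               "loop_", "_symmetry_equiv_pos_as_xyz",
               "'x, y, z'", "'-x, 1/2+y, -z'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z",
               "C1 C 0.1 0.2 0.3"), cif2)
  s2 <- readStructure(cif2)
  expect_equal(length(siteElements(s2)), 2L)
  frac <- cartesianToFractional(siteCoords(s2), structureCell(s2))
  expect_equal(sort(frac[, 1]), c(0.1, 0.9), tolerance = 1e-9)
  expect_equal(sort(frac[, 2]), c(0.2, 0.7), tolerance = 1e-9)

  ## read -> write -> read round trip preserves cell and coordinates
  out <- tempfile(fileext = ".cif")
  writeStructure(s2, out)
  s3 <- readStructure(out)
  expect_equal(cellMatrix(structureCell(s3)), cellMatrix(structureCell(s2)),
               tolerance = 1e-6)
  expect_equal(siteCoords(s3), siteCoords(s2), tolerance = 1e-6)
})

test_that("structure I/O round-trips through XYZ and PDB", {
  cell <- UnitCell(12, 13, 14)
  s <- PeriodicStructure(cell, c("C", "N", "O"),
                         rbind(c(1, 2, 3), c(4.123456, 5, 6), c(7, 8, 9.5)))
  for (ext in c(".xyz", ".pdb")) {
    f <- tempfile(fileext = ext)
    writeStructure(s, f)
    r <- readStructure(f)
    expect_equal(siteCoords(r), siteCoords(s), tolerance = 1e-3)
    expect_equal(siteElements(r), siteElements(s))
    expect_equal(cellMatrix(structureCell(r)), cellMatrix(cell),
                 tolerance = 1e-3)
  }
  ## XYZ keeps full precision
  f <- tempfile(fileext = ".xyz")
  writeStructure(s, f)
  expect_equal(siteCoords(readStructure(f)), siteCoords(s), tolerance = 1e-6)
})

test_that("malformed inputs produce explicit errors", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("0", "empty"), f)
  expect_error(readStructure(f), "empty structure")
  f2 <- tempfile(fileext = ".xyz")
  writeLines(c("1", 'Lattice="10 0 0 0 10 0 0 0 10"', "Qq 0 0 0"), f2)
  expect_error(readStructure(f2), "Qq")
  f3 <- tempfile(fileext = ".cif")
  writeLines("data_nothing", f3)
  expect_error(readStructure(f3), "cell parameters")
})

test_that("trajectory I/O preserves frames and rejects a changing cell", {
  cell <- UnitCell(10, 11, 12)
  frames <- list(matrix(runif(9, 0, 9), 3), matrix(runif(9, 0, 9), 3))
  tr <- Trajectory(frames, 2, list(), cell, elements = c("C", "N", "O"))
  f <- tempfile(fileext = ".xyz")
  writeTrajectory(tr, f)
  r <- readTrajectory(f, frameInterval = 2)
  expect_equal(nFrames(r), 2L)
  expect_equal(getFrame(r, 2), getFrame(tr, 2), tolerance = 1e-6)
  expect_equal(frameInterval(r), 2)

  lines <- readLines(f)
  lines[7] <- 'Lattice="99 0 0 0 11 0 0 0 12"'
  writeLines(lines, f)
  expect_error(readTrajectory(f, 2), "cell changes")

  fp <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, fp)
  rp <- readTrajectory(fp, 2)
  expect_equal(nFrames(rp), 2L)
  expect_equal(getFrame(rp, 1), getFrame(tr, 1), tolerance = 1e-3)
})

test_that("nucleobase role assignment resolves labels and reports gaps", {
  labels <- c("N1", "C2", "N3", "C4", "C5", "C6", "O2", "O4", "C7")
  thy <- assignNucleobases(labels, list(1:9), role_templates(),
                           baseKinds = "thymine")
  expect_length(thy, 1L)
  expect_equal(unname(roleMap(thy[[1]])[c("N3", "O4", "C5", "C6")]),
               c(3L, 8L, 5L, 6L))
  ## missing required role
  expect_error(assignNucleobases(labels[-6], list(1:8), role_templates(),
                                 baseKinds = "thymine"), "C6 unresolved")
  ## duplicated label within a molecule is ambiguous
  expect_error(assignNucleobases(c(labels, "N3"), list(1:10),
                                 role_templates(), baseKinds = "thymine"),
               "ambiguous")
  ## drop mode reports unassigned silently
  expect_length(assignNucleobases(labels[-6], list(1:8), role_templates(),
                                  baseKinds = "thymine",
                                  onUnassigned = "drop"), 0L)
})

test_that("role configs round-trip through JSON", {
  topo <- list(NucleobaseInstance("adenine", 1L, c(N1 = 3L, N6 = 7L)),
               NucleobaseInstance("thymine", 2L,
                                  c(N3 = 11L, O4 = 12L, C5 = 13L, C6 = 14L)))
  f <- tempfile(fileext = ".json")
  writeRoleConfig(topo, f)
  back <- readRoleConfig(f)
  expect_equal(length(back), 2L)
  expect_equal(roleMap(back[[1]]), roleMap(topo[[1]]))
  expect_equal(baseKind(back[[2]]), "thymine")
  expect_equal(roleMap(back[[2]]), roleMap(topo[[2]]))
})
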