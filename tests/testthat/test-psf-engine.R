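## Multiplexed PSF engine: tiling, refocus, equivalence with the
## sequential oracle, and the Zernike machinery.

test_that("a single-tile multiplexed field equals the plain point source", {
  g <- Grid3D(32, 32, 16, dx = 0.15)
  lay <- tileLayout(1, 1, 32, g, planeZ = 0)
  pup <- detectionPupil()
  mux <- multiplexedSourceField(lay, pup, g, sourceFill = "uniform")
  single <- makeField(SourceSpec("point_source", pup,
                                 focus = c(lay@sourcePositions[1, 1],
                                           lay@sourcePositions[1, 2], 0)), g)
  expect_lt(relL2(mux@values, single@values), 1e-12)
})

test_that("layouts reject tiles that exceed the grid or touch", {
  g <- Grid3D(32, 32, 16, dx = 0.15)
  expect_error(tileLayout(4, 4, 16, g, 0), "layout-error")
  lay <- tileLayout(2, 2, 16, g, 0)
  lay@sourcePositions[2, 1] <- lay@sourcePositions[1, 1] + 0.3
  expect_error(multiplexedSourceField(lay, detectionPupil(), g),
               "layout-error")
})

test_that("vacuum PSFs are translation invariant across tiles", {
  g <- Grid3D(64, 64, 24, dx = 0.15)
  lay <- tileLayout(2, 2, 32, g, planeZ = 4 * 0.15)
  ps <- quietly(computePSFSet(RefractiveVolume(g), 4 * 0.15, lay,
                              detectionPupil(), zOffsets = (-2:2) * g@dz))
  for (t in 2:4)
    expect_lt(relL2(ps@psfs[[t]], ps@psfs[[1]]), 1e-6)
  ## stored PSFs integrate to one, collected power below source power
  for (t in 1:4) {
    expect_equal(sum(ps@psfs[[t]]), 1, tolerance = 1e-9)
    expect_lte(ps@rawIntegrals[t], 1 + 1e-6)
  }
  expect_lt(max(ps@crosstalk), 0.01)
})

test_that("multiplexed equals sequential in vacuum and degrades gracefully in tissue", {
  g <- Grid3D(64, 64, 32, dx = 0.3)
  pup <- detectionPupil()
  lay <- tileLayout(2, 2, 32, g, planeZ = 4 * 0.3)
  zo <- (-2:2) * g@dz

  worstFor <- function(vol) {
    ps <- quietly(computePSFSet(vol, 4 * 0.3, lay, pup, zOffsets = zo))
    worst <- 0
    for (t in 1:4) {
      sq <- quietly(sequentialPSF(vol, lay@sourcePositions[t, ], pup,
                                  tileSize = 32, zOffsets = zo))
      worst <- max(worst, relL2(ps@psfs[[t]], sq$psf))
    }
    worst
  }
  ## vacuum: the tiling machinery itself is exact to the tile-leak level
  expect_lt(worstFor(RefractiveVolume(g)), 1e-4)
  ## tissue: cross-talk from scattered neighbor light grows with contrast
  w1 <- worstFor(makePerlinTissue(g, 1.36, 0.002, 2, seed = 5)@refractive)
  w2 <- worstFor(makePerlinTissue(g, 1.36, 0.01, 2, seed = 5)@refractive)
  expect_lt(w1, w2)
  expect_lt(w2, 0.1)
})

test_that("raw integrals decrease monotonically with depth in an absorbing medium", {
  g <- Grid3D(48, 48, 40, dx = 0.2)
  n <- array(complex(real = 1.33, imaginary = 5e-4), c(48, 48, 40))
  vol <- RefractiveVolume(g, n)
  pup <- detectionPupil()
  raws <- vapply(c(2, 10, 18) * 0.2, function(z) {
    lay <- tileLayout(1, 1, 32, g, planeZ = z)
    ps <- quietly(computePSFSet(vol, z, lay, pup, zOffsets = 0))
    ps@rawIntegrals[1]
  }, numeric(1))
  ## deeper focal plane = shorter absorbing path to the detector
  expect_true(all(diff(raws) > 0))
})

test_that("ideal lens refocus: NA crop and band-limited identity", {
  g <- Grid3D(48, 48, 16, dx = 0.15)
  pup <- detectionPupil(na = 0.6)
  u <- makeField(SourceSpec("point_source", pup, focus = c(3.6, 3.6, 1.5)), g)
  ## an aperture wider than the immersion cone is rejected at construction
  expect_error(PupilSpec(1.4, 0.5, nImmersion = 1.33), "nImmersion")
  expect_error(idealLensRefocus(u, pup, c(-2, 0), 3,
                                nImmersion = 0.5), "invalid-parameter")
  ## field already inside the NA: crop is the identity, stack equals plain
  ## back-propagation
  rf <- idealLensRefocus(u, pup, c(-1.5, -1.5), 1, keepFields = TRUE)
  direct <- LightSheetSim:::stepField(u@values, 0.15, 0.15, 0.5, -1.5, 1.33,
                                      "zero")
  expect_lt(relL2(rf$fields[, , 1], direct), 1e-10)
})

test_that("Zernike decomposition: round trip, defocus and tilt selectivity", {
  pup <- PupilSpec(0.5, 0.522)
  set.seed(3)
  co <- c(0, runif(14, -0.4, 0.4))
  fit <- zernikeDecompose(zernikePhaseMap(co, 96), pup)
  expect_lt(sqrt(mean((fit$coefficients - co)^2)), 1e-8)

  flat <- zernikeDecompose(matrix(0, 64, 64), pup)
  expect_lt(max(abs(flat$coefficients)), 1e-10)

  defoc <- zernikeDecompose(zernikePhaseMap(c(0, 0, 0, 0.3), 96), pup)
  expect_equal(unname(defoc$coefficients[4]), 0.3, tolerance = 1e-8)
  expect_lt(max(abs(defoc$coefficients[-4])), 1e-8)

  tilt <- zernikeDecompose(zernikePhaseMap(c(0, 0, 0.25), 96), pup)
  expect_equal(unname(tilt$coefficients[3]), 0.25, tolerance = 1e-8)
  expect_lt(max(abs(tilt$coefficients[-3])), 1e-8)
})

test_that("Zernike maps of a vacuum PSF set carry no aberration beyond piston/defocus noise", {
  g <- Grid3D(64, 64, 24, dx = 0.15)
  lay <- tileLayout(2, 2, 32, g, planeZ = 4 * 0.15)
  ps <- quietly(computePSFSet(RefractiveVolume(g), 4 * 0.15, lay,
                              detectionPupil(), zOffsets = (-1:1) * g@dz,
                              keepExitFields = TRUE))
  zm <- zernikeMap(ps, detectionPupil())
  hi <- subset(zm@coefficients, j >= 5)
  expect_lt(max(abs(hi$coefficient)), 0.05)
})
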