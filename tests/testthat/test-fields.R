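## Input-field catalogue: pupil synthesis, focusing, band limits,
## normalization and the incoherent plane-wave set.

test_that("plane wave source is uniform with unit power", {
  g <- Grid3D(32, 32, 16, dx = 0.2)
  u <- makeField(SourceSpec("plane_wave",
                            PupilSpec(na = 0.3, wavelength = 0.5)), g)
  expect_lt(diff(range(Mod(u@values))), 1e-14)
  expect_lt(max(abs(diff(Arg(u@values[, 1])))), 1e-14)
  expect_equal(fieldPower(u), 1, tolerance = 1e-12)
})

test_that("generated fields have unit power and live inside their NA disk", {
  g <- Grid3D(64, 64, 32, dx = 0.1)
  kinds <- list(
    list(kind = "point_source", pup = PupilSpec(0.6, 0.5)),
    list(kind = "gaussian", pup = PupilSpec(0.4, 0.5)),
    list(kind = "cylindrical_sheet", pup = PupilSpec(0.15, 0.5)),
    list(kind = "bessel", pup = PupilSpec(0.4, 0.5, kind = "annulus",
                                          innerNa = 0.32)),
    list(kind = "bessel_lattice", pup = PupilSpec(0.4, 0.5, kind = "lattice")))
  kg <- LightSheetSim:::kGrids(64, 64, 0.1, 0.1)
  krm <- sqrt(outer(kg$kx^2, rep(1, 64)) + outer(rep(1, 64), kg$ky^2))
  for (ks in kinds) {
    u <- makeField(SourceSpec(ks$kind, ks$pup, focus = c(3.2, 3.2, 1.6)), g)
    expect_equal(fieldPower(u), 1, tolerance = 1e-12)
    spec <- Mod(LightSheetSim:::fft2(u@values))
    out <- spec[krm > 2 * pi / 0.5 * ks$pup@na * (1 + 1e-9)]
    expect_lt(max(out) / max(spec), 1e-10)
  }
})

test_that("point source focuses to the scalar diffraction-limited width", {
  g <- Grid3D(64, 64, 24, dx = 0.1)
  u0 <- makeField(SourceSpec("point_source", PupilSpec(0.6, 0.5),
                             focus = c(3.2, 3.2, 1.2)), g)
  out <- propagate(u0, RefractiveVolume(g), PropagatorConfig(storeVolume = TRUE))
  I <- Mod(out$record)^2
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  ## peaks within one axial voxel of the focus position
  expect_lte(abs(pk[3] - 12L), 1L)
  expect_equal(unname(pk[1:2]), c(33L, 33L))
  x <- (seq_len(64) - 1) * 0.1
  fw <- LightSheetSim:::profileFwhm(x, I[, pk[2], pk[3]])
  expect_lt(abs(fw - 0.51 * 0.5 / 0.6) / (0.51 * 0.5 / 0.6), 0.05)
})

test_that("cylindrical sheet is invariant along the sheet axis with the right waist", {
  g <- Grid3D(128, 64, 32, dx = 0.2)
  u <- makeField(SourceSpec("cylindrical_sheet", PupilSpec(0.1, 0.5),
                            focus = c(12.8, 6.4, 3.2)), g)
  ## invariant along y
  vy <- apply(Mod(u@values), 1, function(r) diff(range(r)))
  expect_lt(max(vy) / max(Mod(u@values)), 1e-6)
  ## focus the sheet in vacuum and measure the waist along x
  v <- quietly(freeSpaceStep(u, 3.2, 1.33))
  x <- (seq_len(128) - 1) * 0.2
  fw <- LightSheetSim:::profileFwhm(x, Mod(v@values[, 32])^2)
  ## uniform 1D pupil: sinc^2 focus, FWHM = 0.886 * lambda / (2 NA)
  th <- 0.886 * 0.5 / (2 * 0.1)
  expect_lt(abs(fw - th) / th, 0.10)
})

test_that("Bessel beam profile follows J0^2 over the first rings", {
  g <- Grid3D(128, 128, 16, dx = 0.1)
  pup <- PupilSpec(0.4, 0.5, kind = "annulus", innerNa = 0.36)
  u <- makeField(SourceSpec("bessel", pup, focus = c(6.4, 6.4, 0)), g)
  I <- Mod(u@values)^2
  prof <- I[65:96, 65] / I[65, 65]
  r <- (0:31) * 0.1
  kbar <- 2 * pi / 0.5 * (0.4 + 0.36) / 2
  th <- besselJ(kbar * r, 0)^2
  ## first three rings: out to the third zero of J0
  sel <- r <= 8.654 / kbar
  expect_lt(sqrt(mean((prof[sel] - th[sel])^2)), 0.05)
})

test_that("Bessel lattice repeats with the configured period", {
  g <- Grid3D(64, 256, 16, dx = 0.1)
  pup <- PupilSpec(0.4, 0.5, kind = "lattice", period = 3.2, count = 5L)
  u <- makeField(SourceSpec("bessel_lattice", pup, focus = c(3.2, 12.8, 0)), g)
  I <- Mod(u@values)^2
  prof <- I[33, ]
  ## intensity peaks 3.2 um (32 px) apart
  pk <- which(prof == max(prof))[1]
  expect_gt(prof[pk + 32L] / prof[pk], 0.6)
  expect_gt(prof[pk - 32L] / prof[pk], 0.6)
})

test_that("sampling and focus-position preconditions are enforced", {
  g <- Grid3D(32, 32, 16, dx = 0.5)
  expect_error(makeField(SourceSpec("point_source", PupilSpec(0.6, 0.5)), g),
               "sampling-error")
  g2 <- Grid3D(32, 32, 16, dx = 0.2)
  expect_error(makeField(SourceSpec("point_source", PupilSpec(0.6, 0.5),
                                    focus = c(3.2, 3.2, 50)), g2),
               "invalid-parameter")
})

test_that("incoherent plane-wave set: trivial case, tilt bound, determinism", {
  g <- Grid3D(48, 48, 16, dx = 0.25)
  one <- incoherentPlaneWaveSet(0, 1, seed = 5, g, wavelength = 0.5)
  expect_length(one, 1L)
  expect_lt(diff(range(Arg(one[[1]]@values))), 1e-12)

  set100 <- incoherentPlaneWaveSet(0.001, 100, seed = 5, g, wavelength = 0.47,
                                   nImmersion = 1.0)
  k0 <- 2 * pi / 0.47
  for (f in set100) {
    kx <- Arg(f@values[2, 1] / f@values[1, 1]) / 0.25
    ky <- Arg(f@values[1, 2] / f@values[1, 1]) / 0.25
    ## all tilt angles inside the stated NA cone
    expect_lte(asin(sqrt(kx^2 + ky^2) / k0), asin(0.001) + 1e-9)
  }

  again <- incoherentPlaneWaveSet(0.001, 100, seed = 5, g, wavelength = 0.47,
                                  nImmersion = 1.0)
  expect_identical(lapply(set100, fieldValues), lapply(again, fieldValues))
})
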