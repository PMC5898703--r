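## Split-step propagation engine: analytic eigenmodes, closed-form beams,
## brute-force diffraction oracle, conservation and reciprocity.

test_that("free-space step handles trivial cases and rejects bad input", {
  u <- planeWaveField(32, 32, dx = 0.18, wavelength = 0.5)
  expect_identical(freeSpaceStep(u, 0, 1.33)@values, u@values)

  v <- freeSpaceStep(u, dz = 3, n0 = 1.33)
  ## plane wave is an eigenmode: uniform intensity, global phase n0*k0*dz
  expect_lt(max(abs(Mod(v@values)^2 - 1)), 1e-12)
  phase <- Arg(v@values[1, 1] / u@values[1, 1])
  expect_lt(Mod(exp(1i * phase) - exp(1i * 2 * pi / 0.5 * 1.33 * 3)), 1e-12)

  expect_error(freeSpaceStep(u, 1, -1), "positive")
  bad <- u; bad@values[1, 1] <- NaN + 0i
  expect_error(freeSpaceStep(bad, 1, 1.33), "NaN")
  expect_warning(freeSpaceStep(planeWaveField(16, 16, dx = 0.4,
                                              wavelength = 0.5), 1, 1.33),
                 "sampling")
})

test_that("Gaussian beam width follows the closed form within 2%", {
  w0 <- 2; lam <- 0.5; nx <- 256L; dx <- 0.15
  u <- gaussianWaistField(nx, dx, w0, lam)
  x <- (seq_len(nx) - 1) * dx
  for (z in c(10, 20, 40)) {
    v <- freeSpaceStep(u, z, 1.0)
    fw <- LightSheetSim:::profileFwhm(x, Mod(v@values[, nx / 2 + 1])^2)
    th <- gaussianBeamWidth(z, w0, lam, 1)$fwhm
    expect_lt(abs(fw - th) / th, 0.02)
  }
})

test_that("angular spectrum matches direct Rayleigh-Sommerfeld summation", {
  nx <- 64L; dx <- 0.4; lam <- 0.5
  u <- softApertureField(nx, dx, 2.5, lam)
  vd <- directDiffraction(u, 30, 1.0)
  ## embed in a larger window so the periodic replicas stay out of frame
  pad <- 256L
  big <- matrix(0i, pad, pad)
  big[1:nx, 1:nx] <- u@values
  vb <- quietly(freeSpaceStep(ComplexField(big, dx, dx, lam), 30, 1.0))
  expect_lt(relL2(vb@values[1:nx, 1:nx], vd@values), 1e-3)
})

test_that("phase screen acts pointwise: identity, slab phase, Beer-Lambert", {
  u <- planeWaveField(24, 24, dx = 0.15, wavelength = 0.5)
  n0 <- 1.33
  same <- phaseScreenStep(u, matrix(n0 + 0i, 24, 24), n0, 0.5)
  expect_identical(same@values, u@values)

  ## uniform slab of contrast 0.05 accumulated over steps: total on-axis
  ## phase delay k0 * dn * d
  dn <- 0.05; d <- 4; nSteps <- 16L
  v <- u
  for (i in seq_len(nSteps))
    v <- phaseScreenStep(v, matrix(n0 + dn + 0i, 24, 24), n0, d / nSteps)
  k0 <- 2 * pi / 0.5
  expect_lt(Mod(exp(1i * Arg(v@values[1, 1])) - exp(1i * k0 * dn * d)), 1e-12)

  kap <- 2e-3; dz <- 0.8
  a <- phaseScreenStep(u, matrix(complex(real = n0, imaginary = kap),
                                 24, 24), n0, dz)
  expect_lt(max(abs(Mod(a@values) - exp(-k0 * kap * dz))), 1e-14)

  expect_error(phaseScreenStep(u, matrix(n0 + 0i, 12, 24), n0, 0.5),
               "shape")
})

test_that("homogeneous propagate reduces exactly to chained free-space steps", {
  g <- Grid3D(24, 24, 10, dx = 0.18)
  vol <- RefractiveVolume(g)
  u0 <- planeWaveField(24, 24, dx = 0.18, wavelength = 0.5)
  out <- propagate(u0, vol)
  v <- u0
  for (i in seq_len(2L * g@nz)) v <- freeSpaceStep(v, g@dz / 2, 1.33)
  expect_identical(out$field@values, v@values)
})

test_that("lossless media conserve non-evanescent power per plane", {
  ## dx <= lambda/(2 max(n)) so the full propagating circle fits the band,
  ## and a band-limited medium (anti-alias sigma 2 voxels) so no medium
  ## spectral tails leak past it
  g <- Grid3D(64, 64, 48, dx = 0.15)
  ph <- makePerlinTissue(g, meanN = 1.36, amplitude = 0.03,
                         correlationLength = 2, seed = 6, aaSigmaVox = 2)
  out <- propagate(planeWaveField(64, 64, dx = 0.15, wavelength = 0.5),
                   ph@refractive)
  pp <- out$planePowers
  settle <- pp[8:length(pp)]
  expect_lt(max(abs(diff(settle)) / settle[1]), 1e-8)
  ## power never increases
  expect_true(all(diff(out$planePowers) < 1e-10 * pp[1]))
})

test_that("exact propagator agrees with the paraxial kernel for low-NA beams", {
  nx <- 128L; dx <- 0.5; lam <- 0.5; n0 <- 1.33
  ## NA ~ 0.016 beam: w0 = lam/(pi*NA) = 10 um
  u <- gaussianWaistField(nx, dx, 10, lam)
  v <- quietly(freeSpaceStep(u, 100, n0))
  ## test-local Fresnel (paraxial) kernel
  kg <- LightSheetSim:::kGrids(nx, nx, dx, dx)
  k <- n0 * 2 * pi / lam
  kr2 <- outer(kg$kx^2, rep(1, nx)) + outer(rep(1, nx), kg$ky^2)
  Hf <- exp(1i * 100 * (k - kr2 / (2 * k)))
  vf <- LightSheetSim:::ifft2(LightSheetSim:::fft2(u@values) * Hf)
  expect_lt(relL2(v@values, vf), 1e-4)
})

test_that("forward-conjugate-backward reproduces the source field", {
  g <- Grid3D(64, 64, 16, dx = 0.2)
  vol <- makePerlinTissue(g, meanN = 1.36, amplitude = 0.01,
                          correlationLength = 1.5, seed = 9)@refractive
  u0 <- makeField(SourceSpec("point_source", detectionPupil(na = 0.5),
                             focus = c(6.4, 6.4, 0)), g)
  fw <- propagate(u0, vol)$field
  bk <- propagate(ComplexField(Conj(fw@values), 0.2, 0.2, 0.5),
                  LightSheetSim:::reverseVolume(vol))$field
  expect_lt(relL2(Conj(bk@values), u0@values), 1e-6)
})

test_that("absorbing frame drains power at the boundary, conservation tests can disable it", {
  g <- Grid3D(48, 48, 24, dx = 0.2)
  vol <- RefractiveVolume(g)
  ## tilted beam walking into the frame
  pup <- PupilSpec(na = 0.3, wavelength = 0.5, tilt = c(3, 0))
  u0 <- makeField(SourceSpec("gaussian", pup, focus = c(4.8, 4.8, 0)), g)
  pAbs <- propagate(u0, vol, PropagatorConfig(boundary = "absorbing"))$planePowers
  pPer <- propagate(u0, vol, PropagatorConfig(boundary = "periodic"))$planePowers
  expect_lt(pAbs[g@nz], pPer[g@nz] - 1e-4)
  expect_lt(abs(pPer[g@nz] - pPer[1]), 1e-8 * pPer[1])
})

test_that("volume reorientation is an involution and permutes pitches", {
  g <- Grid3D(8, 12, 16, dx = 0.5, dy = 0.4, dz = 0.3)
  set.seed(1)
  vol <- RefractiveVolume(g, array(complex(real = runif(8 * 12 * 16, 1.3, 1.4),
                                           imaginary = 0), c(8, 12, 16)))
  vx <- reorientVolume(vol, "x")
  expect_equal(c(vx@grid@nx, vx@grid@ny, vx@grid@nz), c(16, 12, 8))
  expect_equal(c(vx@grid@dx, vx@grid@dy, vx@grid@dz), c(0.3, 0.4, 0.5))
  back <- reorientVolume(vx, "x")
  expect_identical(back@n, vol@n)
})
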