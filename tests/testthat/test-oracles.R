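## Analytic oracles: these are validated against their own limiting cases
## so the engine tests that rely on them rest on independently checked
## references.

test_that("scalar Mie series has the correct limits and self-converges", {
  xs <- seq(-3, 3, length.out = 17)
  ## m -> 1: total field reduces to the incident plane wave
  sp1 <- MieSpec(2.5, 1 + 1e-9, 0.5, 1.33)
  u <- mieNearField(sp1, xs, xs, 5)
  expect_lt(max(Mod(u - exp(1i * 2 * pi / 0.5 * 1.33 * 5))), 1e-6)

  ## doubling the truncation order changes nothing
  sp <- quietly(MieSpec(2.5, 1.0376, 0.5, 1.33))
  u1 <- mieNearField(sp, xs, xs, 5)
  u2 <- mieNearField(sp, xs, xs, 5,
                     nMax = 2L * LightSheetSim:::mieNMax(2 * pi / 0.5 * 1.33 * 2.5))
  expect_lt(max(Mod(u1 - u2)), 1e-8)

  ## r -> 0: vanishing scattered energy (b_0 ~ (m-1) x^3 for size
  ## parameter x = k r = 0.17 here)
  spSmall <- quietly(MieSpec(0.01, 1.05, 0.5, 1.33))
  uS <- mieNearField(spSmall, xs, xs, 5)
  expect_lt(max(Mod(uS - exp(1i * 2 * pi / 0.5 * 1.33 * 5))), 1e-5)

  ## out-of-regime contrast warns
  expect_warning(MieSpec(1, 1.5, 0.5), "regime")
})

test_that("vector Mie far field: Rayleigh limit, efficiencies, coated spheres", {
  ## Rayleigh limit: unpolarized phase function -> (1 + cos^2)/2
  ## (finite-size corrections are O(x^2) ~ 2.5e-3 at x = 0.05)
  pR <- miePhaseFunction(quietly(MieSpec(0.003, 1.05, 0.5, 1.33)))
  expect_lt(max(abs(pR$p - (1 + cos(pR$theta)^2) / 2)), 0.01)

  ## Q_sca -> 0 as m -> 1
  expect_lt(miePhaseFunction(quietly(MieSpec(1, 1 + 1e-7, 0.5)))$Qsca, 1e-9)

  ## coated sphere with equal indices reduces to the solid sphere
  pS <- miePhaseFunction(quietly(MieSpec(1, 1.05, 0.5, 1.33)))
  pC <- miePhaseFunction(quietly(MieSpec(1, 1.05, 0.5, 1.33,
                                         coreRadius = 0.5,
                                         mCore = 1.05 + 1e-8)))
  expect_lt(abs(pS$Qsca - pC$Qsca) / pS$Qsca, 1e-5)
  expect_lt(max(abs(pS$p - pC$p)), 1e-5)

  ## the coated cell model of the validation figures evaluates finitely
  pP <- MieSpec(5, 1.04, 0.5, 1.33, coreRadius = 4, mCore = 1.02)
  out <- miePhaseFunction(pP)
  expect_true(all(is.finite(out$p)) && out$Qsca > 0)
})

test_that("Fresnel knife edge reproduces the classic limiting values", {
  ## edge line carries I = 1/4
  expect_equal(fresnelKnifeEdge(0, 30, 0.47), 0.25, tolerance = 1e-6)
  ## lit side tends to 1, shadow to 0
  expect_lt(abs(mean(fresnelKnifeEdge(seq(40, 60, 0.5), 30, 0.47)) - 1), 0.02)
  expect_lt(fresnelKnifeEdge(-30, 30, 0.47), 1e-3)
})

test_that("BPM edge diffraction matches the Fresnel integral", {
  ## in the paraxial regime (100 um depth) the closed form holds to < 2%
  ke <- LightSheetSim:::knifeEdgeComparison(depth = 100)
  expect_lt(ke$relL2, 0.02)
  ## at 30 um the Fresnel approximation itself drifts; derived bound 5%
  ke30 <- LightSheetSim:::knifeEdgeComparison(depth = 30)
  expect_lt(ke30$relL2, 0.05)
})

test_that("direct diffraction oracle: identity, phase advance, size guard", {
  u <- softApertureField(32, 0.4, 2, 0.5)
  expect_identical(directDiffraction(u, 0, 1.0)@values, u@values)
  ## on-axis phase of a broad Gaussian advances by k z minus the Gouy
  ## phase (a hard-truncated uniform patch is NOT a plane wave: its edge
  ## wave perturbs the center at the 0.2 level)
  w0 <- 4; z <- 10
  ug <- gaussianWaistField(64, 0.4, w0, 0.5)
  vg <- directDiffraction(ug, z, 1.0)
  zR <- pi * w0^2 / 0.5
  c0 <- 33L
  expect_lt(Mod(exp(1i * Arg(vg@values[c0, c0])) -
                exp(1i * (2 * pi / 0.5 * z - atan(z / zR)))), 1e-3)
  expect_lt(abs(Mod(vg@values[c0, c0]) * sqrt(1 + (z / zR)^2) - 1), 1e-3)
  expect_error(directDiffraction(ComplexField(matrix(0i, 128, 128), 0.2, 0.2,
                                              0.5), 1, 1), "64")
})

test_that("sequential PSF oracle gives a diffraction-limited vacuum focus", {
  g <- Grid3D(64, 64, 24, dx = 0.15)
  vol <- RefractiveVolume(g)
  pup <- detectionPupil(na = 0.6)
  sq <- quietly(sequentialPSF(vol, c(4.8, 4.8, 4 * 0.15), pup, tileSize = 32,
                              zOffsets = 0, sourceFill = "uniform"))
  prof <- sq$psf[, 17, 1]
  x <- (seq_len(32) - 1) * 0.15
  fw <- LightSheetSim:::profileFwhm(x, prof)
  expect_lt(abs(fw - 0.51 * 0.5 / 0.6) / (0.51 * 0.5 / 0.6), 0.05)
  ## deterministic
  sq2 <- quietly(sequentialPSF(vol, c(4.8, 4.8, 4 * 0.15), pup,
                               tileSize = 32, zOffsets = 0,
                               sourceFill = "uniform"))
  expect_identical(sq$psf, sq2$psf)
})
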