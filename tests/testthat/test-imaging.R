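## Image formation: excitation volumes, the spatially varying convolution
## against its brute-force oracle, and the end-to-end stack.

test_that("excitation: sheet peaks on its plane, zero source gives zero", {
  g <- Grid3D(64, 64, 64, dx = 0.2)
  vol <- RefractiveVolume(g)
  illum <- SourceSpec("cylindrical_sheet", PupilSpec(0.15, 0.5))
  exc <- excitationVolume(vol, illum, sheetZ = 6.4)
  zprof <- apply(exc$intensity, 3, sum)
  expect_equal(which.max(zprof), 33L)
  ## sheet thickness at focus close to the vacuum waist
  fw <- LightSheetSim:::profileFwhm((0:63) * 0.2, exc$intensity[33, 33, ])
  th <- 0.886 * 0.5 / (2 * 0.15)
  expect_lt(abs(fw - th) / th, 0.12)

  zero <- illum
  zeroField <- makeField(illum, reorientVolume(vol, "x")@grid)
  zeroField@values[] <- 0i
  exc0 <- excitationVolume(vol, list(zeroField), sheetZ = 6.4)
  expect_equal(max(exc0$intensity), 0)
})

test_that("excitation decays by Beer-Lambert in an absorbing medium", {
  g <- Grid3D(48, 48, 48, dx = 0.2)
  kap <- 1e-3
  vol <- RefractiveVolume(g, array(complex(real = 1.33, imaginary = kap),
                                   c(48, 48, 48)))
  exc <- excitationVolume(vol, SourceSpec("plane_wave", PupilSpec(0.15, 0.5)),
                          sheetZ = 4.8)
  pp <- exc$planePowers / exc$planePowers[1]
  theo <- exp(-2 * (2 * pi / 0.5) * kap * 0.2 * (0:47))
  expect_lt(max(abs(pp - theo / theo[1])), 1e-6)
})

test_that("render matches the brute-force spatially varying superposition", {
  g <- Grid3D(32, 32, 32, dx = 0.2)
  planeZ <- 16 * 0.2
  lay <- tileLayout(2, 2, 16, g, planeZ)
  ps <- quietly(computePSFSet(RefractiveVolume(g), planeZ, lay,
                              detectionPupil(na = 0.5),
                              zOffsets = (-2:2) * g@dz))
  set.seed(42)
  pos <- unique(cbind(sample(4:28, 80, TRUE), sample(4:28, 80, TRUE),
                      sample(15:19, 80, TRUE)))
  fl <- array(0, dim = c(32, 32, 32))
  fl[pos] <- runif(nrow(pos))
  fluor <- FluorophoreVolume(g, fl)
  exc <- array(1, dim = c(32, 32, 32))

  bruteForce <- function(blend) {
    tw <- LightSheetSim:::tileWeights(lay, g, blend)
    bf <- matrix(0, 32, 32)
    cx0 <- 16 %/% 2 + 1
    for (e in seq_len(nrow(pos))) {
      kk <- which((-2:2) == pos[e, 3] - 17L)
      if (!length(kk)) next
      for (t in 1:4) {
        tx <- (t - 1) %% 2 + 1; ty <- (t - 1) %/% 2 + 1
        w <- tw$Wx[pos[e, 1], tx] * tw$Wy[pos[e, 2], ty]
        if (w == 0) next
        psf <- ps@psfs[[t]][, , kk]
        for (i in 1:16) for (j in 1:16) {
          xi <- pos[e, 1] + i - cx0; yj <- pos[e, 2] + j - cx0
          if (xi >= 1 && xi <= 32 && yj >= 1 && yj <= 32)
            bf[xi, yj] <- bf[xi, yj] +
              fl[pos[e, 1], pos[e, 2], pos[e, 3]] * w *
              ps@rawIntegrals[t] * psf[i, j]
        }
      }
    }
    bf
  }
  for (blend in c("nearest", "bilinear")) {
    im <- renderCameraImage(exc, fluor, ps, blend = blend)
    expect_lt(relL2(im@values, bruteForce(blend)), 1e-10)
  }
})

test_that("render is linear, exact on a delta emitter, zero on empty fluor", {
  g <- Grid3D(32, 32, 32, dx = 0.2)
  planeZ <- 16 * 0.2
  lay <- tileLayout(2, 2, 16, g, planeZ)
  ps <- quietly(computePSFSet(RefractiveVolume(g), planeZ, lay,
                              detectionPupil(na = 0.5),
                              zOffsets = (-2:2) * g@dz))
  exc <- array(1, dim = c(32, 32, 32))

  empty <- renderCameraImage(exc, FluorophoreVolume(g), ps)
  expect_equal(max(empty@values), 0)

  ## delta at tile 1 center, in focus: image is that tile's scaled PSF slice
  cx <- round(lay@sourcePositions[1, 1] / 0.2) + 1L
  cy <- round(lay@sourcePositions[1, 2] / 0.2) + 1L
  fl <- array(0, dim = c(32, 32, 32)); fl[cx, cy, 17] <- 2
  im <- renderCameraImage(exc, FluorophoreVolume(g, fl), ps,
                          blend = "nearest")
  expected <- 2 * ps@rawIntegrals[1] * ps@psfs[[1]][, , 3]
  sub <- im@values[(cx - 8):(cx + 7), (cy - 8):(cy + 7)]
  expect_lt(relL2(sub, expected), 1e-12)

  ## additivity in fluor
  fl2 <- array(0, dim = c(32, 32, 32)); fl2[20, 12, 16] <- 1
  imA <- renderCameraImage(exc, FluorophoreVolume(g, fl), ps)
  imB <- renderCameraImage(exc, FluorophoreVolume(g, fl2), ps)
  imAB <- renderCameraImage(exc, FluorophoreVolume(g, fl + fl2), ps)
  expect_lt(relL2(imAB@values, imA@values + imB@values), 1e-12)
})

test_that("image energy never exceeds emitted energy times peak transmission", {
  g <- Grid3D(32, 32, 32, dx = 0.2)
  planeZ <- 16 * 0.2
  lay <- tileLayout(2, 2, 16, g, planeZ)
  ps <- quietly(computePSFSet(RefractiveVolume(g), planeZ, lay,
                              detectionPupil(na = 0.5),
                              zOffsets = (-2:2) * g@dz))
  set.seed(8)
  fl <- array(0, dim = c(32, 32, 32))
  fl[cbind(sample(8:24, 40, TRUE), sample(8:24, 40, TRUE),
           sample(15:19, 40, TRUE))] <- 1
  exc <- array(runif(32^3), dim = c(32, 32, 32))
  im <- renderCameraImage(exc, FluorophoreVolume(g, fl), ps)
  emitted <- sum(exc * fl)
  expect_lte(sum(im@values), emitted * max(ps@rawIntegrals) * (1 + 1e-6))
})

test_that("nearest and bilinear blends converge as tiles refine", {
  ## smooth-aberration phantom: index structure much larger than any tile,
  ## so adjacent tiles' PSFs converge as the tiling refines. Emitters stay
  ## inside the coarsest layout's interpolation zone (outside the outermost
  ## tile centers bilinear clamps to nearest, which would mask the gap).
  g <- Grid3D(128, 128, 24, dx = 0.2)
  ph <- makePerlinTissue(g, 1.36, 0.015, 12, seed = 13)
  planeZ <- 8 * 0.2
  set.seed(14)
  fl <- array(0, dim = c(128, 128, 24))
  fl[cbind(sample(36:94, 200, TRUE), sample(36:94, 200, TRUE),
           sample(8:10, 200, TRUE))] <- runif(200)
  fluor <- FluorophoreVolume(g, fl)
  exc <- array(1, dim = c(128, 128, 24))
  gaps <- vapply(c(2L, 4L, 8L), function(nt) {
    lay <- tileLayout(nt, nt, 128L %/% nt, g, planeZ)
    ps <- quietly(computePSFSet(ph@refractive, planeZ, lay,
                                detectionPupil(na = 0.5),
                                zOffsets = (-2:2) * g@dz))
    a <- quietly(renderCameraImage(exc, fluor, ps, blend = "nearest"))
    b <- quietly(renderCameraImage(exc, fluor, ps, blend = "bilinear"))
    relL2(a@values, b@values)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("a vacuum stack reproduces diffraction-limited emitters in 3D", {
  g <- Grid3D(48, 48, 48, dx = 0.15)
  fl <- array(0, dim = c(48, 48, 48))
  fl[25, 25, 25] <- 1
  ph <- new("Phantom", refractive = RefractiveVolume(g),
            fluor = FluorophoreVolume(g, fl), truth = list(kind = "point"))
  illum <- SourceSpec("cylindrical_sheet", PupilSpec(0.1, 0.5))
  zs <- (25 + seq(-10, 10)) * 0.15 - 0.15
  st <- quietly(simulateStack(ph, illum, detectionPupil(na = 0.6),
                              tiles = c(2, 2), zPositions = zs,
                              psfZOffsets = seq(-3, 3, by = 0.15),
                              sourceFill = "uniform"))
  peaks <- vapply(st@images, function(im) max(im@values), numeric(1))
  ## the stack's axial response is the sheet profile times the detection
  ## axial PSF (sheet and focal plane scan together): both are sinc^2
  fw <- LightSheetSim:::profileFwhm(zs, peaks)
  sinc <- function(t) ifelse(abs(t) < 1e-12, 1, sin(pi * t) / (pi * t))
  zf <- seq(-6, 6, by = 0.01)
  axial <- sinc(2 * 0.1 * zf / 0.5)^2 *
    sinc(0.6^2 * zf / (2 * 1.33 * 0.5))^2
  th <- LightSheetSim:::profileFwhm(zf, axial)
  expect_lt(abs(fw - th) / th, 0.10)
})

test_that("tissue along the detection path reduces bar-chart modulation", {
  g <- Grid3D(64, 64, 64, dx = 0.25)
  emb <- makeEmbryo(g, seed = 11, nNuclei = 14, nucleusRadius = 1.3,
                    granularity = 0.025, label = "none")
  chart <- makeTestChart(g, barPeriods = c(2.5), planeZ = 8)
  truth <- attr(chart, "truth")
  izF <- round(8 / 0.25) + 1L
  nClear <- emb@refractive@n
  nClear[, , (izF + 1L):64] <- 1.33 + 0i
  tissue <- new("Phantom", refractive = emb@refractive, fluor = chart,
                truth = emb@truth)
  cleared <- new("Phantom", refractive = RefractiveVolume(g, nClear),
                 fluor = chart, truth = emb@truth)
  illum <- SourceSpec("cylindrical_sheet", PupilSpec(0.1, 0.5))
  modulation <- function(st) {
    o <- truth$groups[[1]]$origin; wpx <- truth$groups[[1]]$widthPx
    per <- round(truth$groups[[1]]$period / 0.25)
    ys <- o[2] + wpx + seq_len(2 * wpx)
    prof <- rowMeans(st@images[[1]]@values[o[1]:(o[1] + 3 * per), ys])
    (max(prof) - min(prof)) / (max(prof) + min(prof))
  }
  stT <- quietly(simulateStack(tissue, illum, detectionPupil(na = 0.6),
                               tiles = c(4, 4), zPositions = 8, seed = 3))
  stC <- quietly(simulateStack(cleared, illum, detectionPupil(na = 0.6),
                               tiles = c(4, 4), zPositions = 8, seed = 3))
  expect_lt(modulation(stT), modulation(stC))
})

test_that("a refractive sphere displaces images as the ray-matrix lens predicts", {
  dx <- 0.2; nx <- 128L; nz <- 120L
  g <- Grid3D(nx, nx, nz, dx = dx)
  R <- 6; n1 <- 1.33; n2 <- 1.48
  cen <- floor(nx / 2) * dx
  zc <- 12; ze <- 2
  ph <- makeSpheres(g, centers = matrix(c(cen, cen, zc), 1), radii = R,
                    deltaN = n2 - n1, nAmbient = n1)
  pup <- PupilSpec(na = 0.15, wavelength = 0.5, nImmersion = n1)
  ## paraxial ray-matrix oracle for the ball lens (reduced angles)
  mkT <- function(t, n) matrix(c(1, 0, t / n, 1), 2, 2)
  mkS <- function(P) matrix(c(1, -P, 0, 1), 2, 2)
  M <- mkS((n2 - n1) / R) %*% mkT(2 * R, n2) %*% mkS((n2 - n1) / R) %*%
    mkT((zc - R) - ze, n1)
  d2 <- -M[1, 2] / M[2, 2] * n1
  zImg <- zc + R + d2
  mag <- M[1, 1] + d2 / n1 * M[2, 1]

  k0 <- 2 * pi / 0.5
  kg <- LightSheetSim:::kGrids(nx, nx, dx, dx)
  krm <- sqrt(outer(kg$kx^2, rep(1, nx)) + outer(rep(1, nx), kg$ky^2))
  xs <- (0:(nx - 1)) * dx
  iz0 <- round(ze / dx) + 1L
  half <- RefractiveVolume(Grid3D(nx, nx, nz - iz0 + 1L, dx = dx),
                           ph@refractive@n[, , iz0:nz], n1)
  for (off in c(0.8, 1.2)) {
    u0 <- makeField(SourceSpec("point_source", pup,
                               focus = c(cen + off, cen, 0)), g)
    ex <- quietly(propagate(u0, half)$field)
    Uk <- LightSheetSim:::fft2(ex@values)
    Uk[krm > k0 * 0.15] <- 0i
    H <- LightSheetSim:::angularSpectrumKernel(
      nx, nx, dx, dx, 0.5, -(nz - iz0 + 1L) * dx + (zImg - ze), n1, "zero")
    I <- Mod(LightSheetSim:::ifft2(Uk * H))^2
    win <- abs(xs - (cen + mag * off)) <= 3
    cx <- sum(outer(xs[win], rep(1, nx)) * I[win, ]) / sum(I[win, ])
    expect_lt(abs((cx - cen) / (mag * off) - 1), 0.10)
  }
})

test_that("stacks are deterministic and noise injection is seeded", {
  g <- Grid3D(32, 32, 32, dx = 0.25)
  ph <- makePerlinTissue(g, 1.36, 0.01, 1.5, seed = 2)
  illum <- SourceSpec("cylindrical_sheet", PupilSpec(0.1, 0.5))
  args <- list(ph, illum, detectionPupil(na = 0.5), tiles = c(2, 2),
               zPositions = 4, noise = "poisson", photons = 500, seed = 7)
  s1 <- quietly(do.call(simulateStack, args))
  s2 <- quietly(do.call(simulateStack, args))
  expect_identical(s1@images[[1]]@values, s2@images[[1]]@values)
})
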