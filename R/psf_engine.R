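## Multiplexed computation of spatially varying detection PSFs.
##
## Because the wave equation is linear and the refocused spots of
## well-separated point sources do not overlap, a whole lattice of
## diffraction-limited sources can be propagated through the tissue in ONE
## simulation and the per-source PSFs recovered by cropping tiles around
## each refocused spot. This is the multiplexing trick that turns thousands
## of sequential PSF runs into a single propagation.

#' Construct a TileLayout
#'
#' Tiles are centered in the transverse plane of \code{grid}; one point
#' source sits at each tile center at depth \code{planeZ}.
#'
#' @param tileNx,tileNy number of tiles along x and y.
#' @param tileSize pixels per square tile.
#' @param grid the [Grid3D-class].
#' @param planeZ focal-plane depth (micrometers).
#' @param guardMargin pixels of the border ring used for the cross-talk
#'   metric (default tileSize/8, at least 1).
#' @return a [TileLayout-class].
#' @export
tileLayout <- function(tileNx, tileNy, tileSize, grid, planeZ,
                       guardMargin = NULL) {
  tileNx <- as.integer(tileNx); tileNy <- as.integer(tileNy)
  tileSize <- as.integer(tileSize)
  if (tileSize * tileNx > grid@nx || tileSize * tileNy > grid@ny)
    stop("layout-error: tiles exceed the transverse grid")
  if (is.null(guardMargin)) guardMargin <- max(1L, tileSize %/% 8L)
  off <- c((grid@nx - tileNx * tileSize) %/% 2L,
           (grid@ny - tileNy * tileSize) %/% 2L)
  pos <- matrix(0, tileNx * tileNy, 3)
  t <- 1L
  for (jy in seq_len(tileNy)) for (jx in seq_len(tileNx)) {
    cxPix <- off[1] + (jx - 1L) * tileSize + tileSize %/% 2L + 1L
    cyPix <- off[2] + (jy - 1L) * tileSize + tileSize %/% 2L + 1L
    pos[t, ] <- c((cxPix - 1L) * grid@dx, (cyPix - 1L) * grid@dy, planeZ)
    t <- t + 1L
  }
  new("TileLayout", tileNx = tileNx, tileNy = tileNy, tileSize = tileSize,
      sourcePositions = pos, guardMargin = as.integer(guardMargin))
}

## pupil copy with the disk fill overridden (engine sources default to the
## Gaussian-apodized fill so neighboring spots separate cleanly)
withPupilFill <- function(pupil, fill) {
  ka <- pupil@kindArgs
  ka$fill <- fill
  new("PupilSpec", na = pupil@na, wavelength = pupil@wavelength,
      nImmersion = pupil@nImmersion, kind = pupil@kind, kindArgs = ka,
      tilt = pupil@tilt)
}

## pixel indices of a tile's window (x and y index vectors)
tileWindow <- function(layout, grid, t) {
  ts <- layout@tileSize
  ix <- as.integer(round(layout@sourcePositions[t, 1] / grid@dx)) + 1L
  iy <- as.integer(round(layout@sourcePositions[t, 2] / grid@dy)) + 1L
  offs <- seq_len(ts) - 1L - ts %/% 2L
  list(xs = ix + offs, ys = iy + offs)
}

#' Coherent superposition of multiplexed point sources
#'
#' One diffraction-limited point source per tile center, each of unit
#' power, summed coherently into a single entrance field at the focal
#' plane.
#'
#' @param layout a [TileLayout-class].
#' @param pupil the detection [PupilSpec-class].
#' @param grid the [Grid3D-class].
#' @param sourceFill pupil fill of the sources: "gaussian" (default;
#'   exponentially confined spots, the regime where tiles stay mutually
#'   independent) or "uniform" (hard aperture, Airy tails).
#' @return a [ComplexField-class].
#' @export
multiplexedSourceField <- function(layout, pupil, grid,
                                   sourceFill = c("gaussian", "uniform")) {
  pupil <- withPupilFill(pupil, match.arg(sourceFill))
  minSep <- min(c(diff(sort(unique(layout@sourcePositions[, 1]))),
                  diff(sort(unique(layout@sourcePositions[, 2]))), Inf))
  if (is.finite(minSep) && minSep < layout@tileSize * grid@dx - 1e-9)
    stop("layout-error: source positions closer than one tile")
  nx <- grid@nx; ny <- grid@ny
  kg <- kGrids(nx, ny, grid@dx, grid@dy)
  kxm <- outer(kg$kx, rep(1, ny)); kym <- outer(rep(1, nx), kg$ky)
  A <- pupilAmplitude(pupil, kxm, kym) + 0i
  ## per-source normalization from a single centered source
  single <- ifft2(A)
  pwr <- sum(Mod(single)^2) * grid@dx * grid@dy
  comb <- matrix(0i, nx, ny)
  for (t in seq_len(nrow(layout@sourcePositions))) {
    p <- layout@sourcePositions[t, ]
    comb <- comb + exp(-1i * (kxm * p[1] + kym * p[2]))
  }
  u <- ifft2(A * comb) / sqrt(pwr)
  ComplexField(u, grid@dx, grid@dy, pupil@wavelength, z = 0)
}

#' Refocus an exit field through an idealized detection lens
#'
#' The ideal telecentric 4f model: the transverse spectrum is cropped to
#' the detection NA disk and the field is then propagated through the
#' homogeneous immersion medium across the requested refocus range, with
#' intensity recorded per plane. No lens aberrations are applied.
#'
#' @param exitField the [ComplexField-class] at the detection-side sample
#'   boundary.
#' @param pupil detection [PupilSpec-class] (NA crop; must satisfy
#'   NA <= nImmersion).
#' @param refocusRange numeric (zMin, zMax) in micrometers, relative to the
#'   exit plane (negative = towards the sample).
#' @param nPlanes number of refocus planes.
#' @param nImmersion immersion index (default the pupil's).
#' @return list with \code{stack} (nx x ny x nPlanes intensity),
#'   \code{z} (refocus distances), and \code{fields} (complex record,
#'   only when \code{keepFields}).
#' @param keepFields also keep the complex field per plane.
#' @export
idealLensRefocus <- function(exitField, pupil, refocusRange, nPlanes,
                             nImmersion = pupil@nImmersion,
                             keepFields = FALSE) {
  if (pupil@na > nImmersion)
    stop("invalid-parameter: NA exceeds the immersion index")
  nx <- nrow(exitField@values); ny <- ncol(exitField@values)
  kg <- kGrids(nx, ny, exitField@dx, exitField@dy)
  k0 <- 2 * pi / exitField@wavelength
  krm <- sqrt(outer(kg$kx^2, rep(1, ny)) + outer(rep(1, nx), kg$ky^2))
  Uk <- fft2(exitField@values)
  Uk[krm > k0 * pupil@na] <- 0i
  zs <- seq(refocusRange[1], refocusRange[2], length.out = nPlanes)
  stack <- array(0, dim = c(nx, ny, nPlanes))
  fields <- if (keepFields) array(0i, dim = c(nx, ny, nPlanes)) else NULL
  for (i in seq_len(nPlanes)) {
    H <- angularSpectrumKernel(nx, ny, exitField@dx, exitField@dy,
                               exitField@wavelength, zs[i], nImmersion,
                               "zero")
    up <- ifft2(Uk * H)
    stack[, , i] <- Mod(up)^2
    if (keepFields) fields[, , i] <- up
  }
  out <- list(stack = stack, z = zs)
  if (keepFields) out$fields <- fields
  out
}

#' Compute the spatially varying PSF set for one focal plane
#'
#' Runs the multiplexed source field from the focal plane through the
#' detection-side half of the volume, refocuses through the idealized lens,
#' and crops per-tile volumetric PSFs. Each PSF is normalized to unit sum;
#' the raw in-focus collected power (detection-path transmission) is kept
#' per tile.
#'
#' @param volume the [RefractiveVolume-class]; the detection axis must
#'   already be the volume's z axis.
#' @param planeZ focal-plane depth (micrometers from the entrance plane).
#' @param layout a [TileLayout-class].
#' @param detectPupil detection [PupilSpec-class].
#' @param zOffsets axial offsets of the stored PSF planes relative to the
#'   focal plane (micrometers); default \code{(-4:4) * dz}.
#' @param config a [PropagatorConfig-class].
#' @param crosstalkTol flagged-tile tolerance on the border-ring energy
#'   fraction (default 0.01).
#' @param sourceFill source-pupil fill, see [multiplexedSourceField()].
#' @param keepExitFields keep per-tile complex in-focus fields for
#'   aberration analysis.
#' @return a [PSFSet-class].
#' @examples
#' g <- Grid3D(64, 64, 32, dx = 0.15)
#' vol <- RefractiveVolume(g)
#' lay <- tileLayout(2, 2, 32, g, planeZ = 1.2)
#' pup <- PupilSpec(na = 0.6, wavelength = 0.5)
#' ps <- computePSFSet(vol, 1.2, lay, pup)
#' @export
computePSFSet <- function(volume, planeZ, layout, detectPupil,
                          zOffsets = NULL, config = PropagatorConfig(),
                          crosstalkTol = 0.01,
                          sourceFill = c("gaussian", "uniform"),
                          keepExitFields = FALSE) {
  g <- volume@grid
  if (is.null(zOffsets)) zOffsets <- (-4:4) * g@dz
  iz0 <- as.integer(round(planeZ / g@dz)) + 1L
  nzH <- g@nz - iz0 + 1L
  if (iz0 < 1L || nzH < 8L)
    stop("focal plane must lie at least 8 slices before the exit surface")
  u0 <- multiplexedSourceField(layout, detectPupil, g,
                               sourceFill = match.arg(sourceFill))
  half <- RefractiveVolume(
    Grid3D(g@nx, g@ny, nzH, dx = g@dx, dy = g@dy, dz = g@dz),
    volume@n[, , iz0:g@nz, drop = FALSE], volume@nAmbient)
  ex <- propagate(u0, half, config)$field
  travel <- nzH * g@dz
  rf <- idealLensRefocus(ex, detectPupil,
                         refocusRange = c(-travel + min(zOffsets),
                                          -travel + max(zOffsets)),
                         nPlanes = length(zOffsets),
                         keepFields = keepExitFields)
  nT <- nrow(layout@sourcePositions)
  ts <- layout@tileSize
  izF <- which.min(abs(zOffsets))
  psfs <- vector("list", nT)
  rawIntegrals <- crosstalk <- numeric(nT)
  exitFields <- if (keepExitFields) vector("list", nT) else list()
  gm <- layout@guardMargin
  ring <- {
    m <- matrix(TRUE, ts, ts)
    m[(gm + 1L):(ts - gm), (gm + 1L):(ts - gm)] <- FALSE
    m
  }
  for (t in seq_len(nT)) {
    w <- tileWindow(layout, g, t)
    p <- rf$stack[w$xs, w$ys, , drop = FALSE]
    rawIntegrals[t] <- sum(p[, , izF]) * g@dx * g@dy
    crosstalk[t] <- sum(p[, , izF][ring]) / max(sum(p[, , izF]), 1e-300)
    psfs[[t]] <- p / sum(p)
    if (keepExitFields) exitFields[[t]] <- rf$fields[w$xs, w$ys, izF]
  }
  flags <- crosstalk > crosstalkTol
  if (any(flags))
    warning(sprintf("cross-talk above %.2g%% in %d tile(s)",
                    100 * crosstalkTol, sum(flags)))
  new("PSFSet", layout = layout, psfs = psfs, rawIntegrals = rawIntegrals,
      planeZ = planeZ, zOffsets = zOffsets, dx = g@dx, dy = g@dy,
      dz = g@dz, crosstalk = crosstalk, flags = flags,
      exitFields = exitFields)
}
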