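## Guide-star phase conjugation and the shift-shift memory effect.
##
## A point emitter (guide star) at depth d radiates towards the entry
## surface; conjugating the recorded complex wavefront and propagating it
## forward refocuses the light onto the guide star — the split-step scheme
## is numerically reciprocal for lossless media. Translating the conjugated
## wavefront laterally probes the iso-planatic patch: the refocused peak
## decays with shift, and its decay is governed by the autocorrelation of
## the speckle a plane wave would produce at the same depth.

## index of the slice holding depth z
depthSlice <- function(grid, z) as.integer(round(z / grid@dz)) + 1L

#' Guide-star wavefront at the entry surface
#'
#' Propagates an ideal point emitter at \code{sourcePos} back through the
#' sample (reversed slice order) to the entry plane (z = 0) and returns the
#' complex exit wavefront.
#'
#' @param volume a [RefractiveVolume-class].
#' @param sourcePos (x, y, depth) of the guide star in micrometers.
#' @param na numerical aperture of the emitted cone.
#' @param wavelength vacuum wavelength (micrometers).
#' @param config a [PropagatorConfig-class].
#' @return a [ComplexField-class] at the entry plane.
#' @export
guidestarExitWavefront <- function(volume, sourcePos, na, wavelength,
                                   config = PropagatorConfig()) {
  g <- volume@grid
  iz0 <- depthSlice(g, sourcePos[3])
  if (iz0 < 8L || iz0 > g@nz)
    stop("guide star must lie at least 8 slices inside the volume")
  pup <- PupilSpec(na = na, wavelength = wavelength,
                   nImmersion = volume@nAmbient)
  src <- SourceSpec("point_source", pup,
                    focus = c(sourcePos[1], sourcePos[2], 0))
  seg <- RefractiveVolume(
    Grid3D(g@nx, g@ny, iz0, dx = g@dx, dy = g@dy, dz = g@dz),
    volume@n[, , iz0:1, drop = FALSE], volume@nAmbient)
  u0 <- makeField(src, seg@grid)
  propagate(u0, seg, config)$field
}

## forward segment of the volume from the entry plane to depth
entrySegment <- function(volume, depth) {
  g <- volume@grid
  iz0 <- depthSlice(g, depth)
  RefractiveVolume(Grid3D(g@nx, g@ny, iz0, dx = g@dx, dy = g@dy, dz = g@dz),
                   volume@n[, , 1:iz0, drop = FALSE], volume@nAmbient)
}

## focus metrics of a focal-plane intensity around a target position
focusMetrics <- function(I, grid, target, searchRadius = 2) {
  xs <- axisCoords(nrow(I), grid@dx); ys <- axisCoords(ncol(I), grid@dy)
  wx <- which(abs(xs - target[1]) <= searchRadius)
  wy <- which(abs(ys - target[2]) <= searchRadius)
  sub <- I[wx, wy, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ix <- wx[pk[1]]; iy <- wy[pk[2]]
  posErr <- sqrt((xs[ix] - target[1])^2 + (ys[iy] - target[2])^2)
  fw <- profileFwhm(xs, I[, iy])
  list(peak = I[ix, iy], posErr = posErr, fwhmLateral = fw,
       peakIndex = c(ix, iy))
}

#' Conjugate a guide-star wavefront and evaluate the refocus
#'
#' Conjugates the recorded entry wavefront (full complex conjugation, or
#' phase-only with uniform amplitude at equal power), propagates it forward
#' through the sample, and reports focus quality at the guide-star
#' position. The Strehl denominator is the peak of the identical experiment
#' through a homogeneous volume (same NA, depth and power).
#'
#' @param exitWavefront the [ComplexField-class] from
#'   [guidestarExitWavefront()].
#' @param volume the [RefractiveVolume-class].
#' @param sourcePos the guide-star position (x, y, depth).
#' @param na numerical aperture used for the guide star.
#' @param mode "phase_and_amplitude" (default) or "phase_only".
#' @param config a [PropagatorConfig-class].
#' @return list with \code{report} (a [FocusReport-class]) and
#'   \code{intensity} (focal-plane intensity matrix).
#' @export
conjugateAndFocus <- function(exitWavefront, volume, sourcePos, na,
                              mode = c("phase_and_amplitude", "phase_only"),
                              config = PropagatorConfig()) {
  mode <- match.arg(mode)
  g <- volume@grid
  pwr <- fieldPower(exitWavefront)
  conjVals <- if (mode == "phase_and_amplitude") Conj(exitWavefront@values)
  else {
    a <- sqrt(pwr / (g@nx * g@ny * g@dx * g@dy))
    a * exp(-1i * Arg(exitWavefront@values))
  }
  uc <- ComplexField(conjVals, g@dx, g@dy, exitWavefront@wavelength, 0)
  seg <- entrySegment(volume, sourcePos[3])
  run <- propagate(uc, seg, config)
  I <- Mod(run$field@values)^2
  met <- focusMetrics(I, g, sourcePos)

  ## ideal reference: vacuum guide star, full conjugation, same power
  vac <- RefractiveVolume(seg@grid, nAmbient = volume@nAmbient)
  uIdeal <- guidestarExitWavefront(vac, sourcePos, na,
                                   exitWavefront@wavelength, config)
  uIdeal@values <- Conj(uIdeal@values) *
    sqrt(pwr / fieldPower(uIdeal))
  Iid <- Mod(propagate(uIdeal, vac, config)$field@values)^2
  metId <- focusMetrics(Iid, g, sourcePos)

  ## axial FWHM around the focus
  ax <- axialProfile(uc, seg, met$peakIndex, config)
  report <- new("FocusReport", peak = met$peak,
                strehl = min(met$peak / metId$peak, 1.05),
                fwhmLateral = met$fwhmLateral,
                fwhmAxial = ax,
                positionError = met$posErr)
  list(report = report, intensity = I)
}

## axial intensity FWHM through a focus: re-propagate, record the on-peak
## intensity per plane, and continue past the focus into ambient medium so
## the half-max crossing beyond the exit surface is captured
axialProfile <- function(entryField, seg, peakIndex, config, extraPlanes = 24L) {
  cfg <- new("PropagatorConfig", nRefMode = config@nRefMode,
             evanescentPolicy = config@evanescentPolicy,
             boundary = config@boundary, storeVolume = TRUE)
  out <- propagate(entryField, seg, cfg)
  prof <- Mod(out$record[peakIndex[1], peakIndex[2], ])^2
  u <- out$field
  extra <- numeric(extraPlanes)
  for (i in seq_len(extraPlanes)) {
    u <- suppressWarnings(freeSpaceStep(u, seg@grid@dz, seg@nAmbient,
                                        config@evanescentPolicy))
    extra[i] <- Mod(u@values[peakIndex[1], peakIndex[2]])^2
  }
  prof <- c(prof, extra)
  zs <- axisCoords(length(prof), seg@grid@dz)
  fw <- profileFwhm(zs, prof)
  if (!is.finite(fw)) fw <- NA_real_
  fw
}

#' Shift-shift memory-effect curve
#'
#' Translates the conjugated guide-star wavefront laterally by each shift,
#' propagates it to the guide-star depth, and records the focal-plane
#' intensity at the shifted target: C(shift) = I(shift)/I(0). The
#' reference curve is the normalized spatial autocorrelation of the
#' focal-plane speckle intensity produced by a plane wave through the same
#' volume.
#'
#' @param volume a [RefractiveVolume-class].
#' @param sourcePos guide-star position (x, y, depth).
#' @param shifts lateral shifts along x (micrometers; include 0).
#' @param na guide-star numerical aperture.
#' @param wavelength vacuum wavelength.
#' @param config a [PropagatorConfig-class].
#' @param meanFreePath scattering mean free path (micrometers) used to
#'   express the depth in mfp units (NA if unknown).
#' @return a [MemoryEffectCurve-class].
#' @export
memoryEffectCurve <- function(volume, sourcePos, shifts, na, wavelength,
                              config = PropagatorConfig(),
                              meanFreePath = NA_real_) {
  g <- volume@grid
  maxShift <- (g@nx %/% 4L) * g@dx
  if (any(abs(shifts) > maxShift)) {
    warning("shifts beyond a quarter of the field truncated")
    shifts <- shifts[abs(shifts) <= maxShift]
  }
  uExit <- guidestarExitWavefront(volume, sourcePos, na, wavelength, config)
  uConj <- ComplexField(Conj(uExit@values), g@dx, g@dy, wavelength, 0)
  seg <- entrySegment(volume, sourcePos[3])
  I0 <- NULL
  corr <- numeric(length(shifts))
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    us <- if (abs(s) < 1e-12) uConj
    else ComplexField(fourierShift2(uConj@values, s, 0, g@dx, g@dy),
                      g@dx, g@dy, wavelength, 0)
    I <- Mod(propagate(us, seg, config)$field@values)^2
    met <- focusMetrics(I, g, c(sourcePos[1] + s, sourcePos[2]),
                        searchRadius = 1)
    if (abs(s) < 1e-12) I0 <- met$peak
    corr[i] <- met$peak
  }
  i0 <- which.min(abs(shifts))
  corr <- corr / corr[i0]

  ## reference: speckle intensity autocorrelation at the same depth
  pw <- planeWaveField(g@nx, g@ny, dx = g@dx, dy = g@dy,
                       wavelength = wavelength)
  Isp <- Mod(propagate(pw, seg, config)$field@values)^2
  ref <- speckleAutocorrelation(Isp, g@dx, shifts)

  new("MemoryEffectCurve", shifts = shifts, correlation = corr,
      reference = ref, depth = sourcePos[3],
      depthMfp = sourcePos[3] / meanFreePath)
}

#' Normalized speckle intensity autocorrelation along x
#'
#' \eqn{C(\Delta) = \langle\delta I(x)\,\delta I(x+\Delta)\rangle /
#' \langle\delta I^2\rangle} computed via FFT over the full plane and
#' interpolated at the requested shifts.
#'
#' @param I intensity matrix.
#' @param dx pixel pitch (micrometers).
#' @param shifts lags (micrometers) at which to sample the curve.
#' @return numeric correlation at \code{shifts}.
#' @export
speckleAutocorrelation <- function(I, dx, shifts) {
  dI <- I - mean(I)
  F <- fft2(dI + 0i)
  ac <- Re(ifft2(F * Conj(F)))
  ac <- ac / ac[1, 1]
  lagsPix <- shifts / dx
  prof <- ac[, 1]
  n <- length(prof)
  vapply(lagsPix, function(l) {
    la <- abs(l)
    i0 <- floor(la); fr <- la - i0
    i0 <- i0 %% n
    i1 <- (i0 + 1L) %% n
    (1 - fr) * prof[i0 + 1L] + fr * prof[i1 + 1L]
  }, numeric(1))
}

#' Estimate the scattering mean free path of a medium
#'
#' Propagates plane waves through independent realizations of the medium,
#' ensemble-averages the complex field per depth, and fits the exponential
#' decay of the ballistic power \eqn{|\langle u(z)\rangle|^2 \propto
#' \exp(-z/\ell_s)}.
#'
#' @param volumeFactory function(seed) returning a [RefractiveVolume-class]
#'   realization of the medium.
#' @param wavelength vacuum wavelength (micrometers).
#' @param nRealizations ensemble size (default 8).
#' @param seed root seed; realization i uses a derived substream.
#' @param config a [PropagatorConfig-class].
#' @param fitRange optional c(zMin, zMax) restriction for the fit.
#' @return list with \code{meanFreePath} (micrometers; Inf with
#'   \code{noDecay = TRUE} for non-scattering media), \code{ballistic}
#'   (power vs depth), \code{z}, \code{fit} (the lm object) and
#'   \code{noDecay}.
#' @export
estimateMeanFreePath <- function(volumeFactory, wavelength,
                                 nRealizations = 8L, seed = 1L,
                                 config = PropagatorConfig(),
                                 fitRange = NULL) {
  acc <- NULL
  g <- NULL
  cfg <- NULL
  for (i in seq_len(nRealizations)) {
    vol <- volumeFactory(substreamSeed(seed, paste0("mfp-", i)))
    if (is.null(g)) {
      g <- vol@grid
      cfg <- new("PropagatorConfig", nRefMode = config@nRefMode,
                 evanescentPolicy = config@evanescentPolicy,
                 boundary = config@boundary, storeVolume = TRUE)
    }
    pw <- planeWaveField(g@nx, g@ny, dx = g@dx, dy = g@dy,
                         wavelength = wavelength)
    rec <- propagate(pw, vol, cfg)$record
    acc <- if (is.null(acc)) rec else acc + rec
  }
  acc <- acc / nRealizations
  dA <- g@dx * g@dy
  ballistic <- apply(acc, 3, function(u) sum(Mod(u)^2)) * dA
  z <- axisCoords(g@nz, g@dz) + g@dz
  sel <- rep(TRUE, length(z))
  if (!is.null(fitRange)) sel <- z >= fitRange[1] & z <= fitRange[2]
  fit <- lm(log(ballistic[sel]) ~ z[sel])
  slope <- coef(fit)[2]
  total <- g@nz * g@dz
  noDecay <- !is.finite(slope) || slope > -1e-6 ||
    (ballistic[1] / ballistic[length(ballistic)]) < exp(0.02)
  ls <- if (noDecay) Inf else -1 / slope
  list(meanFreePath = as.numeric(ls), ballistic = ballistic, z = z,
       fit = fit, noDecay = noDecay)
}
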