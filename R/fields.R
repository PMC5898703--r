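## Input-field catalogue. Every source is synthesized in the pupil
## (transverse spatial-frequency) plane: fill the pupil support, apply the
## defocus kernel exp(-i kz z_f) so free-space propagation by z_f focuses
## the field, shift the focus laterally by a linear pupil phase, inverse
## transform, normalize to unit power. The transverse wavenumber of a ray
## at aperture angle theta is k0 * n * sin(theta) = k0 * NA, so the pupil
## support is the disk |k_perp| <= k0 * NA.

pupilAmplitude <- function(pupil, kxm, kym) {
  k0 <- 2 * pi / pupil@wavelength
  kr <- sqrt(kxm^2 + kym^2)
  kNa <- k0 * pupil@na
  A <- matrix(0, nrow(kxm), ncol(kxm))
  if (pupil@kind == "disk") {
    if (identical(pupil@kindArgs$fill, "gaussian")) {
      ## Gaussian apodization (NA = 4 sigma): spot tails decay like
      ## exp(-r^2/w0^2) and the residual hard-crop discontinuity at NA is
      ## e^-8 in amplitude -- this is what keeps multiplexed spots
      ## mutually independent at one-tile separations
      sigK <- kNa / 4
      A <- exp(-kr^2 / (2 * sigK^2))
      A[kr > kNa] <- 0
    } else {
      A[kr <= kNa] <- 1
    }
  } else if (pupil@kind == "annulus") {
    kIn <- k0 * pupil@kindArgs$innerNa
    A[kr <= kNa & kr >= kIn] <- 1
  } else if (pupil@kind == "cylindrical_slit") {
    ## 1D slit: spectrum confined to the ky = 0 row -> field invariant
    ## along y, focused along x (the sheet's thin axis)
    A[abs(kxm) <= kNa & abs(kym) < 1e-12] <- 1
  } else if (pupil@kind == "lattice") {
    kIn <- k0 * pupil@kindArgs$innerNa
    A[kr <= kNa & kr >= kIn] <- 1
  }
  A
}

#' Construct an input field from a source specification
#'
#' Builds plane waves, Gaussian beams, cylindrical-lens light sheets, Bessel
#' beams, Bessel lattices, and diffraction-limited point sources at the
#' volume entrance plane (z = 0), such that free-space propagation focuses
#' the field at \code{focus(spec)}.
#'
#' @param spec a [SourceSpec-class].
#' @param grid the [Grid3D-class] whose transverse plane the field lives on.
#' @return a [ComplexField-class] of unit total power (unless
#'   \code{normalization = "none"}).
#' @examples
#' pup <- PupilSpec(na = 0.4, wavelength = 0.5)
#' src <- SourceSpec("point_source", pup, focus = c(3.2, 3.2, 2))
#' g <- Grid3D(64, 64, 32, dx = 0.1)
#' u0 <- makeField(src, g)
#' @export
makeField <- function(spec, grid) {
  pupil <- spec@pupil
  lam <- pupil@wavelength
  n0 <- pupil@nImmersion
  if (grid@dx > lam / (2 * pupil@na) || grid@dy > lam / (2 * pupil@na))
    stop(sprintf(
      "sampling-error: pitch %.3g um undersamples NA %.2f (need <= %.3g um)",
      max(grid@dx, grid@dy), pupil@na, lam / (2 * pupil@na)))
  f <- spec@focus
  ext <- c(grid@nx * grid@dx, grid@ny * grid@dy, grid@nz * grid@dz)
  if (any(f < -1e-9) || any(f > ext + 1e-9))
    stop("invalid-parameter: focus position outside the simulation volume")

  nx <- grid@nx; ny <- grid@ny
  kg <- kGrids(nx, ny, grid@dx, grid@dy)
  kxm <- outer(kg$kx, rep(1, ny))
  kym <- outer(rep(1, nx), kg$ky)
  k0 <- 2 * pi / lam

  if (spec@kind == "plane_wave") {
    x <- axisCoords(nx, grid@dx); y <- axisCoords(ny, grid@dy)
    u <- exp(1i * (outer(pupil@tilt[1] * x, rep(1, ny)) +
                   outer(rep(1, nx), pupil@tilt[2] * y)))
  } else {
    A <- switch(spec@kind,
      gaussian = {
        ## Gaussian pupil fill, hard-cropped at the declared NA (3 sigma):
        ## 1/e^2 intensity waist w0 = 3*sqrt(2)/(k0*NA)
        sigK <- k0 * pupil@na / 3
        kr <- sqrt(kxm^2 + kym^2)
        G <- exp(-kr^2 / (2 * sigK^2)); G[kr > k0 * pupil@na] <- 0
        G
      },
      cylindrical_sheet = pupilAmplitude(
        if (pupil@kind == "cylindrical_slit") pupil else
          PupilSpec(pupil@na, lam, n0, kind = "cylindrical_slit"),
        kxm, kym),
      bessel = pupilAmplitude(pupil, kxm, kym),
      bessel_lattice = {
        base <- pupilAmplitude(pupil, kxm, kym)
        per <- pupil@kindArgs$period %||% (2 * lam / pupil@na)
        cnt <- pupil@kindArgs$count %||% 5L
        offs <- (seq_len(cnt) - (cnt + 1) / 2) * per
        comb <- matrix(0i, nx, ny)
        for (o in offs) comb <- comb + exp(-1i * kym * o)
        base * comb
      },
      point_source = pupilAmplitude(pupil, kxm, kym))
    A <- A + 0i
    ## propagating support only
    kz2 <- (n0 * k0)^2 - kxm^2 - kym^2
    A[kz2 <= 0] <- 0i
    kz <- sqrt(pmax(kz2, 0))
    ## defocus so that propagating by f[3] focuses, lateral shift to (x, y)
    A <- A * exp(-1i * kz * f[3]) * exp(-1i * (kxm * f[1] + kym * f[2]))
    if (any(pupil@tilt != 0)) {
      ## carrier: shift the whole spectrum
      x <- axisCoords(nx, grid@dx); y <- axisCoords(ny, grid@dy)
      u <- ifft2(A) * exp(1i * (outer(pupil@tilt[1] * x, rep(1, ny)) +
                                outer(rep(1, nx), pupil@tilt[2] * y)))
      A <- NULL
    }
    if (!is.null(A)) u <- ifft2(A)
  }
  fld <- ComplexField(u, grid@dx, grid@dy, lam, z = 0)
  if (spec@normalization == "power") {
    p <- fieldPower(fld)
    if (p <= 0) stop("invalid-parameter: source has zero power")
    fld@values <- fld@values / sqrt(p)
  }
  fld
}

#' Random plane-wave set emulating an incoherent low-NA source
#'
#' Draws \code{count} plane waves with tilts uniformly filling the cone of
#' the stated NA spread. Consumers must sum member intensities (never
#' amplitudes) to model incoherent illumination.
#'
#' @param naSpread NA of the illumination cone (0 gives on-axis waves).
#' @param count number of plane waves (>= 1).
#' @param seed integer seed; the set is bit-reproducible.
#' @param grid a [Grid3D-class] for the transverse plane.
#' @param wavelength vacuum wavelength (micrometers).
#' @param nImmersion ambient index.
#' @return list of [ComplexField-class], each of unit power.
#' @export
incoherentPlaneWaveSet <- function(naSpread, count, seed, grid, wavelength,
                                   nImmersion = 1.33) {
  if (count < 1) stop("count must be >= 1")
  k0 <- 2 * pi / wavelength
  set.seed(substreamSeed(seed, "illumination"))
  ## uniform fill of the NA disk in transverse-k space
  kr <- k0 * naSpread * sqrt(runif(count))
  phi <- runif(count, 0, 2 * pi)
  if (naSpread == 0) kr[] <- 0
  lapply(seq_len(count), function(i) {
    pup <- PupilSpec(na = max(naSpread, 1e-6), wavelength = wavelength,
                     nImmersion = nImmersion,
                     tilt = c(kr[i] * cos(phi[i]), kr[i] * sin(phi[i])))
    makeField(SourceSpec("plane_wave", pup), grid)
  })
}

#' On-axis unit plane wave (convenience constructor)
#' @param nx,ny transverse size, \code{dx}, \code{dy} pitch, wavelength in
#'   micrometers.
#' @param dx,dy pitch.
#' @param wavelength vacuum wavelength.
#' @export
planeWaveField <- function(nx, ny = nx, dx, dy = dx, wavelength) {
  ComplexField(matrix(1 + 0i, nx, ny), dx, dy, wavelength, z = 0)
}
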