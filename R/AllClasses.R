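#' @import methods
NULL

#' Regular 3D computational grid
#'
#' Voxel counts and pitches (micrometers) of the simulation volume. The
#' stored-array axis order is (x, y, z) and the propagation axis is always
#' the third (z) axis; use [reorientVolume()] to propagate along another
#' lab axis.
#'
#' @slot nx,ny,nz integer voxel counts (each >= 8).
#' @slot dx,dy,dz voxel pitch in micrometers (> 0).
#' @export
setClass("Grid3D",
  representation(nx = "integer", ny = "integer", nz = "integer",
                 dx = "numeric", dy = "numeric", dz = "numeric"),
  validity = function(object) {
    msg <- NULL
    cnt <- c(object@nx, object@ny, object@nz)
    if (any(cnt < 8L)) msg <- c(msg, "all voxel counts must be >= 8")
    pit <- c(object@dx, object@dy, object@dz)
    if (any(!is.finite(pit)) || any(pit <= 0))
      msg <- c(msg, "all pitches must be positive and finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Grid3D
#'
#' @param nx,ny,nz voxel counts.
#' @param dx voxel pitch in micrometers; \code{dy}, \code{dz} default to it.
#' @param dy,dz optional anisotropic pitches.
#' @return A [Grid3D-class] object.
#' @examples
#' g <- Grid3D(64, 64, 64, dx = 0.2)
#' @export
Grid3D <- function(nx, ny = nx, nz = nx, dx, dy = dx, dz = dx) {
  new("Grid3D", nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
      dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
}

#' Complex refractive-index volume
#'
#' The scattering sample: a complex refractive index per voxel. The real part
#' is the phase index, the non-negative imaginary part describes absorption
#' (Beer-Lambert amplitude decay exp(-k0 * Im(n) * dz) per step).
#'
#' @slot grid the [Grid3D-class].
#' @slot n complex array (nx, ny, nz); Re(n) in [1, 2], Im(n) >= 0.
#' @slot nAmbient real immersion/background index (e.g. 1.33 for water).
#' @export
setClass("RefractiveVolume",
  representation(grid = "Grid3D", n = "array", nAmbient = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@n)
    g <- object@grid
    if (length(d) != 3L || !all(d == c(g@nx, g@ny, g@nz)))
      msg <- c(msg, "dim(n) must equal grid counts (nx, ny, nz)")
    if (!is.complex(object@n)) msg <- c(msg, "n must be complex-valued")
    re <- Re(object@n); im <- Im(object@n)
    if (any(!is.finite(re)) || any(!is.finite(im)))
      msg <- c(msg, "n must be finite everywhere")
    else {
      if (min(re) < 1 || max(re) > 2)
        msg <- c(msg, "Re(n) must lie within [1, 2]")
      if (min(im) < 0) msg <- c(msg, "Im(n) must be >= 0")
    }
    if (length(object@nAmbient) != 1L || object@nAmbient < 1 ||
        object@nAmbient > 2)
      msg <- c(msg, "nAmbient must be a single index in [1, 2]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RefractiveVolume
#'
#' @param grid a [Grid3D-class].
#' @param n complex (or real, promoted) array of shape (nx, ny, nz); if
#'   missing, a homogeneous volume at \code{nAmbient}.
#' @param nAmbient immersion index.
#' @return A [RefractiveVolume-class].
#' @export
RefractiveVolume <- function(grid, n = NULL, nAmbient = 1.33) {
  if (is.null(n))
    n <- array(complex(real = nAmbient, imaginary = 0),
               dim = c(grid@nx, grid@ny, grid@nz))
  if (!is.complex(n)) n <- n + 0i
  new("RefractiveVolume", grid = grid, n = n, nAmbient = as.numeric(nAmbient))
}

#' Fluorophore-density volume
#'
#' @slot grid the shared [Grid3D-class].
#' @slot density non-negative array (nx, ny, nz), arbitrary fluorescence units.
#' @export
setClass("FluorophoreVolume",
  representation(grid = "Grid3D", density = "array"),
  validity = function(object) {
    msg <- NULL
    g <- object@grid
    if (!all(dim(object@density) == c(g@nx, g@ny, g@nz)))
      msg <- c(msg, "dim(density) must equal grid counts")
    if (any(!is.finite(object@density)))
      msg <- c(msg, "density must be finite")
    else if (min(object@density) < 0)
      msg <- c(msg, "density must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FluorophoreVolume
#' @param grid a [Grid3D-class].
#' @param density non-negative array; zeros if missing.
#' @export
FluorophoreVolume <- function(grid, density = NULL) {
  if (is.null(density)) density <- array(0, dim = c(grid@nx, grid@ny, grid@nz))
  new("FluorophoreVolume", grid = grid, density = density)
}

#' Transverse complex scalar field at one propagation plane
#'
#' @slot values complex matrix u(x, y).
#' @slot dx,dy transverse pitch (micrometers).
#' @slot wavelength vacuum wavelength (micrometers); k0 = 2*pi/wavelength.
#' @slot z axial coordinate of the plane (micrometers).
#' @export
setClass("ComplexField",
  representation(values = "matrix", dx = "numeric", dy = "numeric",
                 wavelength = "numeric", z = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.complex(object@values)) msg <- c(msg, "values must be complex")
    if (any(!is.finite(Re(object@values))) || any(!is.finite(Im(object@values))))
      msg <- c(msg, "field values must be finite")
    if (object@dx <= 0 || object@dy <= 0) msg <- c(msg, "pitches must be > 0")
    if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ComplexField
#' @param values complex matrix (real input promoted).
#' @param dx,dy transverse pitch in micrometers.
#' @param wavelength vacuum wavelength in micrometers.
#' @param z axial plane position in micrometers.
#' @export
ComplexField <- function(values, dx, dy = dx, wavelength, z = 0) {
  if (!is.complex(values)) values <- values + 0i
  new("ComplexField", values = values, dx = as.numeric(dx),
      dy = as.numeric(dy), wavelength = as.numeric(wavelength),
      z = as.numeric(z))
}

#' Propagator configuration
#'
#' @slot nRefMode reference-index choice for the diffraction step:
#'   \code{"global"} (use nAmbient) or \code{"per_slice_mean"} (mean real
#'   index of each slice; the locally adapted expansion).
#' @slot evanescentPolicy \code{"zero"} or \code{"decay"} for modes beyond
#'   the propagating band.
#' @slot boundary list(type = "periodic") or
#'   list(type = "absorbing", width, strength): a super-Gaussian absorbing
#'   frame applied each step to suppress FFT wrap-around.
#' @slot storeVolume logical; keep the full per-plane complex record.
#' @export
setClass("PropagatorConfig",
  representation(nRefMode = "character", evanescentPolicy = "character",
                 boundary = "list", storeVolume = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@nRefMode %in% c("global", "per_slice_mean"))
      msg <- c(msg, "nRefMode must be 'global' or 'per_slice_mean'")
    if (!object@evanescentPolicy %in% c("zero", "decay"))
      msg <- c(msg, "evanescentPolicy must be 'zero' or 'decay'")
    bt <- object@boundary$type
    if (is.null(bt) || !bt %in% c("periodic", "absorbing"))
      msg <- c(msg, "boundary$type must be 'periodic' or 'absorbing'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PropagatorConfig
#' @param nRefMode "per_slice_mean" (default) or "global".
#' @param evanescentPolicy "zero" (default) or "decay".
#' @param boundary "periodic" (default) or "absorbing"; absorbing takes
#'   \code{width} pixels (default 16) and \code{strength} (default 4).
#' @param width,strength absorbing-frame parameters.
#' @param storeVolume keep the full complex per-plane record.
#' @export
PropagatorConfig <- function(nRefMode = c("per_slice_mean", "global"),
                             evanescentPolicy = c("zero", "decay"),
                             boundary = c("periodic", "absorbing"),
                             width = 16L, strength = 4,
                             storeVolume = FALSE) {
  nRefMode <- match.arg(nRefMode)
  evanescentPolicy <- match.arg(evanescentPolicy)
  boundary <- match.arg(boundary)
  b <- if (boundary == "periodic") list(type = "periodic")
       else list(type = "absorbing", width = as.integer(width),
                 strength = as.numeric(strength))
  new("PropagatorConfig", nRefMode = nRefMode,
      evanescentPolicy = evanescentPolicy, boundary = b,
      storeVolume = isTRUE(storeVolume))
}

#' Pupil specification of an illumination or detection objective
#'
#' @slot na numerical aperture (0 < na <= nImmersion).
#' @slot wavelength vacuum wavelength (micrometers).
#' @slot nImmersion immersion index.
#' @slot kind one of "disk", "annulus", "cylindrical_slit", "lattice".
#' @slot kindArgs list: annulus needs \code{innerNa}; lattice takes
#'   \code{period} (micrometers, default 2*lambda/na) and \code{count}.
#' @slot tilt carrier spatial frequency (kx0, ky0) in rad/micrometer.
#' @export
setClass("PupilSpec",
  representation(na = "numeric", wavelength = "numeric",
                 nImmersion = "numeric", kind = "character",
                 kindArgs = "list", tilt = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@na <= 0 || object@na > object@nImmersion)
      msg <- c(msg, "need 0 < na <= nImmersion")
    if (!object@kind %in% c("disk", "annulus", "cylindrical_slit", "lattice"))
      msg <- c(msg, "unknown pupil kind")
    if (object@kind == "annulus") {
      inner <- object@kindArgs$innerNa
      if (is.null(inner) || inner < 0 || inner >= object@na)
        msg <- c(msg, "annulus requires 0 <= innerNa < na")
    }
    if (length(object@tilt) != 2L) msg <- c(msg, "tilt must be length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PupilSpec
#' @param na numerical aperture.
#' @param wavelength vacuum wavelength (micrometers).
#' @param nImmersion immersion index (default 1.33).
#' @param kind pupil support kind.
#' @param innerNa inner NA for an annulus.
#' @param period,count lattice spot spacing (micrometers) and spot count.
#' @param fill pupil fill for disks: "uniform" (hard aperture, Airy focus)
#'   or "gaussian" (apodized, NA = 3 sigma; exponentially decaying spot
#'   tails, used for multiplexed point sources).
#' @param tilt carrier (kx0, ky0) in rad/micrometer.
#' @export
PupilSpec <- function(na, wavelength, nImmersion = 1.33,
                      kind = c("disk", "annulus", "cylindrical_slit",
                               "lattice"),
                      innerNa = NULL, period = NULL, count = 5L,
                      fill = c("uniform", "gaussian"),
                      tilt = c(0, 0)) {
  kind <- match.arg(kind)
  ka <- list(fill = match.arg(fill))
  if (kind == "annulus") ka$innerNa <- as.numeric(innerNa)
  if (kind == "lattice") {
    ka$period <- if (is.null(period)) 2 * wavelength / na else as.numeric(period)
    ka$count <- as.integer(count)
    ka$innerNa <- if (is.null(innerNa)) 0.8 * na else as.numeric(innerNa)
  }
  new("PupilSpec", na = as.numeric(na), wavelength = as.numeric(wavelength),
      nImmersion = as.numeric(nImmersion), kind = kind, kindArgs = ka,
      tilt = as.numeric(tilt))
}

#' Source specification for an input field
#'
#' @slot kind one of "plane_wave", "gaussian", "cylindrical_sheet", "bessel",
#'   "bessel_lattice", "point_source".
#' @slot pupil the [PupilSpec-class].
#' @slot focus (x, y, z) focus position in micrometers (volume coordinates,
#'   origin at the volume corner; z measured from the entrance plane).
#' @slot normalization "power" (unit total power, default) or "none".
#' @export
setClass("SourceSpec",
  representation(kind = "character", pupil = "PupilSpec", focus = "numeric",
                 normalization = "character"),
  validity = function(object) {
    msg <- NULL
    kinds <- c("plane_wave", "gaussian", "cylindrical_sheet", "bessel",
               "bessel_lattice", "point_source")
    if (!object@kind %in% kinds) msg <- c(msg, "unknown source kind")
    if (length(object@focus) != 3L) msg <- c(msg, "focus must be length 3")
    if (!object@normalization %in% c("power", "none"))
      msg <- c(msg, "normalization must be 'power' or 'none'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SourceSpec
#' @param kind source kind.
#' @param pupil a [PupilSpec-class].
#' @param focus (x, y, z) focus position in micrometers.
#' @param normalization "power" or "none".
#' @export
SourceSpec <- function(kind = c("plane_wave", "gaussian", "cylindrical_sheet",
                                "bessel", "bessel_lattice", "point_source"),
                       pupil, focus = c(0, 0, 0),
                       normalization = c("power", "none")) {
  new("SourceSpec", kind = match.arg(kind), pupil = pupil,
      focus = as.numeric(focus), normalization = match.arg(normalization))
}

#' Tile layout for multiplexed PSF computation
#'
#' Tiles partition the transverse plane; one diffraction-limited point source
#' sits at each tile center in the focal plane, and each tile's PSF is
#' extracted from the common refocused stack.
#'
#' @slot tileNx,tileNy tiles per plane.
#' @slot tileSize pixels per (square) tile.
#' @slot sourcePositions matrix (nTiles x 3) of (x, y, z) in micrometers.
#' @slot guardMargin pixels of the tile-border ring used for the cross-talk
#'   check.
#' @export
setClass("TileLayout",
  representation(tileNx = "integer", tileNy = "integer", tileSize = "integer",
                 sourcePositions = "matrix", guardMargin = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@sourcePositions) != 3L)
      msg <- c(msg, "sourcePositions must have 3 columns")
    if (nrow(object@sourcePositions) != object@tileNx * object@tileNy)
      msg <- c(msg, "one source position per tile required")
    if (object@guardMargin < 1L) msg <- c(msg, "guardMargin must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Set of spatially varying volumetric PSFs for one focal plane
#'
#' @slot layout the [TileLayout-class].
#' @slot psfs list of 3D non-negative arrays (tile x tile x z-offsets), each
#'   normalized to unit integral.
#' @slot rawIntegrals numeric per tile: the pre-normalization integral
#'   (detection-path transmission; equals collected power for a unit source).
#' @slot planeZ focal plane (micrometers) these PSFs serve.
#' @slot zOffsets axial offsets (micrometers) of the PSF planes relative to
#'   the focal plane.
#' @slot dx,dy,dz sampling of the PSF arrays.
#' @slot crosstalk per-tile border-ring energy fraction.
#' @slot flags per-tile logical: cross-talk above tolerance.
#' @slot exitFields optional list of per-tile complex focus-plane fields
#'   (kept on request for aberration analysis).
#' @export
setClass("PSFSet",
  representation(layout = "TileLayout", psfs = "list",
                 rawIntegrals = "numeric", planeZ = "numeric",
                 zOffsets = "numeric", dx = "numeric", dy = "numeric",
                 dz = "numeric", crosstalk = "numeric", flags = "logical",
                 exitFields = "list"),
  validity = function(object) {
    msg <- NULL
    nt <- object@layout@tileNx * object@layout@tileNy
    if (length(object@psfs) != nt) msg <- c(msg, "one PSF per tile required")
    for (p in object@psfs) {
      if (min(p) < 0) { msg <- c(msg, "PSFs must be non-negative"); break }
    }
    if (length(object@rawIntegrals) != nt)
      msg <- c(msg, "one raw integral per tile required")
    else if (any(object@rawIntegrals <= 0))
      msg <- c(msg, "raw integrals must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Paired refractive + fluorophore phantom with ground truth
#'
#' @slot refractive the [RefractiveVolume-class].
#' @slot fluor the [FluorophoreVolume-class] on the same grid.
#' @slot truth list of ground-truth records (object positions, labels,
#'   generator parameters, seed).
#' @export
setClass("Phantom",
  representation(refractive = "RefractiveVolume", fluor = "FluorophoreVolume",
                 truth = "list"),
  validity = function(object) {
    g1 <- object@refractive@grid; g2 <- object@fluor@grid
    if (!identical(c(g1@nx, g1@ny, g1@nz), c(g2@nx, g2@ny, g2@nz)))
      "refractive and fluorophore volumes must share the grid" else TRUE
  })

#' Simulated camera image
#'
#' @slot values non-negative intensity matrix.
#' @slot dx,dy pixel pitch (micrometers).
#' @slot planeZ focal-plane position (micrometers).
#' @slot provenance list describing illumination, PSF layout and blend mode.
#' @export
setClass("CameraImage",
  representation(values = "matrix", dx = "numeric", dy = "numeric",
                 planeZ = "numeric", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (any(!is.finite(object@values))) msg <- c(msg, "image must be finite")
    else if (min(object@values) < -1e-12 * max(abs(object@values), 1))
      msg <- c(msg, "image must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Stack of camera images over scanned focal planes
#'
#' @slot images list of [CameraImage-class] at uniformly spaced planes.
#' @slot zStep scan step (micrometers).
#' @export
setClass("ImageStack",
  representation(images = "list", zStep = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@images) >= 2L) {
      zs <- vapply(object@images, function(im) im@planeZ, numeric(1))
      if (max(abs(diff(zs) - object@zStep)) > 1e-9 * max(abs(zs), 1))
        msg <- c(msg, "focal planes must be uniformly spaced by zStep")
      d <- vapply(object@images, function(im) dim(im@values), integer(2))
      if (any(d != d[, 1])) msg <- c(msg, "inconsistent image shapes")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Focus-quality report for adaptive-optics experiments
#'
#' @slot peak peak intensity near the target position.
#' @slot strehl peak / ideal diffraction-limited peak at equal power and NA.
#' @slot fwhmLateral,fwhmAxial intensity FWHM (micrometers).
#' @slot positionError distance of the measured peak from the target
#'   (micrometers).
#' @export
setClass("FocusReport",
  representation(peak = "numeric", strehl = "numeric",
                 fwhmLateral = "numeric", fwhmAxial = "numeric",
                 positionError = "numeric"),
  validity = function(object) {
    if (object@strehl < 0 || object@strehl > 1.05)
      "Strehl must lie in [0, 1] (+5% numerical slack)" else TRUE
  })

#' Shift-shift memory-effect curve
#'
#' @slot shifts lateral shifts (micrometers).
#' @slot correlation C(shift) = refocused peak intensity ratio I(shift)/I(0).
#' @slot reference plane-wave speckle intensity autocorrelation on the same
#'   shift axis.
#' @slot depth guide-star depth (micrometers).
#' @slot depthMfp the same depth in scattering mean free paths.
#' @export
setClass("MemoryEffectCurve",
  representation(shifts = "numeric", correlation = "numeric",
                 reference = "numeric", depth = "numeric",
                 depthMfp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@correlation) != length(object@shifts) ||
        length(object@reference) != length(object@shifts))
      msg <- c(msg, "curves must share the shift axis")
    i0 <- which.min(abs(object@shifts))
    if (length(i0) && abs(object@correlation[i0] - 1) > 1e-9)
      msg <- c(msg, "C(0) must equal 1")
    if (is.null(msg)) TRUE else msg
  })

#' Spatially resolved Zernike aberration map
#'
#' @slot coefficients data.frame with columns tileX, tileY, j (Noll index),
#'   coefficient (radians RMS).
#' @slot jMax highest Noll index fitted.
#' @slot na,wavelength pupil used for the fit.
#' @slot residualRms per-tile RMS of the unexplained pupil phase.
#' @export
setClass("ZernikeMap",
  representation(coefficients = "data.frame", jMax = "integer",
                 na = "numeric", wavelength = "numeric",
                 residualRms = "numeric"))
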