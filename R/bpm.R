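## Split-step beam propagation core.
##
## A scalar field u(x, y) is advanced through an inhomogeneous medium by
## alternating two exact sub-steps:
##   diffraction:  U(kx, ky) <- U * exp(i * dz * sqrt((n0 k0)^2 - kx^2 - ky^2))
##   refraction:   u(x, y)   <- u * exp(i * k0 * (n(x, y) - n0) * dz)
## The diffraction kernel is the exact (non-paraxial) angular-spectrum
## propagator for a homogeneous medium of reference index n0; the phase
## screen carries the residual, locally varying index. Choosing n0 as the
## per-slice mean real index keeps the residual small (the locally adapted
## expansion), which is what preserves accuracy beyond the paraxial regime.

## Angular-spectrum transfer function. dz may be negative (backward
## propagation). Evanescent modes (kx^2+ky^2 > (n0 k0)^2) are zeroed or
## damped by exp(-|dz| * kappa_z).
angularSpectrumKernel <- function(nx, ny, dx, dy, wavelength, dz, n0,
                                  evanescentPolicy = "zero") {
  k0 <- 2 * pi / wavelength
  kg <- kGrids(nx, ny, dx, dy)
  kz2 <- (n0 * k0)^2 - outer(kg$kx^2, rep(1, ny)) -
    outer(rep(1, nx), kg$ky^2)
  prop <- kz2 > 0
  H <- matrix(0i, nx, ny)
  H[prop] <- exp(1i * dz * sqrt(kz2[prop]))
  if (evanescentPolicy == "decay")
    H[!prop] <- exp(-abs(dz) * sqrt(-kz2[!prop]))
  H
}

#' Advance a field through homogeneous medium (exact angular spectrum)
#'
#' Applies the exact non-paraxial free-space propagator
#' \eqn{\exp(i\,dz\sqrt{(n_0 k_0)^2 - k_x^2 - k_y^2})} in the transverse
#' spatial-frequency domain. Modes beyond the propagating band are zeroed
#' (\code{policy = "zero"}) or exponentially damped (\code{"decay"}).
#'
#' @param field a [ComplexField-class].
#' @param dz step length in micrometers (>= 0).
#' @param n0 homogeneous (reference) refractive index.
#' @param evanescentPolicy "zero" or "decay".
#' @return the advanced [ComplexField-class] with z increased by dz.
#' @examples
#' u <- planeWaveField(32, 32, dx = 0.2, wavelength = 0.5)
#' v <- freeSpaceStep(u, dz = 5, n0 = 1.33)
#' @export
freeSpaceStep <- function(field, dz, n0, evanescentPolicy = c("zero", "decay")) {
  evanescentPolicy <- match.arg(evanescentPolicy)
  if (!is.finite(n0) || n0 <= 0) stop("n0 must be a positive index")
  if (dz < 0) stop("dz must be >= 0 (backward propagation is internal-only)")
  if (any(is.na(field@values))) stop("field contains NaN values")
  if (field@dx > field@wavelength / (2 * n0) + 1e-12)
    warning("transverse sampling dx > lambda/(2 n0); high-NA content aliases")
  if (dz == 0) return(field)
  u <- stepField(field@values, field@dx, field@dy, field@wavelength, dz, n0,
                 evanescentPolicy)
  ComplexField(u, field@dx, field@dy, field@wavelength, field@z + dz)
}

## Unchecked kernel application on a raw complex matrix; signed dz allowed.
stepField <- function(values, dx, dy, wavelength, dz, n0, evanescentPolicy) {
  H <- angularSpectrumKernel(nrow(values), ncol(values), dx, dy, wavelength,
                             dz, n0, evanescentPolicy)
  ifft2(fft2(values) * H)
}

#' Apply a thin refractive phase screen
#'
#' Pointwise multiplication \eqn{u \leftarrow u\,
#' \exp(i k_0 (n_{slice} - n_0)\,dz)}; an imaginary index component gives
#' Beer-Lambert amplitude decay \eqn{\exp(-k_0\,\mathrm{Im}(n)\,dz)}.
#'
#' @param field a [ComplexField-class].
#' @param nSlice complex index map matching the field shape.
#' @param n0 reference index already accounted for by the diffraction step.
#' @param dz slice thickness in micrometers.
#' @return the phase-shifted [ComplexField-class] (z unchanged; the screen
#'   is thin).
#' @export
phaseScreenStep <- function(field, nSlice, n0, dz) {
  if (!all(dim(nSlice) == dim(field@values)))
    stop("nSlice shape must match the field")
  k0 <- 2 * pi / field@wavelength
  u <- field@values * exp(1i * k0 * (nSlice - n0) * dz)
  ComplexField(u, field@dx, field@dy, field@wavelength, field@z)
}

#' Propagate a field through a refractive-index volume
#'
#' Symmetric split-step scheme: for each slice, a half diffraction step
#' dz/2 at the reference index, the slice phase screen over the full dz,
#' and a second half diffraction step (second-order accurate in dz). With
#' \code{nRefMode = "per_slice_mean"} the reference index of each slice is
#' its mean real index; with \code{"global"} it is the ambient index.
#'
#' @param initial the entrance [ComplexField-class] (pitch must match the
#'   volume's transverse pitch).
#' @param volume a [RefractiveVolume-class]; propagation runs along its
#'   third (z) axis.
#' @param config a [PropagatorConfig-class].
#' @return list with \code{field} (the exit [ComplexField-class]),
#'   \code{planePowers} (power after each slice), and, with
#'   \code{storeVolume}, \code{record} — complex array (nx, ny, nz) of the
#'   field after each slice.
#' @examples
#' g <- Grid3D(32, 32, 16, dx = 0.2)
#' vol <- RefractiveVolume(g)
#' u <- planeWaveField(32, 32, dx = 0.2, wavelength = 0.5)
#' out <- propagate(u, vol)
#' @export
propagate <- function(initial, volume, config = PropagatorConfig()) {
  g <- volume@grid
  if (abs(initial@dx - g@dx) > 1e-12 || abs(initial@dy - g@dy) > 1e-12)
    stop("field pitch must match the volume transverse pitch")
  if (!all(dim(initial@values) == c(g@nx, g@ny)))
    stop("field shape must match the volume transverse shape")
  if (g@dz > initial@dx + 1e-12)
    warning("dz > dx: split-step accuracy degrades for high-NA content")

  u <- initial@values
  dz <- g@dz
  pol <- config@evanescentPolicy
  mask <- NULL
  if (config@boundary$type == "absorbing")
    mask <- absorbingMask(g@nx, g@ny, config@boundary$width,
                          config@boundary$strength)
  k0 <- 2 * pi / initial@wavelength
  record <- if (config@storeVolume)
    array(0i, dim = c(g@nx, g@ny, g@nz)) else NULL
  planePowers <- numeric(g@nz)
  dA <- g@dx * g@dy

  ## cache diffraction kernels per reference index (hit rate is high for
  ## piecewise-homogeneous media)
  kernCache <- new.env(parent = emptyenv())
  halfKernel <- function(n0) {
    key <- sprintf("%.15g", n0)
    H <- kernCache[[key]]
    if (is.null(H)) {
      H <- angularSpectrumKernel(g@nx, g@ny, g@dx, g@dy, initial@wavelength,
                                 dz / 2, n0, pol)
      kernCache[[key]] <- H
    }
    H
  }

  for (iz in seq_len(g@nz)) {
    nSlice <- volume@n[, , iz]
    n0 <- if (config@nRefMode == "per_slice_mean") mean(Re(nSlice))
          else volume@nAmbient
    H <- halfKernel(n0)
    u <- ifft2(fft2(u) * H)
    u <- u * exp(1i * k0 * (nSlice - n0) * dz)
    u <- ifft2(fft2(u) * H)
    if (!is.null(mask)) u <- u * mask
    planePowers[iz] <- sum(Mod(u)^2) * dA
    if (!is.null(record)) record[, , iz] <- u
  }

  out <- list(field = ComplexField(u, g@dx, g@dy, initial@wavelength,
                                   initial@z + g@nz * dz),
              planePowers = planePowers)
  if (!is.null(record)) out$record <- record
  out
}
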