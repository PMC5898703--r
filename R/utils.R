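`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats fft rnorm runif setNames sd lm coef mvfft
NULL

## DFT sample frequencies (cycles per unit), numpy fftfreq layout.
fftFreq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L) / (n * d)
}

## Angular spatial-frequency grids (rad/um) for an (nx, ny) field.
kGrids <- function(nx, ny, dx, dy) {
  list(kx = 2 * pi * fftFreq(nx, dx), ky = 2 * pi * fftFreq(ny, dy))
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

## Center the zero frequency (or center coordinate) of a matrix.
fftShift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1L):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1L):nc, 1:floor(nc / 2)), drop = FALSE]
}

## Physical coordinates of grid samples, origin at the first voxel center.
axisCoords <- function(n, d) (seq_len(n) - 1L) * d

## Center coordinate used for on-axis sources (matches an FFT-friendly
## integer voxel: index n/2 + 1).
centerCoord <- function(n, d) (floor(n / 2)) * d

## Super-Gaussian absorbing frame mask (1 in the interior, smoothly
## falling to exp(-strength) at the border) over `width` pixels.
absorbingMask <- function(nx, ny, width, strength) {
  edge <- function(n) {
    i <- seq_len(n)
    d <- pmin(i - 1L, n - i)                # distance to nearest edge, px
    t <- pmax(0, 1 - d / width)
    exp(-strength * t^4)
  }
  outer(edge(nx), edge(ny))
}

## Intensity FWHM of a sampled 1D profile by linear interpolation of the
## half-maximum crossings around the global peak. Returns NA when the
## profile does not fall below half max on both sides.
profileFwhm <- function(x, values) {
  i0 <- which.max(values)
  half <- values[i0] / 2
  left <- NA_real_; right <- NA_real_
  i <- i0
  while (i >= 2L) {
    if (values[i - 1L] <= half && values[i] > half) {
      f <- (values[i] - half) / (values[i] - values[i - 1L])
      left <- x[i] - f * (x[i] - x[i - 1L]); break
    }
    i <- i - 1L
  }
  i <- i0
  while (i <= length(values) - 1L) {
    if (values[i + 1L] <= half && values[i] > half) {
      f <- (values[i] - half) / (values[i] - values[i + 1L])
      right <- x[i] + f * (x[i + 1L] - x[i]); break
    }
    i <- i + 1L
  }
  right - left
}

## Relative L2 distance between two arrays of identical shape.
relL2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

#' Reorient a volume so a chosen lab axis becomes the propagation axis
#'
#' The propagator always advances fields along the third array axis. Imaging
#' geometries with orthogonal illumination/detection are realized by
#' permuting the volume, propagating, and permuting back.
#'
#' @param x a [RefractiveVolume-class], [FluorophoreVolume-class] or plain
#'   3D array.
#' @param axis which current axis ("x", "y" or "z", or 1:3) should become
#'   the propagation (third) axis.
#' @return object of the same class with axes permuted; the permutation is
#'   an involution (applying it twice restores the input).
#' @examples
#' g <- Grid3D(8, 12, 16, dx = 0.5)
#' v <- RefractiveVolume(g)
#' vx <- reorientVolume(v, "x")
#' simGrid(vx)   # 16 x 12 x 8
#' @export
reorientVolume <- function(x, axis = c("z", "x", "y")) {
  if (is.character(axis)) axis <- match(match.arg(axis), c("x", "y", "z"))
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  perm <- switch(axis, c(3L, 2L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
  permGrid <- function(g) {
    cnt <- c(g@nx, g@ny, g@nz)[perm]
    pit <- c(g@dx, g@dy, g@dz)[perm]
    Grid3D(cnt[1], cnt[2], cnt[3], dx = pit[1], dy = pit[2], dz = pit[3])
  }
  if (is(x, "RefractiveVolume"))
    return(RefractiveVolume(permGrid(x@grid), aperm(x@n, perm), x@nAmbient))
  if (is(x, "FluorophoreVolume"))
    return(FluorophoreVolume(permGrid(x@grid), aperm(x@density, perm)))
  aperm(x, perm)
}

## Reverse the slice order along the propagation axis (for reciprocal /
## backward traversal of a volume).
reverseVolume <- function(vol) {
  RefractiveVolume(vol@grid, vol@n[, , vol@grid@nz:1, drop = FALSE],
                   vol@nAmbient)
}

## Derive an independent 32-bit substream seed from a root seed and a
## stream label, so modules are reproducible in isolation.
substreamSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147480009)
}

## Trilinear-shift a 2D field by a sub-voxel amount via its spectrum.
fourierShift2 <- function(values, shiftX, shiftY, dx, dy) {
  nx <- nrow(values); ny <- ncol(values)
  k <- kGrids(nx, ny, dx, dy)
  ph <- exp(-1i * outer(k$kx * shiftX, rep(1, ny))) *
        exp(-1i * outer(rep(1, nx), k$ky * shiftY))
  ifft2(fft2(values) * ph)
}
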