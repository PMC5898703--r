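## Zernike decomposition of sample-induced pupil aberrations.
##
## Basis: Noll-ordered, RMS-normalized Zernike polynomials on the unit
## pupil disk (Z1 piston, Z2/Z3 tilt, Z4 defocus, ...). Coefficients are
## in radians of RMS wavefront. The fit is an ordinary least squares on
## pupil samples restricted to 0.95 * NA to avoid rim artifacts.

#' Noll index to radial degree and azimuthal frequency
#' @param j Noll index (>= 1).
#' @return integer vector c(n, m) with signed m (negative = sine term).
#' @export
nollIndex <- function(j) {
  stopifnot(j >= 1)
  n <- 0L; jj <- j - 1L
  while (jj > n) { n <- n + 1L; jj <- jj - n }
  m <- (-1L)^j * (n %% 2L + 2L * ((jj + (n + 1L) %% 2L) %/% 2L))
  c(n = n, m = as.integer(m))
}

zernikeRadial <- function(n, mAbs, rho) {
  out <- numeric(length(rho))
  for (k in 0:((n - mAbs) %/% 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + mAbs) %/% 2 - k) *
         factorial((n - mAbs) %/% 2 - k)) * rho^(n - 2 * k)
  }
  out
}

#' Evaluate a Noll-ordered Zernike polynomial
#'
#' RMS-normalized: the mean square of each polynomial over the unit disk
#' is 1 (piston included).
#'
#' @param j Noll index.
#' @param rho radial coordinate (0..1).
#' @param theta azimuth (radians).
#' @return numeric values of Z_j.
#' @export
zernikeNoll <- function(j, rho, theta) {
  nm <- nollIndex(j)
  n <- nm[1]; m <- nm[2]
  R <- zernikeRadial(n, abs(m), rho)
  if (m == 0) return(sqrt(n + 1) * R)
  if (m > 0) sqrt(2 * (n + 1)) * R * cos(abs(m) * theta)
  else sqrt(2 * (n + 1)) * R * sin(abs(m) * theta)
}

## Sequential phase unwrap inside a convex (disk) mask: unwrap the center
## column, then each row outward from the center column. Adequate for
## smooth, residue-free pupil phases; residue-laden tiles are flagged by
## the caller via the residual RMS.
unwrapDiskPhase <- function(phase, mask) {
  wrapToPi <- function(a) (a + pi) %% (2 * pi) - pi
  nx <- nrow(phase); ny <- ncol(phase)
  out <- phase
  jc <- which.max(colSums(mask))
  ## center column
  rows <- which(mask[, jc])
  if (length(rows) > 1L) {
    ic <- rows[ceiling(length(rows) / 2)]
    for (i in rev(rows[rows < ic]))
      out[i, jc] <- out[i + 1L, jc] + wrapToPi(out[i, jc] - out[i + 1L, jc])
    for (i in rows[rows > ic])
      out[i, jc] <- out[i - 1L, jc] + wrapToPi(out[i, jc] - out[i - 1L, jc])
  }
  for (i in seq_len(nx)) {
    cols <- which(mask[i, ])
    if (!length(cols)) next
    if (!mask[i, jc]) next
    for (jj in rev(cols[cols < jc]))
      out[i, jj] <- out[i, jj + 1L] + wrapToPi(out[i, jj] - out[i, jj + 1L])
    for (jj in cols[cols > jc])
      out[i, jj] <- out[i, jj - 1L] + wrapToPi(out[i, jj] - out[i, jj - 1L])
  }
  out
}

#' Decompose a pupil phase (or a tile's focus field) into Zernike modes
#'
#' For a complex in-focus field the pupil phase is recovered by a Fourier
#' transform to the pupil plane (zero-padded for adequate pupil sampling).
#' The phase is unwrapped inside the fit disk and fit by least squares
#' against the RMS-normalized Noll basis on 0.95 * NA.
#'
#' @param x either a numeric matrix of pupil phase sampled on a square
#'   k-grid covering the NA disk, or a complex matrix (a tile's in-focus
#'   field sampled at pitch \code{dx}).
#' @param pupil the [PupilSpec-class] (NA and wavelength of the fit).
#' @param jMax highest Noll index (default 15).
#' @param dx field pitch in micrometers (required for complex input).
#' @param pad FFT padding size for complex input (default 256).
#' @return list with \code{coefficients} (length jMax, radians RMS),
#'   \code{residualRms}, and \code{phase} (the unwrapped pupil phase used).
#' @examples
#' pup <- PupilSpec(0.5, 0.522)
#' ph <- zernikePhaseMap(c(0, 0, 0, 0.3), 64)  # 0.3 rad RMS defocus
#' fit <- zernikeDecompose(ph, pup)
#' @export
zernikeDecompose <- function(x, pupil, jMax = 15L, dx = NULL, pad = 256L) {
  if (is.complex(x)) {
    if (is.null(dx)) stop("dx is required for a complex field input")
    k0 <- 2 * pi / pupil@wavelength
    n <- max(pad, dim(x))
    big <- matrix(0i, n, n)
    ## place the tile's center pixel at the FFT origin (wrap-around) so the
    ## pupil phase carries no carrier ramp or sign alternation
    ci <- floor(nrow(x) / 2) + 1L; cj <- floor(ncol(x) / 2) + 1L
    ix <- ((seq_len(nrow(x)) - ci) %% n) + 1L
    jx <- ((seq_len(ncol(x)) - cj) %% n) + 1L
    big[ix, jx] <- x
    Uk <- fftShift2(fft2(big))
    dk <- 2 * pi / (n * dx)
    kc <- floor(n / 2) + 1L
    kRad <- k0 * pupil@na / dk            # pupil radius in pixels
    npx <- max(8L, ceiling(kRad))
    sel <- (kc - npx):(kc + npx)
    sub <- Uk[sel, sel]
    co <- seq(-npx, npx) / kRad
    rho <- sqrt(outer(co^2, rep(1, length(co))) +
                outer(rep(1, length(co)), co^2))
    theta <- atan2(outer(rep(1, length(co)), co), outer(co, rep(1, length(co))))
    phase <- Arg(sub)
    ## for a recovered pupil the rim of the NA disk can carry negligible
    ## amplitude (apodized sources): weight the fit by the pupil intensity
    weights <- Mod(sub)^2
  } else {
    phase <- x
    n <- nrow(x)
    co <- seq(-1, 1, length.out = n)
    rho <- sqrt(outer(co^2, rep(1, n)) + outer(rep(1, n), co^2))
    theta <- atan2(outer(rep(1, n), co), outer(co, rep(1, n)))
    weights <- matrix(1, n, n)
  }
  mask <- rho <= 0.95
  uw <- unwrapDiskPhase(phase, mask)
  rhoV <- rho[mask]; thV <- theta[mask]; phV <- uw[mask]
  wV <- weights[mask]
  wV <- wV / max(wV)
  X <- vapply(seq_len(jMax), function(j) zernikeNoll(j, rhoV, thV),
              numeric(length(rhoV)))
  fit <- stats::lm.wfit(X, phV, wV)
  resid <- phV - X %*% fit$coefficients
  list(coefficients = setNames(as.numeric(fit$coefficients),
                               paste0("Z", seq_len(jMax))),
       residualRms = sqrt(sum(wV * resid^2) / sum(wV)),
       phase = uw)
}

#' Synthesize a pupil phase map from Zernike coefficients
#'
#' @param coefficients numeric vector, Noll-ordered starting at j = 1.
#' @param n samples per side of the square map covering the unit disk.
#' @return numeric matrix; values outside the unit disk are 0.
#' @export
zernikePhaseMap <- function(coefficients, n = 64L) {
  co <- seq(-1, 1, length.out = n)
  rho <- sqrt(outer(co^2, rep(1, n)) + outer(rep(1, n), co^2))
  theta <- atan2(outer(rep(1, n), co), outer(co, rep(1, n)))
  out <- matrix(0, n, n)
  inside <- rho <= 1
  for (j in seq_along(coefficients)) {
    if (coefficients[j] == 0) next
    out[inside] <- out[inside] +
      coefficients[j] * zernikeNoll(j, rho[inside], theta[inside])
  }
  out
}

#' Zernike aberration map of a PSF set
#'
#' Decomposes every tile's recovered pupil phase (requires a PSF set built
#' with \code{keepExitFields = TRUE}) into Noll-ordered Zernike
#' coefficients.
#'
#' @param psfSet a [PSFSet-class] with exit fields.
#' @param pupil the detection [PupilSpec-class].
#' @param jMax highest Noll index (default 15).
#' @return a [ZernikeMap-class].
#' @export
zernikeMap <- function(psfSet, pupil, jMax = 15L) {
  if (!length(psfSet@exitFields))
    stop("PSF set was computed without keepExitFields = TRUE")
  lay <- psfSet@layout
  rows <- list(); res <- numeric(0)
  for (t in seq_along(psfSet@exitFields)) {
    tx <- (t - 1L) %% lay@tileNx + 1L
    ty <- (t - 1L) %/% lay@tileNx + 1L
    fit <- zernikeDecompose(psfSet@exitFields[[t]], pupil, jMax,
                            dx = psfSet@dx)
    rows[[t]] <- data.frame(tileX = tx, tileY = ty, j = seq_len(jMax),
                            coefficient = as.numeric(fit$coefficients))
    res[t] <- fit$residualRms
  }
  new("ZernikeMap", coefficients = do.call(rbind, rows),
      jMax = as.integer(jMax), na = pupil@na, wavelength = pupil@wavelength,
      residualRms = res)
}
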