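## Independent analytic / brute-force references used by the test suite and
## the validation report. None of these share propagation code with the
## modules they validate: the Mie series, the Fresnel edge integral and the
## direct Rayleigh-Sommerfeld summation are closed-form or O(N^4)
## evaluations of the underlying physics.

## ---- spherical Bessel functions --------------------------------------

sphBesselJ <- function(n, x) {
  out <- numeric(length(x))
  small <- x < 1e-12
  if (any(!small))
    out[!small] <- sqrt(pi / (2 * x[!small])) * besselJ(x[!small], n + 0.5)
  if (any(small)) out[small] <- if (n == 0L) 1 else 0
  out
}

sphBesselY <- function(n, x) {
  sqrt(pi / (2 * x)) * besselY(x, n + 0.5)
}

## Truncation order for size parameter x (Wiscombe-style)
mieNMax <- function(x) as.integer(ceiling(x + 4 * x^(1 / 3) + 2))

#' Specification of a (possibly coated) sphere for Mie validation
#'
#' @param radius outer radius in micrometers.
#' @param m relative refractive index of the sphere (outer shell for coated
#'   spheres) with respect to the ambient medium.
#' @param wavelength vacuum wavelength in micrometers.
#' @param nAmbient ambient index.
#' @param coreRadius,mCore optional core radius and relative core index for
#'   a coated sphere (core inside a shell of index \code{m}).
#' @return list with class "MieSpec".
#' @export
MieSpec <- function(radius, m, wavelength, nAmbient = 1.33,
                    coreRadius = NULL, mCore = NULL) {
  if (abs(m - 1) > 0.2)
    warning("|m - 1| > 0.2: outside the low-contrast regime where the BPM comparison is meaningful")
  structure(list(radius = radius, m = m, wavelength = wavelength,
                 nAmbient = nAmbient, coreRadius = coreRadius,
                 mCore = mCore),
            class = "MieSpec")
}

## ---- scalar partial-wave series (near field) -------------------------
##
## The BPM solves the scalar Helmholtz equation, so its like-for-like
## analytic reference is scalar scattering by a penetrable sphere:
## continuity of u and du/dr at the boundary gives
##   b_n = [m j_n'(mx) j_n(x) - j_n(mx) j_n'(x)] /
##         [j_n(mx) h_n'(x) - m j_n'(mx) h_n(x)]
## with size parameter x = k a (k = ambient wavenumber).

scalarMieCoefficients <- function(x, m, nMax) {
  bn <- cn <- complex(nMax + 1L)
  jx <- vapply(0:(nMax + 1L), function(n) sphBesselJ(n, x), numeric(1))
  yx <- vapply(0:(nMax + 1L), function(n) sphBesselY(n, x), numeric(1))
  jm <- vapply(0:(nMax + 1L), function(n) sphBesselJ(n, m * x), numeric(1))
  hx <- jx + 1i * yx
  for (n in 0:nMax) {
    jnx <- jx[n + 1L]; hnx <- hx[n + 1L]; jnm <- jm[n + 1L]
    djx <- if (n == 0L) -jx[2L] else jx[n] - (n + 1) / x * jnx
    dhx <- if (n == 0L) -hx[2L] else hx[n] - (n + 1) / x * hnx
    djm <- if (n == 0L) -jm[2L] else jm[n] - (n + 1) / (m * x) * jnm
    bn[n + 1L] <- (m * djm * jnx - jnm * djx) / (jnm * dhx - m * djm * hnx)
    cn[n + 1L] <- (jnx + bn[n + 1L] * hnx) / jnm
  }
  list(bn = bn, cn = cn)
}

#' Scalar Mie near field behind a sphere
#'
#' Evaluates the partial-wave series of the scalar Helmholtz equation for a
#' unit plane wave exp(i k z) scattered by a homogeneous sphere, on a
#' transverse plane. Points inside the sphere use the interior expansion, so
#' the evaluation plane may intersect the sphere.
#'
#' @param spec a [MieSpec()] (solid sphere; the core fields are ignored).
#' @param x,y coordinate vectors of the evaluation plane (micrometers),
#'   relative to the sphere center.
#' @param zPlane axial position of the plane relative to the sphere center.
#' @param nMax optional truncation override (default
#'   \code{x + 4 x^(1/3) + 2}).
#' @return complex matrix u(x, y) of the total (incident + scattered) field.
#' @export
mieNearField <- function(spec, x, y, zPlane, nMax = NULL) {
  k <- 2 * pi / spec$wavelength * spec$nAmbient
  a <- spec$radius
  xs <- k * a
  if (is.null(nMax)) nMax <- mieNMax(xs)
  co <- scalarMieCoefficients(xs, spec$m, nMax)

  pts <- expand.grid(x = x, y = y)
  r <- sqrt(pts$x^2 + pts$y^2 + zPlane^2)
  r <- pmax(r, 1e-9)
  mu <- zPlane / r
  inside <- r < a

  u <- complex(length(r))
  ## incident plane wave (outside only; inside is replaced by the interior
  ## expansion)
  u[!inside] <- exp(1i * k * zPlane)

  pPrev <- rep(1, length(r))        # P_0
  pCur <- mu                        # P_1
  kr <- k * r
  mkr <- spec$m * kr
  for (n in 0:nMax) {
    Pn <- if (n == 0L) pPrev else if (n == 1L) pCur else {
      pNext <- ((2 * n - 1) * mu * pCur - (n - 1) * pPrev) / n
      pPrev <- pCur; pCur <- pNext
      pNext
    }
    pref <- (1i)^n * (2 * n + 1)
    if (any(!inside)) {
      hn <- sphBesselJ(n, kr[!inside]) + 1i * sphBesselY(n, kr[!inside])
      u[!inside] <- u[!inside] + pref * co$bn[n + 1L] * hn * Pn[!inside]
    }
    if (any(inside)) {
      jn <- sphBesselJ(n, mkr[inside])
      u[inside] <- u[inside] + pref * co$cn[n + 1L] * jn * Pn[inside]
    }
  }
  matrix(u, nrow = length(x))
}

## ---- vector Mie far field (phase function, efficiencies) -------------
##
## Standard unpolarized far-field quantities. Coefficients for solid and
## coated spheres are obtained by solving the boundary-condition system per
## order (continuity of w and dw/dr for TE modes, of w and dw/dr / m^2 for
## TM modes, where w is the radial Riccati function of the Debye potential),
## which reproduces the Bohren-Huffman closed forms and avoids their
## transcription-fragile coated-sphere recursion.

## radial basis value/derivative (wrt r, up to a common k factor) in a
## region of relative index mi at radius r (size parameter s = mi * k * r)
.riccBasis <- function(n, s, mi) {
  j <- sphBesselJ(n, s); jp <- sphBesselJ(n - 1L, s)
  y <- sphBesselY(n, s); yp <- sphBesselY(n - 1L, s)
  psi <- s * j
  dpsi <- mi * (s * jp - n * j)            # d/dr psi(mi k r) / k
  chi <- -s * y
  dchi <- -mi * (s * yp - n * y)
  cbind(psi = psi, dpsi = dpsi, chi = chi, dchi = dchi)
}

## Mie coefficients a_n (TM) and b_n (TE) for a solid or coated sphere.
mieCoefficients <- function(spec, nMax = NULL) {
  k <- 2 * pi / spec$wavelength * spec$nAmbient
  y <- k * spec$radius
  if (is.null(nMax)) nMax <- mieNMax(y)
  coated <- !is.null(spec$coreRadius) && !is.null(spec$mCore) &&
    spec$coreRadius < spec$radius && spec$mCore != spec$m
  an <- bn <- complex(nMax)
  for (n in seq_len(nMax)) {
    solveLayered <- function(tm) {
      wfac <- function(mi) if (tm) 1 / mi^2 else 1
      if (!coated) {
        ## unknowns: c (interior psi), a (scattered, exterior psi - a xi)
        bi <- .riccBasis(n, spec$m * y, spec$m)
        be <- .riccBasis(n, y, 1)
        xi <- be[1, "psi"] - 1i * be[1, "chi"]
        dxi <- be[1, "dpsi"] - 1i * be[1, "dchi"]
        A <- matrix(c(bi[1, "psi"], xi,
                      wfac(spec$m) * bi[1, "dpsi"], dxi), 2, 2, byrow = TRUE)
        rhs <- c(be[1, "psi"], be[1, "dpsi"])
        sc <- apply(Mod(A), 2, max)
        sc[sc == 0] <- 1
        sol <- solve(sweep(A, 2, sc, "/"), rhs) / sc
        return(sol[2])
      }
      x1 <- k * spec$coreRadius
      bCore <- .riccBasis(n, spec$mCore * x1, spec$mCore)
      bSh1 <- .riccBasis(n, spec$m * x1, spec$m)
      bSh2 <- .riccBasis(n, spec$m * y, spec$m)
      bExt <- .riccBasis(n, y, 1)
      xi <- bExt[1, "psi"] - 1i * bExt[1, "chi"]
      dxi <- bExt[1, "dpsi"] - 1i * bExt[1, "dchi"]
      ## unknowns: c (core), d, e (shell psi/chi), a (scattered)
      A <- matrix(0i, 4, 4)
      A[1, ] <- c(bCore[1, "psi"], -bSh1[1, "psi"], -bSh1[1, "chi"], 0)
      A[2, ] <- c(wfac(spec$mCore) * bCore[1, "dpsi"],
                  -wfac(spec$m) * bSh1[1, "dpsi"],
                  -wfac(spec$m) * bSh1[1, "dchi"], 0)
      A[3, ] <- c(0, bSh2[1, "psi"], bSh2[1, "chi"], xi)
      A[4, ] <- c(0, wfac(spec$m) * bSh2[1, "dpsi"],
                  wfac(spec$m) * bSh2[1, "dchi"], dxi)
      rhs <- c(0, 0, bExt[1, "psi"], bExt[1, "dpsi"])
      ## column equilibration: chi_n explodes for orders well above the
      ## size parameter, so the raw system is badly scaled though benign
      sc <- apply(Mod(A), 2, max)
      sc[sc == 0] <- 1
      sol <- solve(sweep(A, 2, sc, "/"), rhs) / sc
      sol[4]
    }
    an[n] <- solveLayered(tm = TRUE)
    bn[n] <- solveLayered(tm = FALSE)
  }
  list(an = an, bn = bn, x = y, nMax = nMax)
}

#' Far-field Mie phase function and scattering efficiency
#'
#' Unpolarized angular scattering distribution
#' \eqn{p(\theta) \propto (|S_1|^2 + |S_2|^2)/2} and the scattering
#' efficiency \eqn{Q_{sca} = (2/x^2)\sum (2n+1)(|a_n|^2+|b_n|^2)} for a
#' solid or coated sphere.
#'
#' @param spec a [MieSpec()].
#' @param theta scattering angles in radians.
#' @return list with \code{theta}, \code{p} (normalized to p(0) = 1),
#'   \code{S1}, \code{S2}, \code{Qsca}.
#' @export
miePhaseFunction <- function(spec, theta = seq(0, pi, length.out = 181)) {
  co <- mieCoefficients(spec)
  mu <- cos(theta)
  S1 <- S2 <- complex(length(theta))
  piPrev <- rep(0, length(mu))    # pi_0
  piCur <- rep(1, length(mu))     # pi_1
  for (n in seq_len(co$nMax)) {
    if (n > 1L) {
      piNext <- ((2 * n - 1) * mu * piCur - n * piPrev) / (n - 1)
      piPrev <- piCur; piCur <- piNext
    }
    tauN <- n * mu * piCur - (n + 1) * piPrev
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (co$an[n] * piCur + co$bn[n] * tauN)
    S2 <- S2 + f * (co$an[n] * tauN + co$bn[n] * piCur)
  }
  p <- (Mod(S1)^2 + Mod(S2)^2) / 2
  qsca <- (2 / co$x^2) *
    sum((2 * seq_len(co$nMax) + 1) * (Mod(co$an)^2 + Mod(co$bn)^2))
  list(theta = theta, p = p / p[1], S1 = S1, S2 = S2, Qsca = qsca)
}

## ---- Fresnel knife edge ----------------------------------------------

## Fresnel cosine/sine integrals C(v), S(v), vectorized (cumulative
## trapezoid on a fine grid; |error| << 1e-6 for the profile use here).
fresnelCS <- function(v) {
  vmax <- max(abs(v), 1e-6)
  h <- min(2e-4, vmax / 5e4 + 1e-9)
  t <- seq(0, vmax + h, by = h)
  fc <- cos(pi * t^2 / 2); fs <- sin(pi * t^2 / 2)
  C <- c(0, cumsum((fc[-1] + fc[-length(fc)]) / 2 * h))
  S <- c(0, cumsum((fs[-1] + fs[-length(fs)]) / 2 * h))
  idx <- abs(v) / h
  i0 <- pmin(floor(idx) + 1L, length(t) - 1L)
  frac <- idx - (i0 - 1L)
  Cv <- (C[i0] + frac * (C[i0 + 1L] - C[i0])) * sign(v)
  Sv <- (S[i0] + frac * (S[i0 + 1L] - S[i0])) * sign(v)
  list(C = Cv, S = Sv)
}

#' Fresnel-integral intensity profile behind a knife edge
#'
#' Closed-form diffraction of a unit plane wave by an opaque half-plane
#' (edge at x = 0, screen covering x < 0), observed at depth z in a medium
#' of index n. \eqn{I(x) = \tfrac12[(C(v)+\tfrac12)^2 + (S(v)+\tfrac12)^2]}
#' with \eqn{v = x \sqrt{2/(\lambda_{med} z)}}; the lit side tends to 1, the
#' edge line carries the classic value 1/4.
#'
#' @param x lateral positions (micrometers; positive = lit side).
#' @param z depth behind the edge (micrometers).
#' @param wavelength vacuum wavelength (micrometers).
#' @param n medium index.
#' @return numeric intensity at \code{x}.
#' @export
fresnelKnifeEdge <- function(x, z, wavelength, n = 1) {
  lamMed <- wavelength / n
  v <- x * sqrt(2 / (lamMed * z))
  cs <- fresnelCS(v)
  0.5 * ((cs$C + 0.5)^2 + (cs$S + 0.5)^2)
}

## ---- Gaussian beam ----------------------------------------------------

#' Closed-form Gaussian beam width
#'
#' \eqn{w(z) = w_0\sqrt{1 + (z/z_R)^2}} with Rayleigh range
#' \eqn{z_R = \pi w_0^2 n / \lambda_0}. The intensity FWHM is
#' \eqn{w(z)\sqrt{2\ln 2}}.
#'
#' @param z axial distance from the waist (micrometers).
#' @param w0 1/e^2 intensity waist radius (micrometers).
#' @param wavelength vacuum wavelength (micrometers).
#' @param n medium index.
#' @return list with \code{w}, \code{fwhm}, \code{zR}.
#' @export
gaussianBeamWidth <- function(z, w0, wavelength, n = 1) {
  zR <- pi * w0^2 * n / wavelength
  w <- w0 * sqrt(1 + (z / zR)^2)
  list(w = w, fwhm = w * sqrt(2 * log(2)), zR = zR)
}

## ---- direct Rayleigh-Sommerfeld summation ----------------------------

#' Direct Rayleigh-Sommerfeld diffraction (brute force)
#'
#' O(N^4) evaluation of the first Rayleigh-Sommerfeld integral
#' \deqn{u(P) = \frac{z}{2\pi}\int u_0\, e^{ikr}\Big(\frac1r - ik\Big)
#'   \frac{1}{r^2}\,dx'dy'}
#' on the same transverse grid, used as an implementation-independent
#' reference for the angular-spectrum step on small grids.
#'
#' @param field a [ComplexField-class] (grid at most 64 x 64).
#' @param dz propagation distance (> 0, micrometers).
#' @param n0 homogeneous medium index.
#' @return a [ComplexField-class] at z + dz.
#' @export
directDiffraction <- function(field, dz, n0) {
  nx <- nrow(field@values); ny <- ncol(field@values)
  if (nx > 64L || ny > 64L) stop("direct summation restricted to grids <= 64^2")
  if (dz == 0) return(field)
  k <- 2 * pi / field@wavelength * n0
  x <- axisCoords(nx, field@dx); y <- axisCoords(ny, field@dy)
  u0 <- field@values
  dA <- field@dx * field@dy
  out <- matrix(0i, nx, ny)
  xm <- outer(x, rep(1, ny)); ym <- outer(rep(1, nx), y)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      r <- sqrt((x[i] - xm)^2 + (y[j] - ym)^2 + dz^2)
      kern <- dz / (2 * pi) * exp(1i * k * r) * (1 / r - 1i * k) / r^2
      out[i, j] <- sum(u0 * kern) * dA
    }
  }
  ComplexField(out, field@dx, field@dy, field@wavelength, field@z + dz)
}

## ---- sequential PSF reference ----------------------------------------

#' Single-source PSF by sequential (non-multiplexed) computation
#'
#' Reference implementation for the multiplexing-equivalence tests: builds
#' one diffraction-limited point source at \code{sourcePos} in the focal
#' plane, propagates it through the detection-side half volume, crops the
#' exit spectrum to the detection NA, refocuses plane by plane, and crops a
#' tile around the source. Shares the elementary propagator with the rest of
#' the package but none of the tiling/multiplexing machinery.
#'
#' @param volume a [RefractiveVolume-class] (detection axis = z).
#' @param sourcePos (x, y, z) of the emitter in micrometers.
#' @param detectPupil a [PupilSpec-class] for the detection lens.
#' @param tileSize half-size (pixels) of the extracted PSF window.
#' @param zOffsets axial offsets (micrometers) of the refocus planes
#'   relative to the source plane.
#' @param config a [PropagatorConfig-class].
#' @param sourceFill source-pupil fill ("gaussian" apodized, the engine
#'   default, or "uniform" for a hard Airy source).
#' @return list with \code{psf} (3D array, unit integral), \code{rawIntegral},
#'   and \code{focusField} (complex in-focus tile).
#' @export
sequentialPSF <- function(volume, sourcePos, detectPupil, tileSize,
                          zOffsets = 0, config = PropagatorConfig(),
                          sourceFill = c("gaussian", "uniform")) {
  g <- volume@grid
  ka <- detectPupil@kindArgs
  ka$fill <- match.arg(sourceFill)
  srcPupil <- new("PupilSpec", na = detectPupil@na,
                  wavelength = detectPupil@wavelength,
                  nImmersion = detectPupil@nImmersion,
                  kind = detectPupil@kind, kindArgs = ka,
                  tilt = detectPupil@tilt)
  src <- SourceSpec("point_source", srcPupil,
                    focus = c(sourcePos[1], sourcePos[2], 0))
  u0 <- makeField(src, g)
  iz0 <- as.integer(round(sourcePos[3] / g@dz)) + 1L
  nzH <- g@nz - iz0 + 1L
  if (iz0 < 1L || nzH < 8L)
    stop("source plane must lie at least 8 slices before the exit surface")
  half <- RefractiveVolume(
    Grid3D(g@nx, g@ny, nzH, dx = g@dx, dy = g@dy, dz = g@dz),
    volume@n[, , iz0:g@nz, drop = FALSE], volume@nAmbient)
  ex <- propagate(u0, half, config)$field
  travel <- nzH * g@dz
  ## detection NA crop + refocus (own loop, no psf_engine code)
  k0 <- 2 * pi / u0@wavelength
  kg <- kGrids(g@nx, g@ny, g@dx, g@dy)
  krm <- sqrt(outer(kg$kx^2, rep(1, g@ny)) + outer(rep(1, g@nx), kg$ky^2))
  Uk <- fft2(ex@values)
  Uk[krm > k0 * detectPupil@na] <- 0i
  n0 <- detectPupil@nImmersion
  ix <- as.integer(round(sourcePos[1] / g@dx)) + 1L
  iy <- as.integer(round(sourcePos[2] / g@dy)) + 1L
  offs <- seq_len(tileSize) - 1L - tileSize %/% 2L
  xs <- (ix + offs - 1L) %% g@nx + 1L
  ys <- (iy + offs - 1L) %% g@ny + 1L
  psf <- array(0, dim = c(tileSize, tileSize, length(zOffsets)))
  focusField <- NULL
  for (iz in seq_along(zOffsets)) {
    d <- -travel + zOffsets[iz]
    H <- angularSpectrumKernel(g@nx, g@ny, g@dx, g@dy, u0@wavelength, d, n0,
                               "zero")
    up <- ifft2(Uk * H)
    psf[, , iz] <- Mod(up[xs, ys])^2
    if (abs(zOffsets[iz]) < 1e-12) focusField <- up[xs, ys]
  }
  rawIntegral <- sum(psf[, , which.min(abs(zOffsets))]) * g@dx * g@dy
  list(psf = psf / sum(psf), rawIntegral = rawIntegral,
       focusField = focusField)
}
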