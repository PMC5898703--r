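## Light-sheet image formation. Lab-frame convention: the illumination
## sheet propagates along lab x, the detection lens looks along lab z.
## Volumes are stored in lab frame (x, y, z); reorientation to the
## propagator's axis happens internally.

#' Excitation intensity of an illumination field in the sample
#'
#' Propagates the illumination source (sheet, beam, or incoherent set of
#' sources) along lab x through the sample and returns the 3D excitation
#' intensity. Coherent sources give |u|^2 of the propagated field;
#' incoherent sets average member intensities.
#'
#' @param volume a [RefractiveVolume-class] in lab frame.
#' @param illum a [SourceSpec-class], or a list of them / of
#'   [ComplexField-class] members treated as an incoherent set. Source
#'   focus positions are in lab coordinates.
#' @param sheetZ detection-plane position (micrometers); overrides the lab-z
#'   focus component so the sheet is centered on the imaged plane.
#' @param config a [PropagatorConfig-class].
#' @return list with \code{intensity} (lab-frame nx x ny x nz array) and
#'   \code{planePowers} (power vs illumination depth, for attenuation
#'   diagnostics).
#' @export
excitationVolume <- function(volume, illum, sheetZ = NULL,
                             config = PropagatorConfig()) {
  volR <- reorientVolume(volume, "x")   # (lab z, lab y, lab x)
  gR <- volR@grid
  cfg <- new("PropagatorConfig", nRefMode = config@nRefMode,
             evanescentPolicy = config@evanescentPolicy,
             boundary = config@boundary, storeVolume = TRUE)
  toField <- function(src) {
    if (is(src, "ComplexField")) return(src)
    if (!is(src, "SourceSpec"))
      stop("invalid-parameter: illumination must be SourceSpec or ComplexField")
    f <- src@focus
    fR <- c(if (is.null(sheetZ)) f[3] else sheetZ, f[2], f[1])
    makeField(new("SourceSpec", kind = src@kind, pupil = src@pupil,
                  focus = fR, normalization = src@normalization), gR)
  }
  members <- if (is.list(illum)) illum else list(illum)
  acc <- NULL; pow <- NULL
  for (m in members) {
    u0 <- toField(m)
    out <- propagate(u0, volR, cfg)
    I <- Mod(out$record)^2
    acc <- if (is.null(acc)) I else acc + I
    pow <- if (is.null(pow)) out$planePowers else pow + out$planePowers
  }
  acc <- acc / length(members)
  ## back to lab frame (x, y, z)
  list(intensity = aperm(acc, c(3L, 2L, 1L)),
       planePowers = pow / length(members))
}

## linear (zero-padded) 2D convolution of image-plane source S with a
## centered kernel K, returning the S-sized "same" result; kernelFFT may be
## precomputed with convKernelFFT for reuse across z planes.
convPadSize <- function(n, k) 2^ceiling(log2(n + k))

convKernelFFT <- function(K, Px, Py) {
  kx <- nrow(K); ky <- ncol(K)
  cx <- kx %/% 2L + 1L; cy <- ky %/% 2L + 1L
  Kp <- matrix(0, Px, Py)
  ix <- ((seq_len(kx) - cx) %% Px) + 1L
  iy <- ((seq_len(ky) - cy) %% Py) + 1L
  Kp[ix, iy] <- K
  fft2(Kp + 0i)
}

convApply <- function(S, kernelFFT, Px, Py) {
  Sp <- matrix(0, Px, Py)
  Sp[seq_len(nrow(S)), seq_len(ncol(S))] <- S
  Re(ifft2(fft2(Sp + 0i) * kernelFFT))[seq_len(nrow(S)), seq_len(ncol(S))]
}

## per-tile blending weights over the camera plane
tileWeights <- function(layout, grid, blend) {
  cxs <- unique(layout@sourcePositions[, 1]) / grid@dx   # pixel coords - 1
  cys <- unique(layout@sourcePositions[, 2]) / grid@dy
  px <- seq_len(grid@nx) - 1L; py <- seq_len(grid@ny) - 1L
  axisW <- function(p, centers) {
    W <- matrix(0, length(p), length(centers))
    if (length(centers) == 1L) { W[, 1] <- 1; return(W) }
    for (i in seq_along(centers)) {
      if (blend == "nearest") {
        d <- abs(p - centers[i])
        dAll <- vapply(centers, function(c0) abs(p - c0),
                       numeric(length(p)))
        W[, i] <- (d == apply(dAll, 1, min)) * 1
      } else {
        lo <- if (i == 1L) -Inf else centers[i - 1L]
        hi <- if (i == length(centers)) Inf else centers[i + 1L]
        w <- rep(0, length(p))
        left <- p <= centers[i] & p > lo
        w[left] <- if (is.finite(lo))
          (p[left] - lo) / (centers[i] - lo) else 1
        right <- p > centers[i] & p < hi
        w[right] <- if (is.finite(hi))
          (hi - p[right]) / (hi - centers[i]) else 1
        w[p == centers[i]] <- 1
        W[, i] <- w
      }
    }
    ## ties in nearest mode: split evenly; normalize rows to 1
    W / pmax(rowSums(W), 1e-300)
  }
  list(Wx = axisW(px, cxs), Wy = axisW(py, cys),
       nCx = length(cxs), nCy = length(cys))
}

#' Render a camera image by spatially varying convolution
#'
#' The emitted density (excitation x fluorophore) is convolved with the
#' tiled PSF set: each emitter contributes through the PSF of its nearest
#' tile (\code{blend = "nearest"}) or through the bilinear blend of the 4
#' surrounding tiles. Tile PSFs enter scaled by their raw in-focus
#' integrals, so detection-path attenuation is preserved.
#'
#' @param excitation 3D excitation intensity (lab frame), e.g. from
#'   [excitationVolume()].
#' @param fluor a [FluorophoreVolume-class] on the same grid.
#' @param psfSet a [PSFSet-class] for the requested focal plane.
#' @param blend "bilinear" (default) or "nearest".
#' @return a [CameraImage-class].
#' @export
renderCameraImage <- function(excitation, fluor, psfSet,
                              blend = c("bilinear", "nearest")) {
  blend <- match.arg(blend)
  g <- fluor@grid
  if (!all(dim(excitation) == c(g@nx, g@ny, g@nz)))
    stop("excitation and fluorophore volumes must share the grid")
  emitted <- excitation * fluor@density
  lay <- psfSet@layout
  izF <- as.integer(round(psfSet@planeZ / g@dz)) + 1L
  offIdx <- as.integer(round(psfSet@zOffsets / g@dz))
  zIdx <- izF + offIdx
  keep <- zIdx >= 1L & zIdx <= g@nz
  ## truncation check: emitted energy outside the PSF axial support
  totalE <- sum(emitted)
  coveredE <- sum(emitted[, , zIdx[keep]])
  if (totalE > 0 && (totalE - coveredE) / totalE > 1e-9)
    warning(sprintf(
      "PSF axial support misses %.3g%% of the emitted energy (truncated)",
      100 * (totalE - coveredE) / totalE))

  tw <- tileWeights(lay, g, blend)
  Px <- convPadSize(g@nx, lay@tileSize)
  Py <- convPadSize(g@ny, lay@tileSize)
  img <- matrix(0, g@nx, g@ny)
  for (t in seq_along(psfSet@psfs)) {
    tx <- (t - 1L) %% lay@tileNx + 1L
    ty <- (t - 1L) %/% lay@tileNx + 1L
    W <- outer(tw$Wx[, tx], tw$Wy[, ty])
    if (max(W) == 0) next
    scale <- psfSet@rawIntegrals[t]
    for (k in which(keep)) {
      S <- emitted[, , zIdx[k]] * W
      if (max(S) == 0) next
      KF <- convKernelFFT(psfSet@psfs[[t]][, , k], Px, Py)
      img <- img + scale * convApply(S, KF, Px, Py)
    }
  }
  img[img < 0] <- 0
  new("CameraImage", values = img, dx = g@dx, dy = g@dy,
      planeZ = psfSet@planeZ,
      provenance = list(blend = blend,
                        tiles = c(lay@tileNx, lay@tileNy),
                        zOffsets = psfSet@zOffsets))
}

#' Simulate a light-sheet image stack
#'
#' Full image-formation pipeline, one focal plane at a time: propagate the
#' illumination (sheet centered on the plane), compute the plane's
#' spatially varying detection PSF set, and render the camera image.
#' Illumination and focal plane move together (standard SPIM scan).
#'
#' @param phantom a [Phantom-class].
#' @param illum a [SourceSpec-class] (lab-frame focus) or list for
#'   incoherent illumination.
#' @param detectPupil detection [PupilSpec-class].
#' @param tiles integer c(tileNx, tileNy).
#' @param tileSize pixels per tile.
#' @param zPositions focal-plane positions (micrometers); must be
#'   uniformly spaced.
#' @param blend "bilinear" or "nearest".
#' @param config a [PropagatorConfig-class].
#' @param noise "none" (ideal camera), "poisson" (emitted intensity scaled
#'   by \code{photons} and Poisson-sampled), or "gaussian" (additive,
#'   sd = \code{noiseSd} x image max).
#' @param photons,noiseSd noise-model parameters.
#' @param psfZOffsets axial support of the per-plane PSFs (micrometers,
#'   relative to the focal plane; default \code{(-4:4) * dz}). Emitters
#'   outside the support are truncated with a warning.
#' @param sourceFill source-pupil fill for the PSF engine, see
#'   [multiplexedSourceField()].
#' @param seed seed for the noise substream.
#' @param verbose log per-plane progress.
#' @return an [ImageStack-class].
#' @export
simulateStack <- function(phantom, illum, detectPupil, tiles = c(4L, 4L),
                          tileSize = NULL, zPositions,
                          blend = c("bilinear", "nearest"),
                          config = PropagatorConfig(),
                          noise = c("none", "poisson", "gaussian"),
                          photons = 1e4, noiseSd = 0.01,
                          psfZOffsets = NULL,
                          sourceFill = c("gaussian", "uniform"),
                          seed = 1L, verbose = FALSE) {
  sourceFill <- match.arg(sourceFill)
  blend <- match.arg(blend); noise <- match.arg(noise)
  g <- simGrid(phantom)
  if (is.null(tileSize))
    tileSize <- min(g@nx %/% tiles[1], g@ny %/% tiles[2])
  images <- vector("list", length(zPositions))
  set.seed(substreamSeed(seed, "camera-noise"))
  for (i in seq_along(zPositions)) {
    z <- zPositions[i]
    t0 <- Sys.time()
    exc <- excitationVolume(phantom@refractive, illum, sheetZ = z,
                            config = config)
    lay <- tileLayout(tiles[1], tiles[2], tileSize, g, planeZ = z)
    ps <- computePSFSet(phantom@refractive, z, lay, detectPupil,
                        zOffsets = psfZOffsets, config = config,
                        sourceFill = sourceFill)
    im <- renderCameraImage(exc$intensity, phantom@fluor, ps, blend = blend)
    if (noise == "poisson") {
      sc <- photons / max(max(im@values), 1e-300)
      im@values <- matrix(stats::rpois(length(im@values),
                                       im@values * sc) / sc,
                          nrow(im@values))
    } else if (noise == "gaussian") {
      im@values <- im@values +
        matrix(rnorm(length(im@values), 0, noiseSd * max(im@values)),
               nrow(im@values))
      im@values[im@values < 0] <- 0
    }
    images[[i]] <- im
    if (verbose)
      message(sprintf("plane %d/%d (z = %.3g um) in %.2f s", i,
                      length(zPositions), z,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  zStep <- if (length(zPositions) > 1L) diff(zPositions)[1] else 0
  new("ImageStack", images = images, zStep = zStep)
}
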