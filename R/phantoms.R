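## Synthetic sample generators. Every phantom is bit-reproducible under
## (spec, seed), keeps its ground truth, and stays inside the physically
## plausible index range for aqueous biological tissue.

fadeCurve <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

## 3D gradient (Perlin) noise on an (nx, ny, nz) voxel grid. `cell` is the
## lattice cell size in voxels; octaves halve the cell and the amplitude.
perlinNoise3 <- function(nx, ny, nz, cell, octaves = 1L, seed = 1L) {
  set.seed(substreamSeed(seed, "perlin"))
  acc <- array(0, dim = c(nx, ny, nz))
  amp <- 1
  for (o in seq_len(octaves)) {
    cs <- max(cell / 2^(o - 1L), 2)
    Lx <- floor((nx - 1) / cs) + 2L; Ly <- floor((ny - 1) / cs) + 2L
    Lz <- floor((nz - 1) / cs) + 2L
    gv <- matrix(rnorm(Lx * Ly * Lz * 3), ncol = 3)
    gv <- gv / sqrt(rowSums(gv^2))
    G <- list(array(gv[, 1], c(Lx, Ly, Lz)), array(gv[, 2], c(Lx, Ly, Lz)),
              array(gv[, 3], c(Lx, Ly, Lz)))
    px <- (seq_len(nx) - 1) / cs; py <- (seq_len(ny) - 1) / cs
    pz <- (seq_len(nz) - 1) / cs
    ix0 <- floor(px); fx <- px - ix0
    iy0 <- floor(py); fy <- py - iy0
    iz0 <- floor(pz); fz <- pz - iz0
    wx <- fadeCurve(fx); wy <- fadeCurve(fy); wz <- fadeCurve(fz)
    oct <- array(0, dim = c(nx, ny, nz))
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      lin <- outer(outer(ix0 + a + 1, (iy0 + b) * Lx, "+"),
                   (iz0 + cc) * Lx * Ly, "+")
      dxA <- array(fx - a, c(nx, ny, nz))
      dyA <- array(rep(fy - b, each = nx), c(nx, ny, nz))
      dzA <- array(rep(fz - cc, each = nx * ny), c(nx, ny, nz))
      dot <- G[[1]][lin] * dxA + G[[2]][lin] * dyA + G[[3]][lin] * dzA
      wxa <- array(if (a) wx else 1 - wx, c(nx, ny, nz))
      wyb <- array(rep(if (b) wy else 1 - wy, each = nx), c(nx, ny, nz))
      wzc <- array(rep(if (cc) wz else 1 - wz, each = nx * ny),
                   c(nx, ny, nz))
      oct <- oct + wxa * wyb * wzc * dot
    }
    acc <- acc + amp * oct
    amp <- amp / 2
  }
  acc
}

## Gaussian spectral smoothing of a 3D array (periodic), sigma in voxels.
gaussSmooth3 <- function(a, sigmaVox) {
  d <- dim(a)
  kf <- function(n) 2 * pi * c(0:(ceiling(n / 2) - 1L),
                               -(floor(n / 2)):-1L) / n
  K <- exp(-0.5 * sigmaVox^2 *
             (outer(outer(kf(d[1])^2, kf(d[2])^2, "+"), kf(d[3])^2, "+")))
  Re(fft(fft(a) * K, inverse = TRUE)) / length(a)
}

## Anti-aliased sphere occupancy: fraction of each voxel inside the sphere,
## 3^3 subvoxel supersampling within the bounding box.
sphereOccupancy <- function(grid, center, radius, supersample = TRUE) {
  occ <- array(0, dim = c(grid@nx, grid@ny, grid@nz))
  xs <- axisCoords(grid@nx, grid@dx); ys <- axisCoords(grid@ny, grid@dy)
  zs <- axisCoords(grid@nz, grid@dz)
  bx <- which(abs(xs - center[1]) <= radius + grid@dx)
  by <- which(abs(ys - center[2]) <= radius + grid@dy)
  bz <- which(abs(zs - center[3]) <= radius + grid@dz)
  if (!length(bx) || !length(by) || !length(bz)) return(occ)
  offs <- c(-1, 0, 1) / 3
  sub <- array(0, dim = c(length(bx), length(by), length(bz)))
  if (supersample) {
    for (ox in offs) for (oy in offs) for (oz in offs) {
      d2 <- outer(outer((xs[bx] + ox * grid@dx - center[1])^2,
                        (ys[by] + oy * grid@dy - center[2])^2, "+"),
                  (zs[bz] + oz * grid@dz - center[3])^2, "+")
      sub <- sub + (d2 <= radius^2)
    }
    sub <- sub / 27
  } else {
    d2 <- outer(outer((xs[bx] - center[1])^2, (ys[by] - center[2])^2, "+"),
                (zs[bz] - center[3])^2, "+")
    sub <- (d2 <= radius^2) * 1
  }
  occ[bx, by, bz] <- sub
  occ
}

#' Sphere / coated-sphere phantom
#'
#' Voxelizes solid or coated spheres with optional anti-aliased boundaries
#' (3^3 supersampling). Coated spheres take a shell of index
#' \code{nShell} between \code{coreRadius} and \code{radius}. The
#' fluorophore volume labels sphere interiors.
#'
#' @param grid a [Grid3D-class].
#' @param centers matrix (nSpheres x 3) of centers in micrometers.
#' @param radii outer radii (micrometers).
#' @param deltaN index contrast of the (core) sphere over ambient.
#' @param nAmbient ambient index.
#' @param coreRadii,deltaNShell optional per-sphere core radii and shell
#'   contrast for coated spheres.
#' @param kappa homogeneous absorption Im(n) inside spheres (default 0).
#' @param antialias 3^3 supersampled boundaries (default TRUE).
#' @return a [Phantom-class]; \code{truth} lists centers, radii and
#'   indices. Overlapping spheres are allowed but flagged in truth.
#' @examples
#' g <- Grid3D(64, 64, 64, dx = 0.1)
#' ph <- makeSpheres(g, centers = matrix(c(3.2, 3.2, 3.2), 1),
#'                   radii = 2.5, deltaN = 0.05)
#' @export
makeSpheres <- function(grid, centers, radii, deltaN, nAmbient = 1.33,
                        coreRadii = NULL, deltaNShell = NULL, kappa = 0,
                        antialias = TRUE) {
  centers <- matrix(centers, ncol = 3)
  nS <- nrow(centers)
  radii <- rep_len(radii, nS)
  deltaN <- rep_len(deltaN, nS)
  stopifnot(all(radii > 0))
  n <- array(nAmbient + 0i, dim = c(grid@nx, grid@ny, grid@nz))
  fl <- array(0, dim = c(grid@nx, grid@ny, grid@nz))
  occTotal <- array(0, dim = dim(fl))
  for (s in seq_len(nS)) {
    occ <- sphereOccupancy(grid, centers[s, ], radii[s], antialias)
    if (!is.null(coreRadii) && !is.null(deltaNShell)) {
      core <- sphereOccupancy(grid, centers[s, ], coreRadii[s], antialias)
      shell <- pmax(occ - core, 0)
      n <- n + core * deltaN[s] + shell * rep_len(deltaNShell, nS)[s]
    } else {
      n <- n + occ * deltaN[s]
    }
    if (kappa > 0) n <- n + 1i * kappa * occ
    fl <- fl + occ
    occTotal <- occTotal + occ
  }
  overlap <- max(occTotal) > 1 + 1e-9
  Phantom <- new("Phantom",
    refractive = RefractiveVolume(grid, n, nAmbient),
    fluor = FluorophoreVolume(grid, pmin(fl, 1)),
    truth = list(kind = "spheres", centers = centers, radii = radii,
                 deltaN = deltaN, coreRadii = coreRadii,
                 deltaNShell = deltaNShell, nAmbient = nAmbient,
                 overlapFlag = overlap))
  if (overlap) warning("spheres overlap; flagged in truth$overlapFlag")
  Phantom
}

#' Parametric multicellular embryo phantom
#'
#' An ellipsoidal eggshell, Poisson-disk placed non-overlapping nuclei, and
#' band-limited cytoplasmic granularity, with all indices clamped to the
#' biologically plausible range [nAmbient, nMax]. The fluorophore channel
#' labels nuclei (or membranes, or carries a test pattern).
#'
#' @param grid a [Grid3D-class].
#' @param seed integer seed (bit-reproducible phantom).
#' @param nNuclei requested nucleus count.
#' @param nucleusRadius nucleus radius in micrometers.
#' @param minGap minimum gap between nucleus surfaces (micrometers).
#' @param nAmbient,nCytoplasm,nNucleus,nShell,nMax index parameters.
#' @param granularity amplitude of the cytoplasmic index fluctuations.
#' @param granularityCell correlation cell of the fluctuations (micrometers).
#' @param shellThickness eggshell thickness (micrometers).
#' @param kappa homogeneous absorption inside the embryo.
#' @param label "nuclei", "membranes" or "none" for the fluorophore channel.
#' @return a [Phantom-class] with nucleus centers in truth.
#' @export
makeEmbryo <- function(grid, seed = 1L, nNuclei = 50L,
                       nucleusRadius = NULL, minGap = NULL,
                       nAmbient = 1.33, nCytoplasm = 1.36, nNucleus = 1.39,
                       nShell = 1.41, nMax = 1.43, granularity = 0.02,
                       granularityCell = 1.5, shellThickness = NULL,
                       kappa = 0, label = c("nuclei", "membranes", "none")) {
  label <- match.arg(label)
  ext <- c(grid@nx * grid@dx, grid@ny * grid@dy, grid@nz * grid@dz)
  semi <- 0.42 * ext
  cen <- ext / 2
  if (is.null(shellThickness)) shellThickness <- 2 * max(grid@dx, grid@dz)
  if (is.null(nucleusRadius))
    nucleusRadius <- 0.09 * min(ext)
  if (is.null(minGap)) minGap <- nucleusRadius / 2

  xs <- axisCoords(grid@nx, grid@dx); ys <- axisCoords(grid@ny, grid@dy)
  zs <- axisCoords(grid@nz, grid@dz)
  ## normalized ellipsoid radius per voxel
  rr <- sqrt(outer(outer(((xs - cen[1]) / semi[1])^2,
                         ((ys - cen[2]) / semi[2])^2, "+"),
                   ((zs - cen[3]) / semi[3])^2, "+"))
  inside <- rr <= 1
  shellFrac <- shellThickness / mean(semi)
  shell <- rr <= 1 & rr >= 1 - shellFrac

  ## Poisson-disk (dart throwing) nucleus placement inside the ellipsoid
  set.seed(substreamSeed(seed, "embryo-nuclei"))
  centers <- matrix(0, 0, 3)
  tries <- 0L
  maxR <- 1 - (nucleusRadius + shellThickness) / min(semi)
  while (nrow(centers) < nNuclei && tries < 20000L) {
    tries <- tries + 1L
    p <- cen + (2 * runif(3) - 1) * semi * maxR
    if (sum(((p - cen) / semi)^2) > maxR^2) next
    if (nrow(centers)) {
      d <- sqrt(rowSums(sweep(centers, 2, p)^2))
      if (min(d) < 2 * nucleusRadius + minGap) next
    }
    centers <- rbind(centers, p)
  }
  if (nrow(centers) < nNuclei)
    warning(sprintf("placed %d of %d requested nuclei", nrow(centers),
                    nNuclei))

  n <- array(nAmbient, dim = c(grid@nx, grid@ny, grid@nz))
  n[inside] <- nCytoplasm
  gran <- perlinNoise3(grid@nx, grid@ny, grid@nz,
                       cell = granularityCell / grid@dx, octaves = 2L,
                       seed = substreamSeed(seed, "embryo-granularity"))
  gran <- gran / max(sd(gran), 1e-12) * granularity
  n[inside] <- n[inside] + gran[inside]
  nucMask <- array(FALSE, dim = dim(n))
  for (s in seq_len(nrow(centers))) {
    occ <- sphereOccupancy(grid, centers[s, ], nucleusRadius,
                           supersample = FALSE)
    nucMask <- nucMask | (occ > 0.5)
  }
  n[nucMask] <- nNucleus
  n[shell] <- nShell
  n <- pmin(pmax(n, nAmbient), nMax)

  fl <- array(0, dim = dim(n))
  if (label == "nuclei") fl[nucMask] <- 1
  if (label == "membranes") {
    ## thin rind around each nucleus
    for (s in seq_len(nrow(centers))) {
      occO <- sphereOccupancy(grid, centers[s, ], nucleusRadius + grid@dx,
                              supersample = FALSE)
      occI <- sphereOccupancy(grid, centers[s, ], nucleusRadius - grid@dx,
                              supersample = FALSE)
      fl[occO > 0.5 & occI < 0.5] <- 1
    }
  }
  nC <- n + if (kappa > 0) 1i * kappa * inside else 0i
  new("Phantom",
      refractive = RefractiveVolume(grid, nC, nAmbient),
      fluor = FluorophoreVolume(grid, fl),
      truth = list(kind = "embryo", seed = seed, centers = centers,
                   nucleusRadius = nucleusRadius, semiAxes = semi,
                   center = cen, indexRange = range(Re(nC)), label = label))
}

#' Perlin-noise tissue phantom
#'
#' Smooth pseudorandom refractive-index field n = meanN +/- amplitude
#' (exact sample mean and standard deviation by construction), with the
#' autocorrelation FWHM controlled by the noise cell size.
#'
#' @param grid a [Grid3D-class].
#' @param meanN mean index (paper regime: 1.36).
#' @param amplitude index standard deviation (paper regime: 0.03).
#' @param correlationLength target autocorrelation FWHM (micrometers).
#' @param seed integer seed.
#' @param octaves gradient-noise octaves (default 1; more octaves add
#'   fine-scale texture but shorten the correlation length).
#' @param nAmbient ambient index stored with the volume.
#' @param antialias band-limit the noise with a Gaussian spectral filter of
#'   \code{aaSigmaVox} voxels (default TRUE). Gradient noise is only C^2,
#'   and its polynomial spectral tails otherwise bleed past the propagating
#'   band, where the propagator must discard them as pseudo-evanescent
#'   power; filtering keeps lossless media numerically lossless. The
#'   requested correlation length is deconvolved for the filter width.
#' @param aaSigmaVox filter sigma in voxels.
#' @return a [Phantom-class] (uniform fluorophore density 1).
#' @export
makePerlinTissue <- function(grid, meanN = 1.36, amplitude = 0.03,
                             correlationLength = 2, seed = 1L,
                             octaves = 1L, nAmbient = 1.33,
                             antialias = TRUE, aaSigmaVox = 1) {
  ## calibration: for single-octave gradient noise the autocorrelation
  ## FWHM measures 0.83 of the lattice cell size (+/-5%, measured over
  ## cells of 8-24 voxels); the anti-alias kernel widens it in quadrature
  clTarget <- correlationLength
  if (antialias && amplitude > 0) {
    kernFwhm <- 2.355 * aaSigmaVox * grid@dx
    if (clTarget^2 <= kernFwhm^2 * 1.1) {
      warning("correlationLength too small for the anti-alias filter; disabling it")
      antialias <- FALSE
    } else clTarget <- sqrt(clTarget^2 - kernFwhm^2)
  }
  cellUm <- clTarget / 0.83
  n <- array(meanN, dim = c(grid@nx, grid@ny, grid@nz))
  if (amplitude > 0) {
    noise <- perlinNoise3(grid@nx, grid@ny, grid@nz,
                          cell = cellUm / grid@dx, octaves = octaves,
                          seed = seed)
    if (antialias) noise <- gaussSmooth3(noise, aaSigmaVox)
    noise <- (noise - mean(noise)) / max(sd(noise), 1e-300)
    n <- meanN + amplitude * noise
  }
  new("Phantom",
      refractive = RefractiveVolume(grid, n + 0i, nAmbient),
      fluor = FluorophoreVolume(grid,
                                array(1, dim = c(grid@nx, grid@ny, grid@nz))),
      truth = list(kind = "perlin", seed = seed, meanN = meanN,
                   amplitude = amplitude,
                   correlationLength = correlationLength))
}

#' Planar resolution test chart
#'
#' A USAF-style pattern of three-bar groups (horizontal and vertical) at
#' several periods, embedded as a one-voxel-thick fluorophore plane.
#'
#' @param grid a [Grid3D-class].
#' @param barPeriods bar periods in micrometers (one group per period).
#' @param planeZ axial position of the chart plane (default mid-section).
#' @return a [FluorophoreVolume-class]; bar geometry in
#'   \code{attr(, "truth")}.
#' @export
makeTestChart <- function(grid, barPeriods = c(1, 2, 4), planeZ = NULL) {
  if (is.null(planeZ)) planeZ <- centerCoord(grid@nz, grid@dz)
  iz <- as.integer(round(planeZ / grid@dz)) + 1L
  stopifnot(iz >= 1L, iz <= grid@nz)
  plane <- matrix(0, grid@nx, grid@ny)
  truth <- list()
  x0 <- max(2L, grid@nx %/% 16L)
  y0 <- max(2L, grid@ny %/% 16L)
  for (gIdx in seq_along(barPeriods)) {
    per <- max(2L, as.integer(round(barPeriods[gIdx] / grid@dx)))
    w <- max(1L, per %/% 2L)          # bar width = half period
    len <- 5L * w
    ## three vertical bars
    for (b in 0:2) {
      xs <- x0 + b * per + seq_len(w) - 1L
      ys <- y0 + seq_len(len) - 1L
      xs <- xs[xs <= grid@nx]; ys <- ys[ys <= grid@ny]
      plane[xs, ys] <- 1
    }
    ## three horizontal bars to the right
    hx <- x0 + 3L * per + seq_len(len) - 1L
    for (b in 0:2) {
      ys <- y0 + b * per + seq_len(w) - 1L
      xs <- hx[hx <= grid@nx]; ys <- ys[ys <= grid@ny]
      plane[xs, ys] <- 1
    }
    truth[[gIdx]] <- list(period = per * grid@dx, widthPx = w,
                          origin = c(x0, y0))
    y0 <- y0 + len + 2L * per
  }
  den <- array(0, dim = c(grid@nx, grid@ny, grid@nz))
  den[, , iz] <- plane
  fv <- FluorophoreVolume(grid, den)
  attr(fv, "truth") <- list(kind = "test_chart", planeZ = (iz - 1L) * grid@dz,
                            groups = truth)
  fv
}
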