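## Shared fixtures: everything is generated in code at test time.

relL2 <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))

## propagate/freeSpaceStep emit sampling-guard warnings on purpose in some
## deliberately coarse fixtures; tests that are not about the guard wrap them
quietly <- function(expr) suppressWarnings(expr)

## Gaussian beam sampled at its waist, centered on the grid
gaussianWaistField <- function(nx, dx, w0, wavelength) {
  x <- (seq_len(nx) - 1) * dx - floor(nx / 2) * dx
  r2 <- outer(x^2, rep(1, nx)) + outer(rep(1, nx), x^2)
  ComplexField(exp(-r2 / w0^2) + 0i, dx, dx, wavelength)
}

## soft-edged circular aperture (band-limited enough for oracle comparisons)
softApertureField <- function(nx, dx, radius, wavelength) {
  x <- (seq_len(nx) - 1) * dx - floor(nx / 2) * dx
  r <- sqrt(outer(x^2, rep(1, nx)) + outer(rep(1, nx), x^2))
  ComplexField(exp(-(r / radius)^8) + 0i, dx, dx, wavelength)
}

## single-sphere phantom centred in the grid
centeredSphere <- function(nx, nz, dx, radius, deltaN, nAmbient = 1.33) {
  g <- Grid3D(nx, nx, nz, dx = dx)
  c0 <- floor(nx / 2) * dx
  cz <- floor(nz / 2) * dx
  makeSpheres(g, centers = matrix(c(c0, c0, cz), 1), radii = radius,
              deltaN = deltaN, nAmbient = nAmbient)
}

detectionPupil <- function(na = 0.6, wavelength = 0.5, nImmersion = 1.33)
  PupilSpec(na = na, wavelength = wavelength, nImmersion = nImmersion)

## tiny JSON config for CLI tests
writeTestConfig <- function(path, nx = 32L, nz = 32L, dx = 0.2) {
  cfg <- list(
    grid = list(nx = nx, ny = nx, nz = nz, dx = dx),
    phantom = list(kind = "perlin", meanN = 1.36, amplitude = 0.01,
                   correlationLength = 1.5),
    illumination = list(kind = "cylindrical_sheet", na = 0.1,
                        wavelength = 0.5),
    detection = list(na = 0.6, wavelength = 0.5),
    tiles = list(nx = 2L, ny = 2L, tileSize = 16L),
    scan = list(from = nz * dx / 2, to = nz * dx / 2, n = 1L))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
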