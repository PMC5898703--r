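## Simulation configuration: a single JSON file describing grid, phantom,
## optics, tiling and scan. Unknown keys are rejected so typos fail loudly,
## and every run writes the resolved configuration beside its outputs.

.configSchema <- list(
  grid = c("nx", "ny", "nz", "dx", "dy", "dz"),
  phantom = c("kind", "seed", "centers", "radii", "deltaN", "nAmbient",
              "coreRadii", "deltaNShell", "meanN", "amplitude",
              "correlationLength", "octaves", "nNuclei", "nucleusRadius",
              "label", "barPeriods", "path"),
  illumination = c("kind", "na", "wavelength", "focus", "count",
                   "naSpread"),
  detection = c("na", "wavelength"),
  tiles = c("nx", "ny", "tileSize"),
  scan = c("from", "to", "n"),
  top = c("grid", "phantom", "illumination", "detection", "tiles", "scan",
          "seed", "output", "blend", "noise", "photons", "noiseSd"))

#' Read and validate a simulation configuration (JSON)
#'
#' @param path JSON config file.
#' @return validated config list with defaults filled in.
#' @export
readSimulationConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), .configSchema$top)
  if (length(bad))
    stop(sprintf("config error: unknown key(s): %s",
                 paste(bad, collapse = ", ")))
  for (sec in intersect(names(cfg),
                        setdiff(names(.configSchema), "top"))) {
    badSec <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(badSec))
      stop(sprintf("config error: unknown key(s) in '%s': %s", sec,
                   paste(badSec, collapse = ", ")))
  }
  for (req in c("grid", "phantom", "detection"))
    if (is.null(cfg[[req]]))
      stop(sprintf("config error: missing required section '%s'", req))
  for (k in c("nx", "ny", "nz", "dx"))
    if (is.null(cfg$grid[[k]]))
      stop(sprintf("config error: missing key 'grid.%s'", k))
  cfg$grid$dy <- cfg$grid$dy %||% cfg$grid$dx
  cfg$grid$dz <- cfg$grid$dz %||% cfg$grid$dx
  cfg$seed <- cfg$seed %||% 1L
  cfg$blend <- cfg$blend %||% "bilinear"
  cfg$noise <- cfg$noise %||% "none"
  cfg
}

configGrid <- function(cfg)
  Grid3D(cfg$grid$nx, cfg$grid$ny, cfg$grid$nz, dx = cfg$grid$dx,
         dy = cfg$grid$dy, dz = cfg$grid$dz)

#' Build the phantom described by a configuration
#' @param cfg validated config list.
#' @param seed seed override (default the config's).
#' @return a [Phantom-class].
#' @export
configPhantom <- function(cfg, seed = NULL) {
  g <- configGrid(cfg)
  p <- cfg$phantom
  seed <- seed %||% cfg$seed
  switch(p$kind,
    spheres = makeSpheres(g, centers = matrix(unlist(p$centers), ncol = 3),
                          radii = p$radii, deltaN = p$deltaN,
                          nAmbient = p$nAmbient %||% 1.33,
                          coreRadii = p$coreRadii,
                          deltaNShell = p$deltaNShell),
    perlin = makePerlinTissue(g, meanN = p$meanN %||% 1.36,
                              amplitude = p$amplitude %||% 0.03,
                              correlationLength = p$correlationLength %||% 2,
                              seed = p$seed %||% seed,
                              octaves = p$octaves %||% 1L,
                              nAmbient = p$nAmbient %||% 1.33),
    embryo = makeEmbryo(g, seed = p$seed %||% seed,
                        nNuclei = p$nNuclei %||% 50L,
                        nucleusRadius = p$nucleusRadius,
                        label = p$label %||% "nuclei"),
    stop(sprintf("config error: unknown phantom kind '%s'", p$kind)))
}

#' Illumination source from a configuration
#' @param cfg validated config list.
#' @return a [SourceSpec-class] or list of fields for incoherent sets.
#' @export
configIllumination <- function(cfg) {
  il <- cfg$illumination
  if (is.null(il)) il <- list(kind = "cylindrical_sheet", na = 0.1,
                              wavelength = 0.5)
  g <- configGrid(cfg)
  ext <- c(g@nx * g@dx, g@ny * g@dy, g@nz * g@dz)
  pup <- PupilSpec(na = il$na %||% 0.1,
                   wavelength = il$wavelength %||% 0.5,
                   nImmersion = cfg$phantom$nAmbient %||% 1.33)
  SourceSpec(il$kind %||% "cylindrical_sheet", pup,
             focus = if (!is.null(il$focus)) unlist(il$focus)
                     else ext / 2)
}
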