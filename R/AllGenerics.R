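#' Field or image sample values
#' @param x object with a values slot.
#' @return complex matrix (fields) or numeric matrix (images).
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "ComplexField", function(x) x@values)

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "CameraImage", function(x) x@values)

#' Total optical power of a field
#'
#' Power is the discrete integral sum(|u|^2) * dx * dy.
#' @param x a [ComplexField-class].
#' @return scalar power.
#' @export
setGeneric("fieldPower", function(x) standardGeneric("fieldPower"))

#' @rdname fieldPower
#' @export
setMethod("fieldPower", "ComplexField", function(x)
  sum(Mod(x@values)^2) * x@dx * x@dy)

#' Grid of an object
#' @param x object carrying a [Grid3D-class].
#' @export
setGeneric("simGrid", function(x) standardGeneric("simGrid"))

#' @rdname simGrid
#' @export
setMethod("simGrid", "RefractiveVolume", function(x) x@grid)

#' @rdname simGrid
#' @export
setMethod("simGrid", "FluorophoreVolume", function(x) x@grid)

#' @rdname simGrid
#' @export
setMethod("simGrid", "Phantom", function(x) x@refractive@grid)

#' Refractive-index array
#' @param x a [RefractiveVolume-class].
#' @export
setGeneric("indexArray", function(x) standardGeneric("indexArray"))

#' @rdname indexArray
#' @export
setMethod("indexArray", "RefractiveVolume", function(x) x@n)

#' Fluorophore density array
#' @param x a [FluorophoreVolume-class] or [Phantom-class].
#' @export
setGeneric("densityArray", function(x) standardGeneric("densityArray"))

#' @rdname densityArray
#' @export
setMethod("densityArray", "FluorophoreVolume", function(x) x@density)

#' @rdname densityArray
#' @export
setMethod("densityArray", "Phantom", function(x) x@fluor@density)

setMethod("show", "Grid3D", function(object) {
  cat(sprintf("Grid3D: %d x %d x %d voxels, pitch (%.4g, %.4g, %.4g) um\n",
              object@nx, object@ny, object@nz,
              object@dx, object@dy, object@dz))
})

setMethod("show", "RefractiveVolume", function(object) {
  re <- range(Re(object@n)); im <- max(Im(object@n))
  cat(sprintf(
    "RefractiveVolume: %d x %d x %d, n in [%.4f, %.4f], max Im(n) %.3g, ambient %.3f\n",
    object@grid@nx, object@grid@ny, object@grid@nz, re[1], re[2], im,
    object@nAmbient))
})

setMethod("show", "ComplexField", function(object) {
  cat(sprintf(
    "ComplexField: %d x %d, pitch (%.4g, %.4g) um, lambda %.4g um, z = %.4g um, power %.4g\n",
    nrow(object@values), ncol(object@values), object@dx, object@dy,
    object@wavelength, object@z, fieldPower(object)))
})

setMethod("show", "PSFSet", function(object) {
  cat(sprintf(
    "PSFSet: %d x %d tiles of %d px at z = %.4g um, %d axial planes, transmission %.3g-%.3g\n",
    object@layout@tileNx, object@layout@tileNy, object@layout@tileSize,
    object@planeZ, length(object@zOffsets),
    min(object@rawIntegrals), max(object@rawIntegrals)))
  if (any(object@flags))
    cat(sprintf("  %d tile(s) flagged for cross-talk above tolerance\n",
                sum(object@flags)))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom '%s':\n", object@truth$kind %||% "custom"))
  show(object@refractive)
})

setMethod("show", "CameraImage", function(object) {
  cat(sprintf("CameraImage: %d x %d px at z = %.4g um, max intensity %.4g\n",
              nrow(object@values), ncol(object@values), object@planeZ,
              max(object@values)))
})

setMethod("show", "ImageStack", function(object) {
  cat(sprintf("ImageStack: %d planes, z step %.4g um\n",
              length(object@images), object@zStep))
})

setMethod("show", "FocusReport", function(object) {
  cat(sprintf(
    "FocusReport: Strehl %.3f, peak %.4g, FWHM lateral %.3g um / axial %.3g um, position error %.3g um\n",
    object@strehl, object@peak, object@fwhmLateral, object@fwhmAxial,
    object@positionError))
})

setMethod("show", "MemoryEffectCurve", function(object) {
  cat(sprintf(
    "MemoryEffectCurve: %d shifts up to %.3g um at depth %.3g um (%.2g mfp)\n",
    length(object@shifts), max(abs(object@shifts)), object@depth,
    object@depthMfp))
})

setMethod("show", "ZernikeMap", function(object) {
  nt <- length(unique(paste(object@coefficients$tileX,
                            object@coefficients$tileY)))
  cat(sprintf("ZernikeMap: %d tiles, Noll j = 1..%d, NA %.3g, lambda %.4g um\n",
              nt, object@jMax, object@na, object@wavelength))
})
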