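## Minimal multi-page 32-bit float TIFF codec (little-endian, uncompressed,
## one strip per page, ImageJ-compatible description tag). No TIFF package
## is available in the target environment, so the few baseline features
## needed for microscopy interchange are implemented here directly.
## Page layout: width = nx (fast axis), length = ny, one page per z slice.

.tiffTypes <- c(SHORT = 3L, LONG = 4L, RATIONAL = 5L, ASCII = 2L)

writeTiffPages <- function(path, pages, dx, dy, dz, description = NULL) {
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]]); np <- length(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- description %||% sprintf(
    "ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%.9g\n",
    np, np, dz)
  descBytes <- nchar(desc, type = "bytes") + 1L   # + terminating NUL
  pageBytes <- nx * ny * 4L
  dataStart <- 8L
  descOff <- dataStart + np * pageBytes
  ratOff <- descOff + descBytes
  ratOff <- ratOff + ratOff %% 2L           # word-align
  ifdStart <- ratOff + 16L
  nTags <- 13L
  ifdSize <- 2L + nTags * 12L + 4L

  ## header
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifdStart), con, size = 4, endian = "little")
  ## pixel data (column-major array order == TIFF row order for [x, y])
  for (p in pages)
    writeBin(as.vector(p), con, size = 4, endian = "little")
  ## description (NUL-terminated) + rationals
  writeBin(c(charToRaw(desc), raw(1)), con)
  if ((descOff + descBytes) %% 2L) writeBin(raw(1), con)
  ## X/Y resolution: pixels per micron as a rational (1e6 / (dx*1e6))
  writeBin(as.integer(c(round(1e6), round(dx * 1e6))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(round(1e6), round(dy * 1e6))), con, size = 4,
           endian = "little")

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == .tiffTypes["SHORT"] && count == 1L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (ip in seq_len(np)) {
    ## IFD for page ip
    writeBin(as.integer(nTags), con, size = 2, endian = "little")
    entry(256, 4, 1, nx)                        # ImageWidth
    entry(257, 4, 1, ny)                        # ImageLength
    entry(258, 3, 1, 32)                        # BitsPerSample
    entry(259, 3, 1, 1)                         # Compression = none
    entry(262, 3, 1, 1)                         # Photometric = BlackIsZero
    entry(270, 2, descBytes, descOff)           # ImageDescription
    entry(273, 4, 1, dataStart + (ip - 1L) * pageBytes)  # StripOffsets
    entry(277, 3, 1, 1)                         # SamplesPerPixel
    entry(278, 4, 1, ny)                        # RowsPerStrip
    entry(279, 4, 1, pageBytes)                 # StripByteCounts
    entry(282, 5, 1, ratOff)                    # XResolution
    entry(283, 5, 1, ratOff + 8L)               # YResolution
    entry(339, 3, 1, 3)                         # SampleFormat = IEEE float
    nextIfd <- if (ip < np) ifdStart + ip * ifdSize else 0L
    writeBin(as.integer(nextIfd), con, size = 4, endian = "little")
  }
  invisible(path)
}

readTiffPages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  getInt <- function(off, size) {
    v <- 0
    for (i in seq_len(size)) v <- v + as.integer(raw[off + i]) * 256^(i - 1)
    v
  }
  if (rawToChar(raw[1:2]) != "II" || getInt(2, 2) != 42L)
    stop("not a little-endian TIFF file")
  ifdOff <- getInt(4, 4)
  pages <- list()
  desc <- NULL; xres <- NULL; yres <- NULL
  while (ifdOff != 0) {
    nTags <- getInt(ifdOff, 2)
    tags <- list()
    for (t in seq_len(nTags)) {
      e <- ifdOff + 2L + (t - 1L) * 12L
      tag <- getInt(e, 2); type <- getInt(e + 2, 2); cnt <- getInt(e + 4, 4)
      val <- if (type == 3L && cnt == 1L) getInt(e + 8, 2) else getInt(e + 8, 4)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val)
    }
    need <- function(tag, default = NULL) {
      tg <- tags[[as.character(tag)]]
      if (is.null(tg)) return(default)
      tg$value
    }
    bps <- need(258, 1L)
    fmt <- need(339, 1L)
    if (bps != 32L || fmt != 3L)
      stop(sprintf(
        "unsupported TIFF sample layout (%d-bit, format %d): convert to 32-bit float first",
        bps, fmt))
    if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
    nx <- need(256); ny <- need(257)
    off <- need(273); nb <- need(279)
    vals <- readBin(raw[(off + 1):(off + nb)], "double", n = nx * ny,
                    size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nx, ny)
    if (is.null(desc) && !is.null(tags[["270"]])) {
      d <- tags[["270"]]
      desc <- rawToChar(raw[(d$value + 1):(d$value + d$count - 1L)])
    }
    for (rtag in c(282, 283)) {
      tg <- tags[[as.character(rtag)]]
      if (!is.null(tg)) {
        num <- getInt(tg$value, 4); den <- getInt(tg$value + 4, 4)
        r <- den / num
        if (rtag == 282) xres <- r else yres <- r
      }
    }
    ifdOff <- getInt(ifdOff + 2L + nTags * 12L, 4)
  }
  spacing <- NA_real_
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) spacing <- as.numeric(m[2])
  }
  list(pages = pages, dx = xres, dy = yres, dz = spacing,
       description = desc)
}

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a volume as a multi-page 32-bit float TIFF
#'
#' One page per z slice, ImageJ-compatible (unit = micron, spacing = dz),
#' with a JSON sidecar carrying the full pitch and class metadata. Complex
#' refractive volumes with absorption are written as paired
#' \code{*_real.tif} / \code{*_imag.tif}.
#'
#' @param x a [RefractiveVolume-class], [FluorophoreVolume-class] or
#'   numeric 3D array.
#' @param path output path (.tif).
#' @param dx,dy,dz pitches, required for plain arrays.
#' @return the main file path, invisibly.
#' @export
writeVolumeTiff <- function(x, path, dx = NULL, dy = NULL, dz = NULL) {
  meta <- list()
  if (is(x, "RefractiveVolume") || is(x, "FluorophoreVolume")) {
    g <- simGrid(x)
    dx <- g@dx; dy <- g@dy; dz <- g@dz
  } else if (is.null(dx)) stop("pitches are required for plain arrays")
  dy <- dy %||% dx; dz <- dz %||% dx
  toPages <- function(a) lapply(seq_len(dim(a)[3]), function(i) a[, , i])
  if (is(x, "RefractiveVolume")) {
    meta <- list(class = "RefractiveVolume", nAmbient = x@nAmbient)
    if (max(Im(x@n)) > 0) {
      base <- tools::file_path_sans_ext(path)
      writeTiffPages(paste0(base, "_real.tif"), toPages(Re(x@n)), dx, dy, dz)
      writeTiffPages(paste0(base, "_imag.tif"), toPages(Im(x@n)), dx, dy, dz)
      meta$pair <- TRUE
      path <- paste0(base, "_real.tif")
    } else {
      writeTiffPages(path, toPages(Re(x@n)), dx, dy, dz)
    }
  } else if (is(x, "FluorophoreVolume")) {
    meta <- list(class = "FluorophoreVolume")
    writeTiffPages(path, toPages(x@density), dx, dy, dz)
  } else {
    meta <- list(class = "array")
    writeTiffPages(path, toPages(x), dx, dy, dz)
  }
  meta$pitch <- c(dx, dy, dz)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume TIFF written by [writeVolumeTiff()]
#'
#' @param path the .tif path (for paired complex volumes, the
#'   \code{*_real.tif} member).
#' @return the stored object ([RefractiveVolume-class],
#'   [FluorophoreVolume-class] or numeric array with pitch attributes).
#' @export
readVolumeTiff <- function(path) {
  tp <- readTiffPages(path)
  meta <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else NULL
  dx <- tp$dx %||% meta$pitch[1]
  dy <- tp$dy %||% meta$pitch[2]
  dz <- if (is.finite(tp$dz)) tp$dz else meta$pitch[3]
  if (is.null(dx) || is.null(dz) || !is.finite(dz))
    stop(sprintf(
      "missing pitch metadata in '%s': provide the JSON sidecar '%s' with a 'pitch' field",
      path, sidecarPath(path)))
  arr <- array(unlist(tp$pages), dim = c(dim(tp$pages[[1]]),
                                         length(tp$pages)))
  g <- Grid3D(dim(arr)[1], dim(arr)[2], dim(arr)[3], dx = dx, dy = dy,
              dz = dz)
  cls <- meta$class %||% "array"
  if (cls == "RefractiveVolume") {
    n <- arr + 0i
    if (isTRUE(meta$pair)) {
      imPath <- sub("_real\\.tif$", "_imag.tif", path)
      im <- readTiffPages(imPath)
      n <- arr + 1i * array(unlist(im$pages), dim = dim(arr))
    }
    return(RefractiveVolume(g, n, meta$nAmbient %||% 1.33))
  }
  if (cls == "FluorophoreVolume") return(FluorophoreVolume(g, arr))
  attr(arr, "pitch") <- c(dx, dy, dz)
  arr
}

#' Persist a complex field as paired real/imaginary TIFFs
#'
#' Writes \code{<base>_real.tif}, \code{<base>_imag.tif} and
#' \code{<base>.json} (dx, dy, wavelength, z).
#'
#' @param field a [ComplexField-class].
#' @param basePath path without extension.
#' @return basePath, invisibly.
#' @export
writeFieldTiff <- function(field, basePath) {
  writeTiffPages(paste0(basePath, "_real.tif"), list(Re(field@values)),
                 field@dx, field@dy, field@dx)
  writeTiffPages(paste0(basePath, "_imag.tif"), list(Im(field@values)),
                 field@dx, field@dy, field@dx)
  jsonlite::write_json(list(class = "ComplexField", dx = field@dx,
                            dy = field@dy, wavelength = field@wavelength,
                            z = field@z),
                       paste0(basePath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basePath)
}

#' Read a complex field written by [writeFieldTiff()]
#' @param basePath path without extension.
#' @return a [ComplexField-class].
#' @export
readFieldTiff <- function(basePath) {
  meta <- jsonlite::read_json(paste0(basePath, ".json"),
                              simplifyVector = TRUE)
  re <- readTiffPages(paste0(basePath, "_real.tif"))$pages[[1]]
  im <- readTiffPages(paste0(basePath, "_imag.tif"))$pages[[1]]
  ComplexField(re + 1i * im, meta$dx, meta$dy, meta$wavelength, meta$z)
}

#' Write an image stack as a multi-page TIFF
#' @param stack an [ImageStack-class].
#' @param path output .tif path.
#' @export
writeStackTiff <- function(stack, path) {
  im1 <- stack@images[[1]]
  pages <- lapply(stack@images, function(im) im@values)
  writeTiffPages(path, pages, im1@dx, im1@dy,
                 if (stack@zStep > 0) stack@zStep else im1@dx)
  jsonlite::write_json(list(class = "ImageStack", zStep = stack@zStep,
                            planeZ = vapply(stack@images,
                                            function(im) im@planeZ,
                                            numeric(1))),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
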