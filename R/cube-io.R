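#' Read a multispectral cube
#'
#' Reads either a multi-page TIFF (one grayscale page per band, page order =
#' band order) or the package's lossless `.msc` archive (per-band 2-D arrays
#' stored as raw little-endian float64 behind a JSON header). For TIFF, a
#' JSON sidecar `<path>.json` of the form `{"wavelengths_nm": [...]}` is
#' consulted when present; when the file carries no wavelength metadata and
#' none is supplied, wavelengths default to band indices `0..W-1` with a
#' warning.
#'
#' @param path file to read (`.tif`/`.tiff` or `.msc`).
#' @param wavelengths optional wavelengths in nm, overriding any sidecar.
#' @return a validated [SpectralCube-class].
#' @details Infinite values are rejected. NaN values (the encoding of
#'   pixels excluded by a mask) are accepted with a warning so that masked
#'   cubes round-trip.
#' @seealso [writeCube()]
#' @examples
#' tt <- makePhantom(phantomPreset("creme", m = 32))
#' p <- file.path(tempdir(), "c.msc")
#' writeCube(tt@cube, p)
#' cube <- readCube(p)
#' identical(cubeData(cube), cubeData(tt@cube))
#' @export
readCube <- function(path, wavelengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("band-pair selection needs at least 2 bands; got ", length(pages))
    if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1))))
      stop("all TIFF pages must be single-channel 2-D images")
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("page shape mismatch between bands")
    data <- array(unlist(pages, use.names = FALSE),
                  c(dims[1, 1], dims[2, 1], length(pages)))
    # unlist concatenates column-major per page, which is exactly the
    # column-major band-last layout of the cube array
    side <- paste0(path, ".json")
    if (is.null(wavelengths) && file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      wavelengths <- meta[["wavelengths_nm"]]
    }
  } else if (ext == "msc") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
    if (!identical(hdr$format, "msc1")) stop("not an msc archive: ", path)
    d <- as.integer(hdr$dim)
    if (d[3] < 2L) stop("band-pair selection needs at least 2 bands")
    vals <- readBin(con, "double", n = prod(d), size = 8L,
                    endian = "little")
    if (length(vals) != prod(d)) stop("truncated msc archive")
    data <- array(vals, d)
    if (is.null(wavelengths)) wavelengths <- hdr$wavelengths_nm
  } else {
    stop("unsupported cube format: .", ext)
  }
  if (any(is.infinite(data))) stop("cube contains infinite values")
  if (anyNA(data))
    warning("cube contains NaN values (masked cube?)")
  if (length(wavelengths) == 0L) wavelengths <- NULL
  if (!is.null(wavelengths) && length(wavelengths) != dim(data)[3])
    stop("wavelength count (", length(wavelengths),
         ") does not match band count (", dim(data)[3], ")")
  SpectralCube(data, wavelengths = wavelengths, sourceId = path)
}

#' Write a multispectral cube
#'
#' `.msc` archives are bitwise-lossless (float64, NaN preserved). TIFF
#' export writes one 32-bit page per band (quantization error below 1e-9)
#' and is restricted to finite values in [0, 1], the reflectance range; a
#' JSON sidecar `<path>.json` carries the wavelengths. Use the archive
#' format for masked cubes or exact round-trips.
#'
#' @param cube a [SpectralCube-class].
#' @param path destination ending in `.msc`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @seealso [readCube()]
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  validObject(cube)
  ext <- tolower(tools::file_ext(path))
  d <- dim(cube@data)
  if (ext %in% c("tif", "tiff")) {
    if (anyNA(cube@data))
      stop("TIFF export cannot preserve NaN; use the .msc archive format")
    if (min(cube@data) < 0 || max(cube@data) > 1)
      stop("TIFF export requires reflectances in [0, 1]; use .msc")
    pages <- lapply(seq_len(d[3]), function(w) cube@data[, , w])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(wavelengths_nm = cube@wavelengths),
                         paste0(path, ".json"), auto_unbox = FALSE,
                         digits = NA)
  } else if (ext == "msc") {
    hdr <- jsonlite::toJSON(list(format = "msc1", dim = d,
                                 wavelengths_nm = cube@wavelengths,
                                 source_id = cube@sourceId),
                            auto_unbox = FALSE, digits = NA)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
    writeBin(as.vector(cube@data), con, size = 8L, endian = "little")
  } else {
    stop("unsupported cube format: .", ext)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Masks are stored as single-band 8-bit images (PNG or TIFF), 0 = excluded;
#' any nonzero value reads as included (both 0/255 and 0/1 dialects are
#' tolerated). Multi-channel images are rejected.
#'
#' @param path a `.png`, `.tif` or `.tiff` file.
#' @param label mask role tag, see [BinaryMask-class].
#' @return a [BinaryMask-class].
#' @seealso [writeMask()]
#' @export
readMask <- function(path, label = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) != 2L)
    stop("mask must be a single-band 2-D image, got ",
         length(dim(img)), " dimensions")
  BinaryMask(img > 0, label = label)
}

#' Write a binary mask
#'
#' Written as a single-band 8-bit image with 0 = excluded, 255 = included.
#'
#' @param mask a [BinaryMask-class].
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @seealso [readMask()]
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  img <- mask@data * 1.0
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L,
                           compression = "none", reduce = FALSE),
    stop("unsupported mask format: .", ext))
  invisible(path)
}
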