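## File I/O: 8-bit grayscale rasters, profile CSVs, model JSON.

#' Read an 8-bit single-channel PNG or TIFF en-face image
#'
#' Multi-channel or deeper-than-8-bit rasters are rejected with an
#' explicit message; pixel values are loaded unmodified as gray levels
#' 0-255.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param extentX,extentY lateral extents in mm (default 3.25 mm square).
#' @return an [EnFaceImage-class].
#' @export
readEnFace <- function(path, extentX = 3.25, extentY = 3.25) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    r <- png::readPNG(path, info = TRUE)
    info <- attr(r, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L)
      stop("expected single-channel 8-bit image, got ", info$bit.depth,
           "-bit PNG")
    if (length(dim(r)) == 3L)
      stop("expected single-channel 8-bit image, got ", dim(r)[3L],
           " channels")
    px <- matrix(round(r * 255), nrow(r))
  } else if (ext %in% c("tif", "tiff")) {
    r <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(r, "bits.per.sample")
    if (!is.null(bits) && bits > 8L)
      stop("expected single-channel 8-bit image, got ", bits, "-bit TIFF")
    if (length(dim(r)) == 3L)
      stop("expected single-channel 8-bit image, got ", dim(r)[3L],
           " channels")
    px <- matrix(round(r * 255), nrow(r))
  } else stop("unsupported image format: .", ext)
  EnFaceImage(px, extentX = extentX, extentY = extentY)
}

#' Write an en-face image as 8-bit grayscale PNG or TIFF
#'
#' @param image an [EnFaceImage-class]; pixels are rounded to integers.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
writeEnFace <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  g <- round(image@pixels) / 255
  if (ext == "png") png::writePNG(g, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(g, path, bits.per.sample = 8L)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Profile CSV round trip
#'
#' Profiles are written as comma-separated UTF-8 with a header row:
#' `x_mm,reflectivity` for raw profiles, `x_mm,reflectivity_smoothed` for
#' smoothed graphs.
#'
#' @param profile a [ReflectivityProfile-class].
#' @param path CSV path.
#' @return `writeProfileCSV`: `path` invisibly; `readProfileCSV`: a
#'   [ReflectivityProfile-class].
#' @export
writeProfileCSV <- function(profile, path) {
  col <- if (profile@kind == "raw") "reflectivity" else
    "reflectivity_smoothed"
  df <- data.frame(x_mm = profile@x, v = profile@rho)
  names(df)[2L] <- col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeProfileCSV
#' @export
readProfileCSV <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  kind <- if ("reflectivity_smoothed" %in% names(df)) "smoothed" else "raw"
  new("ReflectivityProfile", x = df$x_mm, rho = df[[2L]], kind = kind)
}

#' Model JSON round trip
#'
#' A [PiecewiseModel-class] serializes as
#' `{archetype, segments: [{x_lo, x_hi, a, b, c}], anchors}`.
#'
#' @param model a [PiecewiseModel-class].
#' @param path JSON path.
#' @return `writeModelJSON`: `path` invisibly; `readModelJSON`: a
#'   [PiecewiseModel-class].
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(
    list(archetype = model@archetype,
         segments = model@segments,
         anchors = model@anchors),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PiecewiseModel",
      segments = as.data.frame(j$segments),
      archetype = j$archetype,
      anchors = as.list(j$anchors))
}
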