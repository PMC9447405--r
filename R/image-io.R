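#' Construct a RasterImage from a pixel array
#'
#' @param pixels numeric matrix (greyscale) or height x width x 3 array
#'   (RGB), values in `[0, 2^bitDepth - 1]`.
#' @param bitDepth 8 or 16.
#' @return a [RasterImage-class].
#' @export
RasterImage <- function(pixels, bitDepth = 8L) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("RasterImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' @rdname pixelData
#' @export
setMethod("pixelData", "RasterImage", function(img) {
  p <- img@pixels
  if (length(dim(p)) == 2L) p <- matrix(p, nrow = dim(p)[1])
  p
})

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "RasterImage", function(img) img@bitDepth)

#' @rdname isColour
#' @export
setMethod("isColour", "RasterImage", function(img) length(dim(img@pixels)) == 3L)

#' Image dimensions
#'
#' @param img a [RasterImage-class].
#' @return integer `c(height, width)`.
#' @export
imageDim <- function(img) dim(img@pixels)[1:2]

# round half-up: R's round() is round-half-even, imaging convention is not
.roundHalfUp <- function(x) floor(x + 0.5)

#' Read a scanned array image
#'
#' Reads a TIFF, PNG or JPEG file into a [RasterImage-class], preserving
#' the native bit depth (8 or 16). Multi-page TIFFs use page 1 only. RGBA
#' input drops the alpha channel with a warning. The format is inferred
#' from the file signature, falling back to the file extension.
#'
#' @param path path to an existing TIFF/PNG/JPEG file.
#' @return a [RasterImage-class] (greyscale or RGB colour).
#' @seealso [writeArrayImage()], [toGrey()]
#' @export
readArrayImage <- function(path) {
  if (length(path) != 1L || !is.character(path))
    stop("'path' must be a single file path")
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  fmt <- .sniffFormat(path)
  px <- switch(fmt,
    tiff = .readTiff(path),
    png  = .readPng(path),
    jpeg = .readJpeg(path),
    stop("unsupported image format (expected TIFF, PNG or JPEG): ", path)
  )
  px
}

.sniffFormat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) >= 4L) {
    if ((magic[1] == as.raw(0x49) && magic[2] == as.raw(0x49)) ||
        (magic[1] == as.raw(0x4d) && magic[2] == as.raw(0x4d))) return("tiff")
    if (magic[1] == as.raw(0x89) && magic[2] == as.raw(0x50)) return("png")
    if (magic[1] == as.raw(0xff) && magic[2] == as.raw(0xd8)) return("jpeg")
  }
  switch(tolower(tools::file_ext(path)),
         tif = , tiff = "tiff", png = "png", jpg = , jpeg = "jpeg",
         "unknown")
}

.dropAlpha <- function(a, path) {
  if (length(dim(a)) == 3L && dim(a)[3] %in% c(2L, 4L)) {
    warning("ignoring alpha channel in ", path)
    a <- a[, , -dim(a)[3], drop = FALSE]
    if (dim(a)[3] == 1L) a <- matrix(a[, , 1], nrow = dim(a)[1])
  }
  a
}

.readTiff <- function(path) {
  a <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = FALSE),
                error = function(e) stop("cannot read TIFF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  depth <- attr(a, "bits.per.sample")
  if (is.null(depth)) depth <- 8L
  if (!depth %in% c(8, 16))
    stop("unsupported TIFF sample depth (", depth, " bits) in ", path)
  a <- .dropAlpha(unclass(a), path)
  if (length(dim(a)) == 3L && dim(a)[3] == 1L)
    a <- matrix(a[, , 1], nrow = dim(a)[1])
  RasterImage(a * 1.0, bitDepth = as.integer(depth))
}

.readPng <- function(path) {
  a <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) stop("cannot read PNG '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  info <- attr(a, "info")
  depth <- if (!is.null(info) && !is.null(info$bit.depth))
    as.integer(info$bit.depth) else 8L
  if (depth < 8L) depth <- 8L
  if (!depth %in% c(8L, 16L))
    stop("unsupported PNG bit depth (", depth, ") in ", path)
  a <- .dropAlpha(unclass(a), path)
  # readPNG returns [0,1]; recover native integer codes
  RasterImage(.roundHalfUp(a * (2^depth - 1)), bitDepth = depth)
}

.readJpeg <- function(path) {
  a <- tryCatch(jpeg::readJPEG(path),
                error = function(e) stop("cannot read JPEG '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  RasterImage(.roundHalfUp(unclass(a) * 255), bitDepth = 8L)
}

#' Write an image to TIFF or PNG
#'
#' Lossless writer used for fixtures and synthetic output. TIFF supports
#' 8- and 16-bit; PNG is written at the image's bit depth. The format is
#' chosen from the file extension.
#'
#' @param img a [RasterImage-class].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
writeArrayImage <- function(img, path) {
  stopifnot(is(img, "RasterImage"))
  mx <- 2^bitDepth(img) - 1
  norm <- img@pixels / mx
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = bitDepth(img))
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop("writeArrayImage supports .tif/.tiff/.png, got: ", path)
  }
  invisible(path)
}

#' @rdname toGrey
#' @export
setMethod("toGrey", "RasterImage", function(img) {
  if (!isColour(img)) return(img)
  p <- img@pixels
  g <- 0.3 * p[, , 1] + 0.59 * p[, , 2] + 0.11 * p[, , 3]
  RasterImage(matrix(.roundHalfUp(g), dim(p)[1], dim(p)[2]),
              bitDepth = bitDepth(img))
})

#' @rdname rescaleTo8bit
#' @export
setMethod("rescaleTo8bit", "RasterImage", function(img) {
  if (bitDepth(img) != 16L)
    stop("rescaleTo8bit expects a 16-bit image")
  if (isColour(img))
    stop("rescaleTo8bit expects a greyscale image; call toGrey() first")
  p <- pixelData(img)
  lo <- min(p); hi <- max(p)
  out <- if (hi == lo) matrix(0, nrow(p), ncol(p))
         else .roundHalfUp((p - lo) / (hi - lo) * 255)
  RasterImage(out, bitDepth = 8L)
})
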