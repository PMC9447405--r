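#' @import methods
NULL

#' RasterImage: a scanned array image
#'
#' Container for one raster image as read from a TIFF/PNG/JPEG scan.
#' Greyscale images hold a height x width numeric matrix of integer-valued
#' intensities; colour images hold a height x width x 3 array with
#' channels ordered R, G, B. Row 1 is the top of the image. All values lie
#' in `[0, 2^bitDepth - 1]`.
#'
#' @slot pixels numeric matrix (grey) or 3-d array (colour) of intensities.
#' @slot bitDepth integer, 8 or 16.
#'
#' @seealso [readArrayImage()], [toGrey()], [rescaleTo8bit()]
#' @export
setClass("RasterImage",
  representation(pixels = "array", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!length(d) %in% c(2L, 3L))
      return("pixels must be a 2-d matrix or height x width x 3 array")
    if (length(d) == 3L && d[3] != 3L)
      return("colour images must have exactly 3 channels (R, G, B)")
    if (d[1] < 1L || d[2] < 1L)
      return("image must be at least 1 x 1")
    if (!object@bitDepth %in% c(8L, 16L))
      return("bitDepth must be 8 or 16")
    mx <- 2^object@bitDepth - 1
    v <- object@pixels
    if (anyNA(v)) return("pixels must not contain NA")
    if (min(v) < 0 || max(v) > mx)
      return(sprintf("pixel values must lie in [0, %d]", mx))
    TRUE
  }
)

#' GridSpec: a rows x columns partition of an array image
#'
#' The user-declared grid: how many spot rows and columns the scanned
#' array contains, plus optional margins (in pixels) trimmed off the image
#' border before partitioning. Each resulting cell is intended to contain
#' exactly one spot.
#'
#' @slot nRows,nCols integer counts of grid rows / columns (>= 1).
#' @slot marginTop,marginLeft,marginBottom,marginRight integer pixel
#'   margins excluded from the usable region (default 0).
#'
#' @seealso [makeGrid()]
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer",
                 marginTop = "integer", marginLeft = "integer",
                 marginBottom = "integer", marginRight = "integer"),
  prototype(marginTop = 0L, marginLeft = 0L,
            marginBottom = 0L, marginRight = 0L),
  validity = function(object) {
    if (object@nRows < 1L || object@nCols < 1L)
      return("nRows and nCols must both be >= 1")
    m <- c(object@marginTop, object@marginLeft,
           object@marginBottom, object@marginRight)
    if (any(m < 0L)) return("margins must be non-negative")
    TRUE
  }
)

#' IntensityHistogram: 256-bin pixel-intensity histogram
#'
#' All thresholding methods operate on a fixed 256-bin histogram. 8-bit
#' data maps one intensity per bin; 16-bit data is binned into 256
#' equal-width bins over `[0, 65535]` (binWidth 256). Thresholds are
#' reported on the original intensity scale as the upper edge of the
#' chosen background bin, so "value > threshold" selects foreground.
#'
#' @slot counts integer vector of length 256.
#' @slot binWidth integer, 1 (8-bit) or 256 (16-bit).
#'
#' @seealso [buildHistogram()], [otsuThreshold()], [thresholdSuite()]
#' @export
setClass("IntensityHistogram",
  representation(counts = "integer", binWidth = "integer"),
  validity = function(object) {
    if (length(object@counts) != 256L)
      return("counts must have exactly 256 bins")
    if (any(object@counts < 0L)) return("bin counts must be non-negative")
    if (sum(object@counts) < 1L) return("histogram must contain >= 1 pixel")
    if (!object@binWidth %in% c(1L, 256L))
      return("binWidth must be 1 (8-bit) or 256 (16-bit)")
    TRUE
  }
)

#' BinaryMask: foreground/background classification of a region
#'
#' Produced by thresholding one grid cell (local mode) or a whole image
#' (global mode). `TRUE` marks foreground (spot) pixels. `threshold` is
#' `NA` when the source histogram was degenerate (a single occupied bin:
#' no two-class split exists), in which case the mask is all background
#' and the `"empty"` flag is set.
#'
#' @slot mask logical matrix, same dimensions as the source region.
#' @slot threshold numeric threshold applied (intensity scale), or `NA`.
#' @slot method character, thresholding method name.
#' @slot flags character vector, subset of `c("empty", "degenerate")`.
#'
#' @seealso [binarizeGlobal()], [binarizeLocal()]
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", threshold = "numeric",
                 method = "character", flags = "character"),
  prototype(flags = character(0)),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@threshold) != 1L) return("threshold must be length 1")
    TRUE
  }
)

#' SyntheticSpec: recipe for a synthetic array image
#'
#' Everything needed to render a seeded, fully determined synthetic array
#' scan with ground truth: the spot layout, geometry, optics-like blur,
#' background field, noise level and per-spot true amplitudes.
#'
#' @slot layout data.frame with columns `row`, `col` (1-based), `analyte`,
#'   `concentration`, `replicate`; one entry per grid position.
#' @slot cellSize integer, side length of each square grid cell (pixels).
#' @slot spotRadiusRange numeric length-2, min/max spot radius (pixels).
#' @slot shape character, one of `"disc"`, `"ellipse"`, `"blob"`.
#' @slot psfSigma numeric, Gaussian edge blur of the spot profile (pixels).
#' @slot background list with `type` (`"uniform"`, `"linear"`,
#'   `"quadratic"`), `base` (grey level) and `amplitude` (grey levels of
#'   variation across the image; 0 for uniform).
#' @slot noiseSigma numeric, sd of additive Gaussian pixel noise.
#' @slot amplitudes numeric, true amplitude per layout entry (grey levels
#'   above local background at the spot centre).
#' @slot bitDepth integer, 8 or 16.
#' @slot seed integer; fixed seed implies bit-identical output.
#'
#' @seealso [arraySpec()], [renderArray()]
#' @export
setClass("SyntheticSpec",
  representation(layout = "data.frame", cellSize = "integer",
                 spotRadiusRange = "numeric", shape = "character",
                 psfSigma = "numeric", background = "list",
                 noiseSigma = "numeric", amplitudes = "numeric",
                 bitDepth = "integer", seed = "integer"),
  validity = function(object) {
    lay <- object@layout
    need <- c("row", "col", "analyte", "concentration", "replicate")
    if (!all(need %in% names(lay)))
      return(paste("layout must have columns:", paste(need, collapse = ", ")))
    nr <- max(lay$row); nc <- max(lay$col)
    key <- paste(lay$row, lay$col)
    if (nrow(lay) != nr * nc || anyDuplicated(key))
      return("layout entries must cover every grid position exactly once")
    if (length(object@amplitudes) != nrow(lay))
      return("amplitudes must have one value per layout entry")
    if (any(object@amplitudes < 0)) return("amplitudes must be >= 0")
    if (object@cellSize < 8L) return("cellSize must be >= 8 pixels")
    rr <- object@spotRadiusRange
    if (length(rr) != 2L || rr[1] > rr[2] || rr[1] <= 0)
      return("spotRadiusRange must be c(min, max) with 0 < min <= max")
    if (object@psfSigma < 0) return("psfSigma must be >= 0")
    # jitter (<= 2 px) + blur tail must keep the spot inside its cell
    if (rr[2] + 2 + 2 * object@psfSigma > object@cellSize / 2)
      return("spot radius too large for cell: max radius + blur must fit in cellSize/2")
    if (!object@shape %in% c("disc", "ellipse", "blob"))
      return("shape must be one of disc, ellipse, blob")
    bg <- object@background
    if (!all(c("type", "base", "amplitude") %in% names(bg)))
      return("background must be list(type=, base=, amplitude=)")
    if (!bg$type %in% c("uniform", "linear", "quadratic"))
      return("background type must be uniform, linear or quadratic")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
    TRUE
  }
)

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage: %d x %d, %d-bit, %s\n", d[1], d[2],
              object@bitDepth,
              if (length(d) == 3L) "colour (RGB)" else "greyscale"))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d rows x %d cols", object@nRows, object@nCols))
  m <- c(object@marginTop, object@marginLeft,
         object@marginBottom, object@marginRight)
  if (any(m > 0L))
    cat(sprintf(" (margins t/l/b/r = %d/%d/%d/%d)", m[1], m[2], m[3], m[4]))
  cat("\n")
})

setMethod("show", "IntensityHistogram", function(object) {
  cat(sprintf("IntensityHistogram: %d pixels in 256 bins (bin width %d)\n",
              sum(object@counts), object@binWidth))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask: %d x %d, method %s, threshold %s, %d fg pixels%s\n",
              d[1], d[2], object@method,
              ifelse(is.na(object@threshold), "NA",
                     format(object@threshold)),
              sum(object@mask),
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d spots, cell %d px, shape %s, %s background, noise sd %g, seed %d\n",
    max(object@layout$row), max(object@layout$col), object@cellSize,
    object@shape, object@background$type, object@noiseSigma, object@seed))
})
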