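#' Convert a colour image to greyscale
#'
#' Colour (RGB) images are reduced to a single luminance channel with the
#' weights 0.3, 0.59, 0.11 for red, green and blue; the weighted value is
#' computed in floating point and rounded half-up to the integer range of
#' the input bit depth. Greyscale input is returned unchanged, so the
#' operation is idempotent.
#'
#' @param img a [RasterImage-class].
#' @return a greyscale [RasterImage-class] of the same size and bit depth.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' toGrey(RasterImage(px, bitDepth = 8))  # 0.3 * 255 = 76.5 -> 77
#' @export
setGeneric("toGrey", function(img) standardGeneric("toGrey"))

#' Rescale a 16-bit image linearly to 8 bits
#'
#' Min-max rescaling of the intensity range actually present onto
#' `[0, 255]` with half-up rounding; a constant image maps to 0. Provided
#' for workflows that mirror an 8-bit analysis of 16-bit scanner output;
#' the pipeline otherwise processes 16-bit data natively.
#'
#' @param img a greyscale 16-bit [RasterImage-class].
#' @return an 8-bit [RasterImage-class].
#' @export
setGeneric("rescaleTo8bit", function(img) standardGeneric("rescaleTo8bit"))

#' Partition an image into grid cells
#'
#' Splits the usable region (image minus margins) into `nRows * nCols`
#' rectangular cells in row-major order. Cell heights are
#' `floor(usable_height / nRows)`, with the remainder pixels given one
#' each to the last rows (likewise for columns), so the cells tile the
#' usable region exactly: no gap, no overlap.
#'
#' @param img a [RasterImage-class].
#' @param spec a [GridSpec-class].
#' @return a data.frame with one row per cell, in row-major order:
#'   `row_index`, `col_index` (0-based), and 0-based half-open pixel
#'   bounds `y0`, `y1`, `x0`, `x1`.
#' @export
setGeneric("makeGrid", function(img, spec) standardGeneric("makeGrid"))

#' Render a synthetic array image with ground truth
#'
#' Produces a seeded, fully deterministic synthetic scan: a background
#' field (uniform, linear gradient, or quadratic), one roughly circular
#' (or elliptical / irregular-blob) spot per grid cell with a Gaussian
#' blurred edge, plus additive Gaussian noise, clipped and rounded to the
#' requested bit depth. Rendering the same spec twice yields bit-identical
#' images.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a list with elements `image` (greyscale [RasterImage-class]),
#'   `truth` (data.frame: `row`, `col`, `analyte`, `concentration`,
#'   `replicate`, `true_amplitude`), and `masks` (list of logical
#'   matrices, the true within-cell spot masks, row-major cell order).
#' @export
setGeneric("renderArray", function(spec) standardGeneric("renderArray"))

#' @describeIn RasterImage-class pixel array accessor
#' @param img,object a `RasterImage`
#' @export
setGeneric("pixelData", function(img) standardGeneric("pixelData"))

#' @describeIn RasterImage-class bit depth accessor (8 or 16)
#' @export
setGeneric("bitDepth", function(img) standardGeneric("bitDepth"))

#' @describeIn RasterImage-class TRUE if the image carries R,G,B channels
#' @export
setGeneric("isColour", function(img) standardGeneric("isColour"))

#' @describeIn BinaryMask-class logical foreground mask accessor
#' @param mask,object a `BinaryMask`
#' @export
setGeneric("maskData", function(mask) standardGeneric("maskData"))

#' @describeIn BinaryMask-class threshold that produced the mask (NA if
#'   degenerate)
#' @export
setGeneric("thresholdUsed", function(mask) standardGeneric("thresholdUsed"))
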