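#' Run the full measurement workflow on an image
#'
#' The load -> grid -> threshold -> quantify -> save workflow in one
#' call: reads the image (or takes a [RasterImage-class] directly),
#' converts colour to greyscale, optionally rescales 16-bit input to 8
#' bits, partitions into the declared grid and quantifies every spot.
#'
#' @param image file path (TIFF/PNG/JPEG) or a [RasterImage-class].
#' @param rows,cols grid dimensions (>= 1 each).
#' @param margins length-4 integer vector (top, left, bottom, right
#'   pixels), default all 0.
#' @param method thresholding method (see [thresholdSuite()]).
#' @param mode `"local"` (default) or `"global"`.
#' @param bgStat background statistic, `"median"` or `"mean"`.
#' @param minArea minimum foreground pixels per detected spot.
#' @param rescale if `TRUE`, 16-bit input is min-max rescaled to 8 bits
#'   before analysis (default `FALSE`: native 16-bit processing).
#' @param output optional CSV path; measurements are written there too.
#' @return the measurement data.frame (see [quantifyArray()]),
#'   invisibly if `output` is given.
#' @export
runCalculate <- function(image, rows, cols, margins = c(0L, 0L, 0L, 0L),
                         method = "otsu", mode = "local",
                         bgStat = "median", minArea = 4L,
                         rescale = FALSE, output = NULL) {
  if (rows < 1L || cols < 1L)
    stop("rows and cols must both be >= 1")
  img <- if (is(image, "RasterImage")) image else readArrayImage(image)
  if (isColour(img)) img <- toGrey(img)
  if (rescale && bitDepth(img) == 16L) img <- rescaleTo8bit(img)
  spec <- GridSpec(rows, cols, margins[1], margins[2], margins[3], margins[4])
  res <- quantifyArray(img, spec, method = method, mode = mode,
                       bgStat = bgStat, minArea = minArea)
  if (!is.null(output)) {
    writeMeasurements(res, output)
    return(invisible(res))
  }
  res
}

#' Validate pipeline output against a reference
#'
#' Joins two measurement tables on their `(row, col)` grid positions and
#' reports the Spearman rank correlation (with significance), and the
#' OLS calibration line with its R-squared, between the pipeline values
#' and the reference values.
#'
#' @param results data.frame or CSV path with columns `row`, `col` and
#'   `valueCol`.
#' @param reference data.frame or CSV path with columns `row`, `col` and
#'   `refCol`.
#' @param valueCol column of `results` to validate
#'   (default `"net_intensity"`).
#' @param refCol column of `reference` to compare against (default
#'   `"true_amplitude"`).
#' @return list: `r`, `p_value`, `N`, `slope`, `intercept`, `r_squared`.
#' @export
runValidate <- function(results, reference, valueCol = "net_intensity",
                        refCol = "true_amplitude") {
  readTab <- function(x) if (is.character(x))
    utils::read.csv(x, stringsAsFactors = FALSE) else x
  res <- readTab(results); ref <- readTab(reference)
  for (nm in c("row", "col", valueCol))
    if (!nm %in% names(res)) stop("results table lacks column '", nm, "'")
  for (nm in c("row", "col", refCol))
    if (!nm %in% names(ref)) stop("reference table lacks column '", nm, "'")
  merged <- merge(res[, c("row", "col", valueCol)],
                  ref[, c("row", "col", refCol)], by = c("row", "col"))
  if (nrow(merged) == 0L)
    stop("no overlapping (row, col) positions between results and reference")
  x <- merged[[valueCol]]; y <- merged[[refCol]]
  sp <- spearmanCorrelation(x, y)
  lr <- linearCalibration(y, x)
  list(r = sp$r, p_value = sp$p_value, N = sp$N,
       slope = lr$slope, intercept = lr$intercept,
       r_squared = lr$r_squared)
}

#' Compare thresholding methods on one array image
#'
#' Runs local-mode quantification once per method and tabulates, for
#' each, the number of detected spots and (when ground truth is given)
#' the mean absolute error of the net intensities against the true
#' amplitudes — a quantitative version of the side-by-side binarization
#' comparison used to pick a production method.
#'
#' @param image file path or [RasterImage-class].
#' @param rows,cols grid dimensions.
#' @param methods character vector of method names (default: all of
#'   [thresholdMethods()]).
#' @param truth optional ground-truth data.frame (`row`, `col`,
#'   `true_amplitude`).
#' @param minArea minimum foreground pixels per detected spot.
#' @return data.frame: `method`, `spots_detected`, `mean_abs_error`
#'   (`NA` without truth).
#' @export
runCompareMethods <- function(image, rows, cols,
                              methods = thresholdMethods(), truth = NULL,
                              minArea = 4L) {
  bad <- setdiff(methods, thresholdMethods())
  if (length(bad))
    stop("unknown thresholding method(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(thresholdMethods(), collapse = ", "))
  img <- if (is(image, "RasterImage")) image else readArrayImage(image)
  if (isColour(img)) img <- toGrey(img)
  rows <- do.call(rbind, lapply(methods, function(m) {
    tab <- quantifyArray(img, GridSpec(rows, cols), method = m,
                         mode = "local", minArea = minArea)
    mae <- NA_real_
    if (!is.null(truth)) {
      merged <- merge(tab, truth[, c("row", "col", "true_amplitude")],
                      by = c("row", "col"))
      mae <- mean(abs(merged$net_intensity - merged$true_amplitude))
    }
    data.frame(method = m, spots_detected = sum(tab$fg_area >= minArea),
               mean_abs_error = mae)
  }))
  rows
}

#' Generate and save a synthetic fixture
#'
#' Renders one of the built-in synthetic presets and writes the image
#' plus its ground-truth CSV.
#'
#' @param seed integer seed.
#' @param preset `"gradient"` (70-spot gradient-background array),
#'   `"cd14"` (five-replicate panel) or `"antigen"` (31-condition
#'   dilution layout).
#' @param imagePath output image path (`.tif`/`.tiff`/`.png`).
#' @return paths written (image, truth CSV), invisibly.
#' @export
runSynth <- function(seed, preset = c("gradient", "cd14", "antigen"),
                     imagePath) {
  preset <- match.arg(preset)
  spec <- switch(preset,
                 gradient = gradientArraySpec(seed = seed),
                 cd14 = cd14PanelSpec(seed = seed),
                 antigen = arraySpec(seed = as.integer(seed)))
  writeSyntheticArray(renderArray(spec), imagePath)
}
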