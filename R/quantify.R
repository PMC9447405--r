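#' Estimate the local background level of one cell
#'
#' The background level is the median intensity of the cell's
#' background-labelled pixels — robust against the spot occupying a
#' variable fraction of the cell and against bright outliers. If the mask
#' labels every pixel foreground, the minimum cell intensity is used as a
#' fallback and a warning is raised.
#'
#' @param px numeric matrix, the cell's pixels (see [cellPixels()]).
#' @param mask the cell's [BinaryMask-class].
#' @param stat background statistic, `"median"` (default) or `"mean"`.
#' @return background level (numeric scalar).
#' @export
estimateBackground <- function(px, mask, stat = "median") {
  stopifnot(is(mask, "BinaryMask"), all(dim(px) == dim(maskData(mask))))
  stat <- match.arg(stat, c("median", "mean"))
  bg <- px[!maskData(mask)]
  if (length(bg) == 0L) {
    warning("mask labels the whole cell foreground; ",
            "using minimum cell intensity as background")
    return(min(px))
  }
  if (stat == "median") stats::median(bg) else mean(bg)
}

#' Measure one spot
#'
#' Converts a cell's pixels and foreground mask into a background
#' corrected intensity record. `net_intensity` is the mean foreground
#' intensity minus the local background estimate, clipped at zero;
#' `fg_sum` is the integrated (summed) foreground intensity with `bg`
#' subtracted per pixel, also clipped at zero. Empty cells yield an
#' all-zero record flagged `"empty"`. A spot is flagged `"saturated"`
#' when at least 1% of its foreground pixels sit at the bit-depth
#' maximum, and `"edge_clipped"` when its foreground touches the cell
#' border.
#'
#' @param px numeric matrix, the cell's pixels.
#' @param mask the cell's [BinaryMask-class].
#' @param bg background level from [estimateBackground()].
#' @param bitDepth bit depth of the source image (for the saturation
#'   check), default 8.
#' @param row,col 1-based grid position recorded in the output.
#' @return one-row data.frame: `row`, `col`, `fg_mean`, `fg_sum`,
#'   `fg_area`, `bg_estimate`, `net_intensity`, `flags`
#'   (semicolon-separated, possibly empty string).
#' @export
measureSpot <- function(px, mask, bg, bitDepth = 8L, row = 1L, col = 1L) {
  stopifnot(is(mask, "BinaryMask"), all(dim(px) == dim(maskData(mask))))
  m <- maskData(mask)
  area <- sum(m)
  flags <- mask@flags
  if (area == 0L) {
    flags <- unique(c(flags, "empty"))
    return(data.frame(row = row, col = col, fg_mean = 0, fg_sum = 0,
                      fg_area = 0L, bg_estimate = bg, net_intensity = 0,
                      flags = paste(sort(flags), collapse = ";")))
  }
  fg <- px[m]
  fgMean <- mean(fg)
  if (mean(fg == (2^bitDepth - 1)) >= 0.01)
    flags <- c(flags, "saturated")
  edge <- any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
  if (edge) flags <- c(flags, "edge_clipped")
  data.frame(row = row, col = col,
             fg_mean = fgMean,
             fg_sum = max(0, sum(fg) - bg * area),
             fg_area = area,
             bg_estimate = bg,
             net_intensity = max(0, fgMean - bg),
             flags = paste(sort(unique(flags)), collapse = ";"))
}

#' Quantify every spot of an array image
#'
#' The full measurement pipeline for one greyscale image: partition into
#' grid cells, threshold (per cell by default, or one global threshold),
#' estimate each cell's local background from its background-labelled
#' pixels, and report one background-corrected measurement per cell in
#' row-major order. Deterministic for fixed input.
#'
#' @param img a [RasterImage-class]; colour input is converted with
#'   [toGrey()] first.
#' @param grid a [GridSpec-class], or a cells data.frame from
#'   [makeGrid()].
#' @param method thresholding method name (see [thresholdSuite()]).
#' @param mode `"local"` (per-cell thresholds, default) or `"global"`.
#' @param bgStat background statistic, `"median"` or `"mean"`.
#' @param minArea minimum foreground pixels per cell (default 4).
#' @param minContrast local-mode detection limit in background-sd units
#'   (default 3; see [binarizeLocal()]).
#' @return data.frame with one row per cell (row-major): `row`, `col`
#'   (1-based), `fg_mean`, `fg_sum`, `fg_area`, `bg_estimate`,
#'   `net_intensity`, `flags`.
#' @examples
#' res <- renderArray(gradientArraySpec(seed = 42))
#' tab <- quantifyArray(res$image, GridSpec(7, 10))
#' head(tab)
#' @export
quantifyArray <- function(img, grid, method = "otsu", mode = "local",
                          bgStat = "median", minArea = 4L,
                          minContrast = 3) {
  stopifnot(is(img, "RasterImage"))
  mode <- match.arg(mode, c("local", "global"))
  if (isColour(img)) img <- toGrey(img)
  cells <- if (is(grid, "GridSpec")) makeGrid(img, grid) else grid
  masks <- if (mode == "local") {
    binarizeLocal(img, cells, method = method, minArea = minArea,
                  minContrast = minContrast)
  } else {
    full <- binarizeGlobal(img, method = method)
    fm <- maskData(full)
    lapply(seq_len(nrow(cells)), function(k) {
      c <- cells[k, ]
      sub <- fm[(c$y0 + 1L):c$y1, (c$x0 + 1L):c$x1, drop = FALSE]
      m <- new("BinaryMask", mask = sub, threshold = full@threshold,
               method = method, flags = full@flags)
      if (sum(sub) < minArea) {
        m@mask[] <- FALSE
        m@flags <- unique(c(m@flags, "empty"))
      }
      m
    })
  }
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    c <- cells[k, ]
    px <- cellPixels(img, c)
    bg <- suppressWarnings(estimateBackground(px, masks[[k]], stat = bgStat))
    measureSpot(px, masks[[k]], bg, bitDepth = bitDepth(img),
                row = c$row_index + 1L, col = c$col_index + 1L)
  })
  do.call(rbind, rows)
}

#' Write spot measurements to CSV
#'
#' Plain comma-separated output with one header line, UTF-8, `.` decimal
#' separator — the pipeline's save format.
#'
#' @param measurements data.frame from [quantifyArray()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
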