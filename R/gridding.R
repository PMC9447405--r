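#' Construct a GridSpec
#'
#' @param nRows,nCols number of grid rows / columns (>= 1 each).
#' @param marginTop,marginLeft,marginBottom,marginRight pixels trimmed
#'   from each image border before partitioning (default 0).
#' @return a [GridSpec-class].
#' @export
GridSpec <- function(nRows, nCols, marginTop = 0L, marginLeft = 0L,
                     marginBottom = 0L, marginRight = 0L) {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      marginTop = as.integer(marginTop), marginLeft = as.integer(marginLeft),
      marginBottom = as.integer(marginBottom),
      marginRight = as.integer(marginRight))
}

# integer partition of `total` into `n` parts: base size floor(total/n),
# remainder pushed one pixel each onto the trailing parts
.partitionEdges <- function(total, n, offset = 0L) {
  base <- total %/% n
  rem <- total %% n
  sizes <- rep(base, n)
  if (rem > 0L) sizes[(n - rem + 1L):n] <- base + 1L
  offset + cumsum(c(0L, sizes))
}

#' @rdname makeGrid
#' @export
setMethod("makeGrid", signature("RasterImage", "GridSpec"),
function(img, spec) {
  d <- imageDim(img)
  uh <- d[1] - spec@marginTop - spec@marginBottom
  uw <- d[2] - spec@marginLeft - spec@marginRight
  if (uh < spec@nRows)
    stop(sprintf(
      "grid does not fit: %d rows requested but usable height is %d px",
      spec@nRows, uh))
  if (uw < spec@nCols)
    stop(sprintf(
      "grid does not fit: %d cols requested but usable width is %d px",
      spec@nCols, uw))
  ye <- .partitionEdges(uh, spec@nRows, spec@marginTop)
  xe <- .partitionEdges(uw, spec@nCols, spec@marginLeft)
  k <- seq_len(spec@nRows * spec@nCols) - 1L
  ri <- k %/% spec@nCols
  ci <- k %% spec@nCols
  data.frame(row_index = ri, col_index = ci,
             y0 = ye[ri + 1L], y1 = ye[ri + 2L],
             x0 = xe[ci + 1L], x1 = xe[ci + 2L])
})

#' Extract the pixels of one grid cell
#'
#' @param img a greyscale [RasterImage-class].
#' @param cell one row of the data.frame returned by [makeGrid()].
#' @return numeric matrix of the cell's pixels.
#' @export
cellPixels <- function(img, cell) {
  p <- pixelData(img)
  p[(cell$y0 + 1L):cell$y1, (cell$x0 + 1L):cell$x1, drop = FALSE]
}
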