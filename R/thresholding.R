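#' Build a 256-bin intensity histogram
#'
#' @param x numeric vector or matrix of pixel intensities.
#' @param bitDepth 8 or 16; 16-bit data is binned into 256 equal-width
#'   bins over `[0, 65535]`.
#' @return an [IntensityHistogram-class].
#' @export
buildHistogram <- function(x, bitDepth = 8L) {
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  bw <- if (bitDepth == 8L) 1L else 256L
  idx <- pmin(as.integer(x) %/% bw, 255L)
  counts <- tabulate(idx + 1L, nbins = 256L)
  new("IntensityHistogram", counts = counts, binWidth = bw)
}

# representative intensity of each 0-based bin index (exact for 8-bit,
# bin midpoint for 16-bit)
.binValues <- function(h) (0:255) * h@binWidth + (h@binWidth - 1) / 2

# split index t -> threshold on the intensity scale: pixels <= thr are
# background, > thr foreground
.splitToThreshold <- function(t, h) (t + 1) * h@binWidth - 1

.isDegenerate <- function(h) sum(h@counts > 0L) < 2L

#' Otsu's threshold
#'
#' Selects the threshold maximizing the between-class variance
#' `w0(t) * w1(t) * (mu0(t) - mu1(t))^2` of the two pixel classes split at
#' `t` (pixels `<=` threshold are background, `>` threshold foreground).
#' Ties are broken by the smallest maximizing threshold. A degenerate
#' histogram (all pixels in one bin) admits no two-class split and
#' returns `NA`.
#'
#' @param h an [IntensityHistogram-class].
#' @return the threshold on the intensity scale of the histogram's source
#'   data, or `NA_real_` for a degenerate histogram.
#' @examples
#' h <- buildHistogram(c(rep(50, 100), rep(200, 100)))
#' otsuThreshold(h)  # 50: any split in [50, 199] is maximal, smallest wins
#' @export
otsuThreshold <- function(h) {
  stopifnot(is(h, "IntensityHistogram"))
  if (.isDegenerate(h)) return(NA_real_)
  p <- h@counts / sum(h@counts)
  v <- .binValues(h)
  w0 <- cumsum(p)                 # P(class 0) for split at t = 0..255
  m0 <- cumsum(p * v)             # unnormalized class-0 mean
  mt <- m0[256]                   # grand mean
  t <- 0:254
  w0t <- w0[t + 1L]
  w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- m0[t + 1L] / w0t
  mu1 <- (mt - m0[t + 1L]) / w1t
  sb <- ifelse(valid, w0t * w1t * (mu0 - mu1)^2, -Inf)
  if (all(!valid)) return(NA_real_)
  .splitToThreshold(t[which.max(sb)], h)
}

.meanThreshold <- function(h) {
  if (.isDegenerate(h)) return(NA_real_)
  floor(sum(h@counts * .binValues(h)) / sum(h@counts))
}

.isodataThreshold <- function(h) {
  if (.isDegenerate(h)) return(NA_real_)
  v <- .binValues(h)
  cnt <- h@counts
  # split index in bin units; start from the overall mean
  t <- floor(sum(cnt * v) / sum(cnt) / h@binWidth)
  for (i in 1:256) {
    lo <- cnt[1:(t + 1L)]; hi <- cnt[(t + 2L):256]
    if (sum(lo) == 0L || sum(hi) == 0L) break
    mu0 <- sum(lo * v[1:(t + 1L)]) / sum(lo)
    mu1 <- sum(hi * v[(t + 2L):256]) / sum(hi)
    tNew <- floor((mu0 + mu1) / 2 / h@binWidth)
    tNew <- max(0L, min(254L, tNew))
    if (tNew == t) break
    t <- tNew
  }
  .splitToThreshold(t, h)
}

.triangleThreshold <- function(h) {
  if (.isDegenerate(h)) return(NA_real_)
  cnt <- as.numeric(h@counts)
  nz <- which(cnt > 0L)
  lo <- nz[1] - 1L; hi <- nz[length(nz)] - 1L      # 0-based bin indices
  pk <- which.max(cnt) - 1L
  # take the longer tail; mirror the left-tail case onto the right
  if ((hi - pk) >= (pk - lo)) { a <- pk; b <- hi } else { a <- pk; b <- lo }
  if (a == b) return(.splitToThreshold(a, h))
  ia <- seq(min(a, b), max(a, b))
  # perpendicular distance from (i, h_i) to the line (a, h_a) -- (b, h_b)
  d <- abs((cnt[b + 1L] - cnt[a + 1L]) * ia -
             (b - a) * cnt[ia + 1L] +
             b * cnt[a + 1L] - a * cnt[b + 1L])
  t <- ia[which.max(d)]
  .splitToThreshold(min(t, 254L), h)
}

.liThreshold <- function(h) {
  if (.isDegenerate(h)) return(NA_real_)
  v <- .binValues(h) + 1            # shift so log() is defined at 0
  cnt <- h@counts
  t <- sum(cnt * v) / sum(cnt)      # continuous threshold in shifted units
  for (i in 1:100) {
    bg <- v <= t
    if (all(bg) || !any(bg)) break
    mu0 <- sum(cnt[bg] * v[bg]) / sum(cnt[bg])
    mu1 <- sum(cnt[!bg] * v[!bg]) / sum(cnt[!bg])
    tNew <- (mu0 - mu1) / (log(mu0) - log(mu1))
    if (!is.finite(tNew) || abs(tNew - t) < 0.5) { t <- tNew; break }
    t <- tNew
  }
  split <- max(0L, min(254L, floor((t - 1) / h@binWidth)))
  .splitToThreshold(split, h)
}

.yenThreshold <- function(h) {
  if (.isDegenerate(h)) return(NA_real_)
  p <- h@counts / sum(h@counts)
  P <- cumsum(p)
  S0 <- cumsum(p^2)
  S1 <- sum(p^2) - S0
  t <- 0:254
  P0 <- P[t + 1L]
  valid <- P0 > 0 & P0 < 1 & S0[t + 1L] > 0 & S1[t + 1L] > 0
  crit <- ifelse(valid,
                 -log(S0[t + 1L] * S1[t + 1L]) + 2 * log(P0 * (1 - P0)),
                 -Inf)
  if (all(!valid)) return(NA_real_)
  .splitToThreshold(t[which.max(crit)], h)
}

.thresholdMethods <- c("otsu", "mean", "isodata", "triangle", "li", "yen")

#' Classic histogram thresholding methods
#'
#' A suite of automatic threshold selectors spanning the clustering
#' (otsu, isodata), statistical (mean, triangle) and entropy (li, yen)
#' families, used to compare binarization behaviour on spots of varying
#' brightness and background. All share one convention: pixels with value
#' greater than the returned threshold are foreground; ties are broken by
#' the smallest maximizing threshold; a degenerate (single-bin) histogram
#' yields `NA`.
#'
#' @param h an [IntensityHistogram-class].
#' @param method one of `"otsu"`, `"mean"`, `"isodata"`, `"triangle"`,
#'   `"li"`, `"yen"`.
#' @return threshold on the intensity scale, or `NA_real_` (degenerate).
#' @seealso [otsuThreshold()], [runCompareMethods()]
#' @export
thresholdSuite <- function(h, method = "otsu") {
  stopifnot(is(h, "IntensityHistogram"))
  if (length(method) != 1L || !method %in% .thresholdMethods)
    stop("unknown thresholding method '", method, "'; available: ",
         paste(.thresholdMethods, collapse = ", "))
  switch(method,
         otsu = otsuThreshold(h),
         mean = .meanThreshold(h),
         isodata = .isodataThreshold(h),
         triangle = .triangleThreshold(h),
         li = .liThreshold(h),
         yen = .yenThreshold(h))
}

#' List the available thresholding methods
#' @return character vector of method names accepted by [thresholdSuite()].
#' @export
thresholdMethods <- function() .thresholdMethods

.maskFromThreshold <- function(px, thr, method) {
  if (is.na(thr)) {
    new("BinaryMask", mask = matrix(FALSE, nrow(px), ncol(px)),
        threshold = NA_real_, method = method,
        flags = c("degenerate", "empty"))
  } else {
    new("BinaryMask", mask = px > thr, threshold = thr, method = method)
  }
}

#' Global thresholding of a whole image
#'
#' One threshold is computed from the whole-image histogram and applied
#' everywhere. On images with a strong or non-uniform background this is
#' the failure mode that loses faint spots: the global threshold sits
#' above faint-spot intensities in the darker regions.
#'
#' @param img a greyscale [RasterImage-class].
#' @param method thresholding method name (see [thresholdSuite()]).
#' @return a [BinaryMask-class] covering the full image. A degenerate
#'   (constant) image yields an all-background mask flagged
#'   `"degenerate"`.
#' @seealso [binarizeLocal()]
#' @export
binarizeGlobal <- function(img, method = "otsu") {
  stopifnot(is(img, "RasterImage"))
  if (isColour(img)) stop("binarizeGlobal expects a greyscale image")
  px <- pixelData(img)
  thr <- thresholdSuite(buildHistogram(px, bitDepth(img)), method)
  m <- .maskFromThreshold(px, thr, method)
  if ("degenerate" %in% m@flags)
    warning("degenerate histogram: whole image is a single intensity bin")
  m
}

#' Local (per-cell) thresholding
#'
#' The production path: a threshold is computed and applied independently
#' within each grid cell, so each spot is segmented against its own local
#' background. A cell is declared empty (all-background mask flagged
#' `"empty"`) when its histogram is degenerate, when its foreground would
#' be smaller than `minArea` pixels, or when the foreground-background
#' contrast fails the local detection limit: any histogram threshold
#' splits even pure noise into two "classes", so a putative spot must
#' exceed `minContrast` standard deviations of the cell's background
#' pixels (default 3, the conventional 3-sigma detection limit) to count
#' as real.
#'
#' @param img a greyscale [RasterImage-class].
#' @param cells data.frame from [makeGrid()].
#' @param method thresholding method name (see [thresholdSuite()]).
#' @param minArea minimum foreground pixel count for a cell to count as
#'   containing a spot (default 4).
#' @param minContrast detection limit in background-sd units (default 3);
#'   set to 0 to disable.
#' @return a list of [BinaryMask-class], one per cell, in row-major cell
#'   order.
#' @seealso [binarizeGlobal()], [quantifyArray()]
#' @export
binarizeLocal <- function(img, cells, method = "otsu", minArea = 4L,
                          minContrast = 3) {
  stopifnot(is(img, "RasterImage"))
  if (isColour(img)) stop("binarizeLocal expects a greyscale image")
  lapply(seq_len(nrow(cells)), function(k) {
    px <- cellPixels(img, cells[k, ])
    thr <- thresholdSuite(buildHistogram(px, bitDepth(img)), method)
    m <- .maskFromThreshold(px, thr, method)
    nFg <- sum(m@mask)
    empty <- !is.na(m@threshold) && nFg < minArea
    if (!empty && !is.na(m@threshold) && minContrast > 0 &&
        nFg > 0L && nFg < length(px)) {
      bg <- px[!m@mask]
      sdBg <- if (length(bg) > 1L) stats::sd(bg) else 0
      empty <- (mean(px[m@mask]) - mean(bg)) < minContrast * sdBg
    }
    if (empty) {
      m@mask[] <- FALSE
      m@flags <- unique(c(m@flags, "empty"))
    }
    m
  })
}

#' @rdname maskData
#' @export
setMethod("maskData", "BinaryMask", function(mask) mask@mask)

#' @rdname thresholdUsed
#' @export
setMethod("thresholdUsed", "BinaryMask", function(mask) mask@threshold)

#' Count grid cells containing a detected spot
#'
#' A cell counts as a detection when at least `minArea` of its pixels are
#' foreground. Accepts either the per-cell mask list from
#' [binarizeLocal()] or a whole-image [BinaryMask-class] from
#' [binarizeGlobal()] (counted per cell via `cells`).
#'
#' @param masks list of [BinaryMask-class] or a single whole-image mask.
#' @param cells data.frame from [makeGrid()]; required for a whole-image
#'   mask.
#' @param minArea minimum foreground pixel count (default 4).
#' @return integer number of cells with a detected spot.
#' @export
countDetections <- function(masks, cells = NULL, minArea = 4L) {
  if (is(masks, "BinaryMask")) {
    if (is.null(cells))
      stop("'cells' is required to count detections in a whole-image mask")
    full <- maskData(masks)
    hits <- vapply(seq_len(nrow(cells)), function(k) {
      c <- cells[k, ]
      sum(full[(c$y0 + 1L):c$y1, (c$x0 + 1L):c$x1]) >= minArea
    }, logical(1))
    return(sum(hits))
  }
  sum(vapply(masks, function(m) sum(maskData(m)) >= minArea, logical(1)))
}
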