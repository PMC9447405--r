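# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' The 31-condition antigen dilution layout
#'
#' The default antigen-array layout: six analytes, each printed as a
#' five-step two-fold dilution series (CENP-B 50 to 3.125, Cytokeratin-6
#' 12.5 to 0.78125, GPC 12.5 to 0.78125, P2 100 to 6.25, Proteoglycan 50
#' to 3.125, and positive-control IgG 50 to 3.125 ug/mL), plus a PBS
#' negative control — 31 distinct analyte/concentration conditions. The
#' entries fill a 4 x 8 grid row-major; the 32nd position carries a
#' second PBS replicate so every grid position is covered exactly once.
#'
#' @return data.frame with columns `row`, `col` (1-based), `analyte`,
#'   `concentration` (ug/mL; 0 for PBS), `replicate`.
#' @export
defaultAntigenLayout <- function() {
  series <- function(analyte, top) {
    data.frame(analyte = analyte, concentration = top / 2^(0:4))
  }
  cond <- rbind(series("CENP-B", 50), series("Cytokeratin-6", 12.5),
                series("GPC", 12.5), series("P2", 100),
                series("Proteoglycan", 50), series("IgG", 50),
                data.frame(analyte = "PBS", concentration = 0))
  cond$replicate <- 1L
  pad <- data.frame(analyte = "PBS", concentration = 0, replicate = 2L)
  lay <- rbind(cond, pad)
  lay$row <- (seq_len(nrow(lay)) - 1L) %/% 8L + 1L
  lay$col <- (seq_len(nrow(lay)) - 1L) %% 8L + 1L
  lay[, c("row", "col", "analyte", "concentration", "replicate")]
}

#' Map analyte concentration to fluorescence amplitude
#'
#' Saturating binding-curve signal model: amplitude
#' `a = 0.9 * (2^bitDepth - 1) * c / (c + K)`. Strictly monotone in
#' concentration, zero at zero, and bounded by 90% of the bit-depth
#' maximum so default spots stay unsaturated.
#'
#' @param conc concentration(s), same units as `K`.
#' @param bitDepth image bit depth (default 8).
#' @param K half-saturation constant (default 25, the ug/mL scale of the
#'   antigen layout).
#' @return amplitude(s) in grey levels.
#' @export
amplitudeFromConcentration <- function(conc, bitDepth = 8L, K = 25) {
  0.9 * (2^bitDepth - 1) * conc / (conc + K)
}

#' Construct a SyntheticSpec
#'
#' @param layout layout data.frame (see [defaultAntigenLayout()]).
#' @param amplitudes true per-spot amplitudes; by default derived from
#'   `layout$concentration` via [amplitudeFromConcentration()].
#' @param cellSize cell side in pixels (default 40).
#' @param spotRadiusRange min/max spot radius in pixels (default 8-12).
#' @param shape `"disc"`, `"ellipse"` or `"blob"` (irregular outline).
#' @param psfSigma Gaussian edge blur sigma in pixels (default 0.8, a
#'   sub-pixel edge spread typical of a focused array scanner; 0 renders
#'   hard-edged spots).
#' @param background list: `type` (`"uniform"`, `"linear"`,
#'   `"quadratic"`), `base` grey level, `amplitude` grey levels of
#'   spatial variation.
#' @param noiseSigma additive Gaussian noise sd (default 2).
#' @param bitDepth 8 or 16 (default 8).
#' @param seed integer RNG seed; fixes the rendering bit-for-bit.
#' @return a [SyntheticSpec-class].
#' @export
arraySpec <- function(layout = defaultAntigenLayout(), amplitudes = NULL,
                      cellSize = 40L, spotRadiusRange = c(8, 12),
                      shape = "disc", psfSigma = 0.8,
                      background = list(type = "uniform", base = 20,
                                        amplitude = 0),
                      noiseSigma = 2, bitDepth = 8L, seed = 1L) {
  if (is.null(amplitudes))
    amplitudes <- amplitudeFromConcentration(layout$concentration,
                                             bitDepth = bitDepth)
  new("SyntheticSpec", layout = layout, cellSize = as.integer(cellSize),
      spotRadiusRange = as.numeric(spotRadiusRange), shape = shape,
      psfSigma = psfSigma, background = background,
      noiseSigma = noiseSigma, amplitudes = as.numeric(amplitudes),
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))
}

.backgroundField <- function(bg, H, W) {
  switch(bg$type,
    uniform = matrix(bg$base, H, W),
    linear = {
      # left-to-right gradient spanning `amplitude` grey levels
      g <- if (W > 1) (seq_len(W) - 1) / (W - 1) else 0
      matrix(bg$base, H, W) + matrix(bg$amplitude * g, H, W, byrow = TRUE)
    },
    quadratic = {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      r2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)
      bg$base + bg$amplitude * r2 / max(r2)
    })
}

#' @rdname renderArray
#' @export
setMethod("renderArray", "SyntheticSpec", function(spec) {
  lay <- spec@layout
  nr <- max(lay$row); nc <- max(lay$col)
  cs <- spec@cellSize
  H <- nr * cs; W <- nc * cs
  mx <- 2^spec@bitDepth - 1
  # row-major cell order, matching makeGrid / quantifyArray output
  ord <- order(lay$row, lay$col)
  lay <- lay[ord, , drop = FALSE]
  amp <- spec@amplitudes[ord]
  .withSeed(spec@seed, {
    field <- .backgroundField(spec@background, H, W)
    masks <- vector("list", nrow(lay))
    yy <- matrix(seq_len(cs), cs, cs)          # within-cell coordinates
    xx <- matrix(seq_len(cs), cs, cs, byrow = TRUE)
    for (k in seq_len(nrow(lay))) {
      radius <- stats::runif(1, spec@spotRadiusRange[1],
                             spec@spotRadiusRange[2])
      jit <- stats::runif(2, -2, 2)
      ry2 <- stats::runif(1, spec@spotRadiusRange[1],
                          spec@spotRadiusRange[2])   # ellipse minor axis
      four <- stats::rnorm(6, 0, 1)                  # blob outline terms
      if (amp[k] <= 0) { masks[[k]] <- matrix(FALSE, cs, cs); next }
      cy <- (cs + 1) / 2 + jit[1]
      cx <- (cs + 1) / 2 + jit[2]
      dy <- yy - cy; dx <- xx - cx
      dist <- sqrt(dy^2 + dx^2)
      rim <- switch(spec@shape,
        disc = radius,
        ellipse = {
          # radial extent of the ellipse along each pixel's direction
          th <- atan2(dy, dx)
          (radius * ry2) / sqrt((ry2 * cos(th))^2 + (radius * sin(th))^2)
        },
        blob = {
          th <- atan2(dy, dx)
          mod <- 1 + 0.18 * (four[1] * cos(2 * th) + four[2] * sin(2 * th)) +
                     0.12 * (four[3] * cos(3 * th) + four[4] * sin(3 * th)) +
                     0.08 * (four[5] * cos(4 * th) + four[6] * sin(4 * th))
          pmin(pmax(radius * mod, 0.4 * radius), cs / 2 - 1)
        })
      profile <- if (spec@psfSigma > 0) {
        amp[k] * stats::pnorm((rim - dist) / spec@psfSigma)
      } else {
        amp[k] * (dist <= rim)          # hard-edged limit
      }
      y0 <- (lay$row[k] - 1L) * cs
      x0 <- (lay$col[k] - 1L) * cs
      field[y0 + seq_len(cs), x0 + seq_len(cs)] <-
        field[y0 + seq_len(cs), x0 + seq_len(cs)] + profile
      masks[[k]] <- dist <= rim
    }
    if (spec@noiseSigma > 0)
      field <- field + matrix(stats::rnorm(H * W, 0, spec@noiseSigma), H, W)
    img <- RasterImage(pmin(pmax(.roundHalfUp(field), 0), mx),
                       bitDepth = spec@bitDepth)
    truth <- data.frame(lay, true_amplitude = amp, row.names = NULL)
    list(image = img, truth = truth, masks = masks)
  })
})

#' Spec for the 70-spot gradient-background array
#'
#' A 7 x 10 array on a linear background gradient: 70 spot amplitudes
#' evenly spanning 15 to 220 grey levels (assigned to positions in a
#' seeded random order), background rising 40 grey levels left to right
#' from a base of 20, additive Gaussian noise sd 3, 8-bit. Several spot
#' amplitudes sit below the gradient amplitude, which is exactly the
#' regime where one global threshold loses faint spots while per-cell
#' thresholds retain them.
#'
#' @param seed integer seed (default 42).
#' @param shape spot shape (default `"disc"`).
#' @return a [SyntheticSpec-class].
#' @export
gradientArraySpec <- function(seed = 42L, shape = "disc") {
  lay <- expand.grid(col = 1:10, row = 1:7)[, c("row", "col")]
  lay$analyte <- sprintf("probe%02d", seq_len(70))
  lay$concentration <- NA_real_
  lay$replicate <- 1L
  amp <- seq(15, 220, length.out = 70)
  amp <- .withSeed(seed + 1000L, sample(amp))   # scatter faint spots
  arraySpec(layout = lay, amplitudes = amp, shape = shape,
            background = list(type = "linear", base = 20, amplitude = 40),
            noiseSigma = 3, seed = seed)
}

#' Spec for the five-replicate CD14-style panel
#'
#' An antibody-array style panel: ten conditions in columns — a six-step
#' two-fold dilution standard series (500 down to 15.625 ng/mL) plus two
#' high "LN-like" and two low "HC-like" serum levels — each spotted in
#' five replicates (rows). Uniform background (base 20), noise sd 2,
#' 8-bit; amplitudes follow the saturating binding curve with
#' half-saturation 100 ng/mL, so LN-like mean amplitude exceeds HC-like
#' by construction.
#'
#' @param seed integer seed (default 7).
#' @return a [SyntheticSpec-class].
#' @export
cd14PanelSpec <- function(seed = 7L) {
  cond <- data.frame(
    analyte = c(sprintf("standard%d", 1:6), "LN-1", "LN-2", "HC-1", "HC-2"),
    concentration = c(500 / 2^(0:5), 300, 350, 30, 45))
  lay <- expand.grid(row = 1:5, col = 1:10)
  lay$analyte <- cond$analyte[lay$col]
  lay$concentration <- cond$concentration[lay$col]
  lay$replicate <- lay$row
  arraySpec(layout = lay[, c("row", "col", "analyte", "concentration",
                             "replicate")],
            amplitudes = amplitudeFromConcentration(
              cond$concentration[lay$col], K = 100),
            background = list(type = "uniform", base = 20, amplitude = 0),
            noiseSigma = 2, seed = seed)
}

#' Render the CD14-style replicate panel
#'
#' @param seed integer seed (default 7).
#' @return as [renderArray()]: list(`image`, `truth`, `masks`).
#' @export
renderCd14Panel <- function(seed = 7L) renderArray(cd14PanelSpec(seed))

#' Write a rendered synthetic array to disk
#'
#' Writes the image (TIFF or PNG by extension) and its ground-truth table
#' (`<prefix>_truth.csv`: row, col, analyte, concentration, replicate,
#' true_amplitude).
#'
#' @param rendered list from [renderArray()].
#' @param imagePath output image path (`.tif`/`.tiff`/`.png`).
#' @return character vector of the two paths written, invisibly.
#' @export
writeSyntheticArray <- function(rendered, imagePath) {
  writeArrayImage(rendered$image, imagePath)
  truthPath <- paste0(tools::file_path_sans_ext(imagePath), "_truth.csv")
  utils::write.csv(rendered$truth, truthPath, row.names = FALSE, quote = FALSE)
  invisible(c(imagePath, truthPath))
}
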