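test_that("background estimation is the median of background-labelled pixels", {
  px <- squareSpotCell(20L, bg = 20, amp = 180)
  mask <- binarizeLocal(RasterImage(px, 8L),
                        makeGrid(RasterImage(px, 8L), GridSpec(1, 1)))[[1]]
  expect_equal(estimateBackground(px, mask), 20)

  # ramp background 10..30: median of the generated values
  ramp <- matrix(rep(seq(10, 30, length.out = 21), each = 21), 21, 21)
  ramp <- round(ramp)
  mAll <- new("BinaryMask", mask = matrix(FALSE, 21, 21),
              threshold = 255, method = "otsu")
  expect_equal(estimateBackground(ramp, mAll), median(round(seq(10, 30,
               length.out = 21))))

  mFull <- new("BinaryMask", mask = matrix(TRUE, 21, 21),
               threshold = 0, method = "otsu")
  expect_warning(bg <- estimateBackground(ramp, mFull), "foreground")
  expect_equal(bg, min(ramp))
})

test_that("spot measurement: net = fg mean - background, clipped at zero", {
  px <- squareSpotCell(20L, bg = 20, amp = 180)
  img <- RasterImage(px, 8L)
  mask <- binarizeLocal(img, makeGrid(img, GridSpec(1, 1)))[[1]]
  ms <- measureSpot(px, mask, estimateBackground(px, mask))
  expect_equal(ms$net_intensity, 180)
  expect_equal(ms$fg_mean, 200)
  expect_equal(ms$fg_area, sum(px == 200))
  expect_equal(ms$fg_sum, 180 * sum(px == 200))
  expect_equal(ms$flags, "")
})

test_that("empty cells yield all-zero measurements flagged empty", {
  px <- matrix(20, 20, 20)
  mask <- new("BinaryMask", mask = matrix(FALSE, 20, 20),
              threshold = NA_real_, method = "otsu",
              flags = c("degenerate", "empty"))
  ms <- measureSpot(px, mask, 20)
  expect_equal(ms$net_intensity, 0)
  expect_equal(ms$fg_area, 0L)
  expect_match(ms$flags, "empty")
})

test_that("saturation and edge contact are flagged", {
  px <- squareSpotCell(20L, bg = 20, amp = 235)   # spot pixels at 255
  img <- RasterImage(px, 8L)
  mask <- binarizeLocal(img, makeGrid(img, GridSpec(1, 1)))[[1]]
  ms <- measureSpot(px, mask, 20, bitDepth = 8L)
  expect_match(ms$flags, "saturated")

  pxe <- matrix(20, 20, 20); pxe[1:6, 1:6] <- 200   # touches the border
  imge <- RasterImage(pxe, 8L)
  maske <- binarizeLocal(imge, makeGrid(imge, GridSpec(1, 1)))[[1]]
  mse <- measureSpot(pxe, maske, 20)
  expect_match(mse$flags, "edge_clipped")
})

test_that("irregular blob spots on a ramp background recover their amplitude", {
  lay <- data.frame(row = 1L, col = 1L, analyte = "x",
                    concentration = NA_real_, replicate = 1L)
  spec <- arraySpec(layout = lay, amplitudes = 100, shape = "blob",
                    background = list(type = "linear", base = 15,
                                      amplitude = 10),
                    noiseSigma = 1, seed = 99L)
  r <- renderArray(spec)
  tab <- quantifyArray(r$image, GridSpec(1, 1))
  expect_lt(abs(tab$net_intensity - 100) / 100, 0.10)
})

test_that("quantifyArray is a row-major, deterministic composition of per-cell measurement", {
  r <- renderArray(gradientArraySpec(seed = 42L))
  t1 <- quantifyArray(r$image, GridSpec(7, 10))
  t2 <- quantifyArray(r$image, GridSpec(7, 10))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 70L)
  expect_equal(t1$row, rep(1:7, each = 10))
  expect_equal(t1$col, rep(1:10, times = 7))

  # 1 x 1 grid equals a direct whole-image measurement
  px <- squareSpotCell(40L, bg = 20, amp = 150)
  img <- RasterImage(px, 8L)
  whole <- quantifyArray(img, GridSpec(1, 1))
  mask <- binarizeLocal(img, makeGrid(img, GridSpec(1, 1)))[[1]]
  direct <- measureSpot(px, mask, estimateBackground(px, mask))
  expect_equal(whole$net_intensity, direct$net_intensity)
  expect_equal(whole$fg_area, direct$fg_area)
})

test_that("adding a constant offset leaves net intensities unchanged", {
  r <- renderArray(arraySpec(seed = 11L))
  px <- pixelData(r$image)
  expect_lte(max(px) + 25, 255)   # the shifted image must not saturate
  shifted <- RasterImage(px + 25, 8L)
  t0 <- quantifyArray(r$image, GridSpec(4, 8))
  t1 <- quantifyArray(shifted, GridSpec(4, 8))
  expect_true(all(abs(t0$net_intensity - t1$net_intensity) <= 1))
})

test_that("net intensity rises monotonically along every dilution series", {
  r <- renderArray(arraySpec(seed = 11L))
  tab <- merge(quantifyArray(r$image, GridSpec(4, 8)), r$truth,
               by = c("row", "col"))
  for (an in setdiff(unique(tab$analyte), "PBS")) {
    sub <- tab[tab$analyte == an, ]
    sub <- sub[order(sub$concentration), ]
    expect_true(all(diff(sub$net_intensity) > 0), label = an)
  }
  # negative controls stay dark
  expect_true(all(tab$net_intensity[tab$analyte == "PBS"] < 5))
})

test_that("local-mode quantification beats global mode on a gradient background", {
  r <- renderArray(gradientArraySpec(seed = 42L))
  err <- function(mode) {
    tab <- merge(quantifyArray(r$image, GridSpec(7, 10), mode = mode),
                 r$truth, by = c("row", "col"))
    mean(abs(tab$net_intensity - tab$true_amplitude))
  }
  expect_lt(err("local"), err("global"))
})
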