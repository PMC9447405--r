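test_that("Otsu picks the smallest maximizing split of a bimodal histogram", {
  h <- buildHistogram(c(rep(50, 100), rep(200, 100)))
  # any split in [50, 199] attains the maximal between-class variance
  expect_equal(otsuThreshold(h), 50)
  expect_equal(otsuThreshold(h), bruteForceOtsu(h@counts))
})

test_that("constant data is degenerate: no two-class split exists", {
  h <- buildHistogram(rep(42, 500))
  expect_true(is.na(otsuThreshold(h)))
  for (m in thresholdMethods())
    expect_true(is.na(thresholdSuite(h, m)))
})

test_that("Otsu matches the brute-force between-class-variance argmax", {
  set.seed(301)
  for (i in 1:60) {
    counts <- randomClusterHistogram()
    h <- new("IntensityHistogram", counts = counts, binWidth = 1L)
    expect_identical(otsuThreshold(h), bruteForceOtsu(counts))
  }
})

test_that("Otsu is invariant to uniform scaling of the histogram counts", {
  set.seed(302)
  for (i in 1:20) {
    counts <- randomClusterHistogram()
    h1 <- new("IntensityHistogram", counts = counts, binWidth = 1L)
    h5 <- new("IntensityHistogram", counts = counts * 5L, binWidth = 1L)
    expect_identical(otsuThreshold(h1), otsuThreshold(h5))
  }
})

test_that("suite methods match their defining computations on hand cases", {
  hm <- buildHistogram(c(0, 0, 100, 100))
  expect_equal(thresholdSuite(hm, "mean"), 50)   # floor of the pixel mean

  hb <- buildHistogram(c(rep(50, 100), rep(200, 100)))
  # isodata: t = (mu0 + mu1) / 2 = 125 is the fixed point
  expect_equal(thresholdSuite(hb, "isodata"), 125)
  # dispatch identity
  expect_identical(thresholdSuite(hb, "otsu"), otsuThreshold(hb))

  expect_error(thresholdSuite(hb, "banana"), "otsu, mean, isodata")
})

test_that("every suite method separates two well-spread classes", {
  set.seed(303)
  px <- c(round(rnorm(1500, 40, 5)), round(rnorm(500, 200, 5)))
  px <- pmin(pmax(px, 0), 255)
  h <- buildHistogram(px)
  for (m in thresholdMethods()) {
    t <- thresholdSuite(h, m)
    expect_false(is.na(t))
    expect_gt(t, 40)    # above the background mode centre
    expect_lt(t, 200)   # below the foreground mode centre
  }
})

test_that("foreground shrinks monotonically as the threshold rises", {
  set.seed(304)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  counts <- vapply(0:255, function(t) sum(px > t), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("16-bit data is binned into 256 bins and thresholds return on the 16-bit scale", {
  px <- c(rep(1000, 100), rep(60000, 100))
  h <- buildHistogram(px, bitDepth = 16L)
  expect_equal(h@binWidth, 256L)
  t <- otsuThreshold(h)
  expect_true(t > 1000 && t < 60000)
  expect_equal(t %% 256, 255)   # upper edge of the chosen bin
})

test_that("global binarization finds bright spots on a uniform background", {
  px <- squareSpotCell(40L, bg = 20, amp = 200)
  img <- RasterImage(px, 8L)
  m <- binarizeGlobal(img)
  expect_true(all(maskData(m)[px == 220]))
  expect_false(any(maskData(m)[px == 20]))

  expect_warning(mc <- binarizeGlobal(RasterImage(matrix(7, 10, 10), 8L)),
                 "degenerate")
  expect_false(any(maskData(mc)))
  expect_true("empty" %in% mc@flags)
})

test_that("local thresholding flags noise-only and uniform cells empty", {
  set.seed(305)
  # negative-control cell: pure Gaussian noise, no spot. A histogram
  # threshold still splits the noise in two, but the split fails the
  # 3-sigma contrast detection limit.
  px <- matrix(20, 40, 80)
  px[, 1:40] <- pmin(pmax(round(rnorm(1600, 20, 2)), 0), 255)
  img <- RasterImage(px, 8L)
  cells <- makeGrid(img, GridSpec(1, 2))
  masks <- binarizeLocal(img, cells)
  expect_true("empty" %in% masks[[1]]@flags)
  expect_equal(sum(maskData(masks[[1]])), 0L)
  # uniform cell: degenerate histogram
  expect_true("empty" %in% masks[[2]]@flags)
  expect_true(is.na(thresholdUsed(masks[[2]])))
  # a zero-amplitude spot from the generator behaves the same way
  lay <- data.frame(row = 1L, col = 1L, analyte = "PBS",
                    concentration = 0, replicate = 1L)
  r <- renderArray(arraySpec(layout = lay, noiseSigma = 2, seed = 44L))
  mNeg <- binarizeLocal(r$image, makeGrid(r$image, GridSpec(1, 1)))[[1]]
  expect_true("empty" %in% mNeg@flags)
})

test_that("local mode with a 1 x 1 grid is pixel-identical to global mode", {
  set.seed(306)
  r <- renderArray(arraySpec(seed = 306L))
  img <- r$image
  cells <- makeGrid(img, GridSpec(1, 1))
  loc <- binarizeLocal(img, cells, minArea = 0L)[[1]]
  glo <- binarizeGlobal(img)
  expect_identical(maskData(loc), maskData(glo))
  expect_identical(thresholdUsed(loc), thresholdUsed(glo))
})

test_that("a global threshold loses faint spots on a gradient background but local keeps all", {
  r <- renderArray(gradientArraySpec(seed = 42L))
  cells <- makeGrid(r$image, GridSpec(7, 10))
  nLocal <- countDetections(binarizeLocal(r$image, cells), minArea = 4L)
  nGlobal <- countDetections(binarizeGlobal(r$image), cells, minArea = 4L)
  expect_equal(nLocal, 70L)
  expect_lt(nGlobal, 70L)
  # the misses are faint spots: every missed amplitude below the gradient span
  full <- maskData(binarizeGlobal(r$image))
  missed <- vapply(seq_len(70), function(k) {
    c <- cells[k, ]
    sum(full[(c$y0 + 1):c$y1, (c$x0 + 1):c$x1]) < 4L
  }, logical(1))
  expect_true(all(r$truth$true_amplitude[missed] < 150))
})
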