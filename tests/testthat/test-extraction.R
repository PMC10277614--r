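# Metadata-only pyramid for pure level-selection arithmetic.
bigPyramid <- function() {
  new("SlidePyramid", sourcePath = "<memory>", levelCount = 4L,
      levelDims = cbind(width = c(80000L, 20000L, 5000L, 1250L),
                        height = c(60000L, 15000L, 3750L, 938L)),
      levelDownsamples = c(1, 4, 16, 64), mpp = c(0.25, 0.25),
      vendor = "synthetic")
}

test_that("chooseLevel picks the finest level fitting the target", {
  sl <- bigPyramid()
  ext <- RegionL0(0, 0, 80000, 60000)
  expect_equal(chooseLevel(sl, ext, 2000L), 3L)    # 1250 <= 2000; 5000 > 2000
  expect_equal(chooseLevel(sl, ext, 10000L), 2L)   # downsample 16
  expect_equal(chooseLevel(sl, ext, 200000L), 0L)  # larger than level 0
  # monotone: larger target never yields a coarser level
  targets <- c(100L, 500L, 2000L, 10000L, 90000L)
  lv <- vapply(targets, function(t) chooseLevel(sl, ext, t), 0L)
  expect_true(all(diff(lv) <= 0))
})

test_that("computeScaleBar picks nice lengths by log-distance inside the width window", {
  b1 <- computeScaleBar(4.0, 1250L, 0.25)
  expect_equal(b1@lengthUm, 1000)
  expect_equal(b1@lengthPx, 250L)
  expect_equal(b1@label, "1.0 mm")
  b2 <- computeScaleBar(0.25, 1000L, 0.25)
  expect_equal(b2@lengthUm, 50)
  expect_equal(b2@lengthPx, 200L)
  expect_equal(b2@label, "50 µm")
  # 500 µm would be 50% of the width: excluded by the <= 0.40 window
  b3 <- computeScaleBar(1.0, 1000L, 0.25)
  expect_equal(b3@lengthUm, 200)
  # log-distance tie-break between two in-window candidates
  b4 <- computeScaleBar(1.25, 1000L, 0.25)  # target 312.5 µm
  expect_equal(b4@lengthUm, 200)
  expect_equal(b4@lengthPx, 160L)
})

test_that("computeScaleBar agrees with brute-force candidate enumeration", {
  set.seed(42)
  for (i in 1:50) {
    u <- 10^stats::runif(1, -1, 1.2)
    w <- sample(200:3000, 1)
    bar <- computeScaleBar(u, w, 0.25)
    cand <- sort(c(1, 2, 5) * rep(10^(-1:6), each = 3))
    frac <- cand / u / w
    pool <- cand[frac >= 0.10 & frac <= 0.40]
    if (length(pool)) {
      target <- 0.25 * w * u
      expect_equal(bar@lengthUm, pool[which.min(abs(log(pool / target)))])
      expect_gte(bar@lengthPx / w, 0.10 - 1e-9)
      expect_lte(bar@lengthPx / w, 0.40 + 1e-2)
    }
  }
})

test_that("extractOverview hits the target size exactly, never upsamples, and carries a bar", {
  fx <- makeStandardSlide()
  bb <- truthBbox(fx$truth)           # 1250 x 750
  ov <- extractOverview(fx$slide, bb, targetPx = 500L)
  expect_equal(unname(imageDims(overviewRaster(ov))), c(500L, 300L))
  expect_equal(overviewDownsample(ov), 2.5)
  expect_false(is.null(overviewScaleBar(ov)))
  # crop smaller than the target at level 0: finest data returned unchanged
  ovSmall <- extractOverview(fx$slide, RegionL0(900, 700, 200, 100),
                             targetPx = 500L)
  expect_equal(unname(imageDims(overviewRaster(ovSmall))), c(200L, 100L))
  # rotation swaps output axes
  ovR <- extractOverview(fx$slide, bb, targetPx = 500L,
                         transform = Transform(rotate90 = 1L))
  expect_equal(unname(imageDims(overviewRaster(ovR))), c(300L, 500L))
})

test_that("a slide without calibration renders without a bar and warns", {
  dir <- withr::local_tempdir()
  spec <- SlideSpec(level0Dims = c(600, 400), downsamples = c(1, 4),
                    mpp = numeric(0),
                    tissueShapes = list(list(center = c(300, 200),
                                             semiAxes = c(200, 120),
                                             fillRgb = c(170, 80, 130))))
  p <- file.path(dir, "nocal.tiff")
  generateSlide(spec, p)
  sl <- openSlide(p)
  expect_warning(ov <- extractOverview(sl, RegionL0(100, 80, 400, 240),
                                       targetPx = 200L),
                 class = "calibrationMissingWarning")
  expect_null(overviewScaleBar(ov))
})

test_that("scale-bar physical truth holds on every rendered overview", {
  fx <- makeStandardSlide()
  for (target in c(200L, 333L, 500L)) {
    ov <- extractOverview(fx$slide, truthBbox(fx$truth), targetPx = target)
    bar <- overviewScaleBar(ov)
    umPerPx <- 0.25 * overviewDownsample(ov)
    expect_lte(abs(bar@lengthPx * umPerPx - bar@lengthUm), umPerPx)
    expect_true(bar@lengthUm %in% (c(1, 2, 5) * rep(10^(-1:6), each = 3)))
  }
})

test_that("inset physical-width arithmetic reads the forced level-0 window", {
  fx <- makeStandardSlide()
  # 250 µm at 0.25 µm/px -> 1000 level-0 px, window (500, 250, 1000, 1000)
  ins <- extractInset(fx$slide, roiCenter = c(1000, 750),
                      physicalWidthUm = 250, outPx = 250L)
  expect_match(ins@provenance, "(500,250,1000,1000)", fixed = TRUE)
  expect_equal(unname(imageDims(ins))[1], 250L)
  # 500 µm -> 2000 level-0 px
  dir <- withr::local_tempdir()
  spec <- SlideSpec(level0Dims = c(3000, 2400), downsamples = c(1, 4, 16),
                    mpp = c(0.25, 0.25),
                    tissueShapes = list(list(center = c(1500, 1200),
                                             semiAxes = c(1000, 800),
                                             fillRgb = c(170, 80, 130))))
  p <- file.path(dir, "mid.tiff")
  generateSlide(spec, p)
  ins2 <- extractInset(openSlide(p), roiCenter = c(1500, 1200),
                       physicalWidthUm = 500, outPx = 200L)
  expect_match(ins2@provenance, "(500,200,2000,2000)", fixed = TRUE)
  # calibration missing: physical width must error with the pixel-path hint
  spec@mpp <- numeric(0)
  p2 <- file.path(dir, "nocal.tiff")
  generateSlide(spec, p2)
  expect_error(extractInset(openSlide(p2), roiCenter = c(1500, 1200),
                            physicalWidthUm = 500),
               class = "calibrationMissingError")
  expect_equal(unname(imageDims(extractInset(openSlide(p2),
                                             roi = RegionL0(500, 200, 400, 400),
                                             outPx = 100L))),
               c(100L, 100L))
})

test_that("an inset covering the checkerboard ROI is pixel-identical to the oracle", {
  fx <- makeStandardSlide()
  # 62.5 µm at 0.25 µm/px -> exactly the 250-px checkerboard region
  ins <- extractInset(fx$slide, roiCenter = c(1000, 750),
                      physicalWidthUm = 62.5, outPx = 250L)
  want <- oracleCheckerboard(RegionL0(875, 625, 250, 250), 25,
                             c(40, 40, 40), c(210, 210, 80))
  expect_identical(imagePixels(ins), want)
})

test_that("transform group identities are pixel-exact", {
  fx <- makeStandardSlide()
  img <- readRegion(fx$slide, RegionL0(600, 400, 300, 200), 0L)
  r2 <- applyTransform(applyTransform(img, Transform(rotate90 = 1L)),
                       Transform(rotate90 = 1L))
  expect_identical(imagePixels(r2),
                   imagePixels(applyTransform(img, Transform(rotate90 = 2L))))
  r4 <- applyTransform(applyTransform(r2, Transform(rotate90 = 2L)),
                       Transform())
  expect_identical(imagePixels(r4), imagePixels(img))
  ff <- applyTransform(applyTransform(img, Transform(flipH = TRUE)),
                       Transform(flipH = TRUE))
  expect_identical(imagePixels(ff), imagePixels(img))
})

test_that("annotateRoi maps the rectangle through crop offset and downsample", {
  white <- RasterImage(array(255L, c(600L, 1000L, 3L)))
  ov <- new("OverviewImage", image = white, sourceLevel = 1L,
            effectiveDownsample = 5, crop = RegionL0(1500, 1500, 5000, 3000),
            transform = Transform(), scaleBar = NULL)
  ann <- annotateRoi(ov, RegionL0(3500, 2500, 1000, 1000))
  arr <- imagePixels(overviewRaster(ann))
  # rect at (400, 200), 200 x 200, stroke 2 px drawn inside
  expect_equal(arr[201, 401, 1], 0L)
  expect_equal(arr[201, 600, 1], 0L)
  expect_equal(arr[400, 401, 1], 0L)
  expect_equal(arr[300, 500, 1], 255L)    # interior untouched
  expect_equal(arr[100, 100, 1], 255L)    # outside untouched
  # input object unmodified
  expect_true(all(imagePixels(overviewRaster(ov)) == 255L))
  # disjoint ROI: warning, image unchanged
  expect_warning(same <- annotateRoi(ov, RegionL0(0, 0, 100, 100)),
                 class = "roiDisjointWarning")
  expect_identical(imagePixels(overviewRaster(same)),
                   imagePixels(overviewRaster(ov)))
})

test_that("annotation commutes with rotation (corner-mapping oracle)", {
  fx <- makeStandardSlide()
  base <- extractOverview(fx$slide, truthBbox(fx$truth), targetPx = 400L,
                          withScaleBar = FALSE)
  roi <- RegionL0(875, 625, 250, 250)
  annThenRot <- applyTransform(overviewRaster(annotateRoi(base, roi)),
                               Transform(rotate90 = 1L))
  rot <- extractOverview(fx$slide, truthBbox(fx$truth), targetPx = 400L,
                         transform = Transform(rotate90 = 1L),
                         withScaleBar = FALSE)
  rotThenAnn <- overviewRaster(annotateRoi(rot, roi))
  expect_identical(imagePixels(annThenRot), imagePixels(rotThenAnn))
})

test_that("overview ROI interior and inset agree in mean colour", {
  fx <- makeStandardSlide()
  roi <- RegionL0(875, 625, 250, 250)
  ov <- annotateRoi(extractOverview(fx$slide, truthBbox(fx$truth),
                                    targetPx = 500L, withScaleBar = FALSE), roi)
  eff <- overviewDownsample(ov)
  arr <- imagePixels(overviewRaster(ov))
  x0 <- round((875 - 375) / eff); y0 <- round((625 - 375) / eff)
  side <- round(250 / eff)
  interior <- arr[(y0 + 4):(y0 + side - 3), (x0 + 4):(x0 + side - 3), ,
                  drop = FALSE]
  ins <- extractInset(fx$slide, roiCenter = c(1000, 750),
                      physicalWidthUm = 62.5, outPx = 250L)
  for (ch in 1:3)
    expect_lte(abs(mean(interior[, , ch]) - mean(imagePixels(ins)[, , ch])), 5)
})

test_that("renderOverview appends a margin band and never draws the bar over tissue", {
  fx <- makeStandardSlide()
  ov <- extractOverview(fx$slide, truthBbox(fx$truth), targetPx = 500L)
  tissueH <- dim(imagePixels(overviewRaster(ov)))[1]
  rendered <- renderOverview(ov)
  rd <- dim(imagePixels(rendered))
  expect_gt(rd[1], tissueH)
  expect_identical(imagePixels(rendered)[1:tissueH, , ],
                   imagePixels(overviewRaster(ov)))
  band <- imagePixels(rendered)[(tissueH + 1):rd[1], , ]
  expect_true(any(band == 0L))   # bar and label drawn in the band
})
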