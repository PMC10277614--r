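# Shared fixtures and independent oracles. Oracles are deliberately written
# with different arithmetic than the package code paths they check.

# Independent rasterisation of a checkerboard window at level 0: pixel with
# 0-based global column gx has centre gx + 0.5; parity of the period cell
# indices picks colour A or B. Returns an H x W x 3 integer array.
oracleCheckerboard <- function(region, periodPx, rgbA, rgbB) {
  gx <- region@x + seq_len(region@w) - 1L
  gy <- region@y + seq_len(region@h) - 1L
  px <- floor((gx + 0.5 - region@x) / periodPx)
  py <- floor((gy + 0.5 - region@y) / periodPx)
  parity <- outer(py, px, "+") %% 2
  arr <- array(0, c(region@h, region@w, 3L))
  for (ch in 1:3) arr[, , ch] <- ifelse(parity == 0, rgbA[ch], rgbB[ch])
  storage.mode(arr) <- "integer"
  arr
}

# Independent ellipse mask at an arbitrary scale: TRUE where the pixel
# centre (in level-0 coordinates) lies inside the ellipse.
oracleEllipseMask <- function(W, H, downsample, center, semiAxes) {
  xs <- (seq_len(W) - 0.5) * downsample
  ys <- (seq_len(H) - 0.5) * downsample
  outer(((ys - center[2]) / semiAxes[2])^2,
        ((xs - center[1]) / semiAxes[1])^2, "+") <= 1
}

# Hand computation of the Pearson chi-square statistic on a 2x2 table.
oracleChi2 <- function(k1, n1, k2, n2) {
  O <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Standard test slide: one ellipse, known bbox (375, 375, 1250, 750),
# checkerboard ROI at (875, 625, 250, 250) with period 25 px, mpp 0.25.
standardSpec <- function(noiseSd = 0) {
  SlideSpec(
    level0Dims = c(2000L, 1500L), downsamples = c(1, 4, 16),
    mpp = c(0.25, 0.25),
    tissueShapes = list(list(center = c(1000, 750), semiAxes = c(625, 375),
                             fillRgb = c(170, 80, 130))),
    roiPattern = list(region = RegionL0(875, 625, 250, 250),
                      kind = "checkerboard", periodPx = 25,
                      rgbA = c(40, 40, 40), rgbB = c(210, 210, 80)),
    noiseSd = noiseSd)
}

makeStandardSlide <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "standard.tiff")
  truth <- generateSlide(standardSpec(), path)
  list(path = path, truth = truth, slide = openSlide(path))
}

# Random valid slide spec for property tests; geometry only (no noise),
# sizes kept moderate so a full property sweep stays fast.
randomSpec <- function() {
  w0 <- sample(700:1400, 1)
  h0 <- sample(500:1100, 1)
  nShapes <- sample(1:3, 1)
  shapes <- lapply(seq_len(nShapes), function(i) {
    a <- sample(round(w0 * 0.10):round(w0 * 0.28), 1)
    b <- sample(round(h0 * 0.10):round(h0 * 0.28), 1)
    cx <- sample(a:(w0 - a), 1)
    cy <- sample(b:(h0 - b), 1)
    hue <- sample(1:3, 1)
    base <- switch(hue, c(170, 80, 130), c(150, 90, 40), c(70, 60, 140))
    list(center = c(cx, cy), semiAxes = c(a, b),
         fillRgb = pmax(0, pmin(255, base + sample(-20:20, 3, replace = TRUE))))
  })
  SlideSpec(level0Dims = c(w0, h0), downsamples = c(1, 4, 16),
            mpp = c(0.25, 0.25), tissueShapes = shapes)
}

expectRegionEqual <- function(a, b) {
  expect_equal(c(regionX(a), regionY(a), regionW(a), regionH(a)),
               c(regionX(b), regionY(b), regionW(b), regionH(b)))
}
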