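#' Choose the pyramid level for a target rendering size
#'
#' Returns the finest level (smallest downsample) whose rendering of
#' \code{extent} fits within \code{targetPx}; subsequent resampling is then
#' always downsampling. If even the coarsest level exceeds the target, the
#' coarsest level is returned.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param extent a \linkS4class{RegionL0}.
#' @param targetPx target maximum dimension in pixels (>= 64).
#' @return Integer level index (0-based).
#' @export
chooseLevel <- function(slide, extent, targetPx) {
  if (targetPx < 64L) soStop("targetPx must be >= 64", "parameterError")
  ext <- max(extent@w, extent@h)
  ok <- which(ext / slide@levelDownsamples <= targetPx)
  if (length(ok) == 0L) return(slide@levelCount - 1L)
  min(ok) - 1L
}

niceCandidatesUm <- function() {
  k <- rep(10^(-1:6), each = 3L)
  sort(c(1, 2, 5) * k)
}

#' Choose and size a physically calibrated scale bar
#'
#' Candidate lengths are the "nice" set \{1, 2, 5\} x 10^k microns. The
#' target physical length is \code{targetFrac} of the image width; among
#' candidates whose drawn width lies between 10\% and 40\% of the image, the
#' one minimising the log-distance to the target is chosen. If no candidate
#' satisfies the width window (pathological aspect ratios), the globally
#' nearest candidate is used and a warning is raised.
#'
#' @param umPerPx microns per pixel of the rendered image (> 0).
#' @param imageWidthPx rendered image width (>= 64).
#' @param targetFrac desired bar width as a fraction of the image (default
#'   0.25, which reproduces 1.0 mm bars on ~5 mm-wide tissue overviews).
#' @return A \linkS4class{ScaleBar}.
#' @examples
#' computeScaleBar(4.0, 1250)   # 1000 µm -> "1.0 mm", 250 px
#' computeScaleBar(0.25, 1000)  # 50 µm, 200 px
#' @export
computeScaleBar <- function(umPerPx, imageWidthPx, targetFrac = 0.25) {
  if (umPerPx <= 0) soStop("umPerPx must be > 0", "parameterError")
  if (imageWidthPx < 64L) soStop("imageWidthPx must be >= 64", "parameterError")
  target <- targetFrac * imageWidthPx * umPerPx
  cand <- niceCandidatesUm()
  frac <- cand / umPerPx / imageWidthPx
  inWindow <- frac >= 0.10 & frac <= 0.40
  if (any(inWindow)) {
    pool <- cand[inWindow]
  } else {
    soWarn("no nice scale-bar length fits the 10-40% width window; relaxing",
           "scaleBarWindowWarning")
    pool <- cand
  }
  lengthUm <- pool[which.min(abs(log(pool / target)))]
  label <- if (lengthUm >= 1000) sprintf("%.1f mm", lengthUm / 1000)
           else sprintf("%g µm", lengthUm)
  new("ScaleBar", lengthUm = lengthUm,
      lengthPx = as.integer(round(lengthUm / umPerPx)), label = label)
}

#' Extract a downsampled overview of a slide crop
#'
#' Reads \code{crop} at the level chosen by \code{\link{chooseLevel}},
#' area-average resamples so the maximum dimension equals \code{targetPx}
#' exactly (unless that would upsample, in which case the finest available
#' data is returned as-is), applies the orientation transform, and computes a
#' scale bar from the effective micron calibration when present. A slide
#' without calibration renders without a bar and warns — calibration is never
#' invented.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param crop a \linkS4class{RegionL0}; clamped to slide bounds.
#' @param targetPx target maximum output dimension (default 1000).
#' @param transform a \linkS4class{Transform}.
#' @param withScaleBar logical; request a scale bar.
#' @return An \linkS4class{OverviewImage}.
#' @export
extractOverview <- function(slide, crop, targetPx = 1000L,
                            transform = Transform(), withScaleBar = TRUE) {
  if (targetPx < 64L) soStop("targetPx must be >= 64", "parameterError")
  crop <- clampRegion(crop, slide@levelDims[1, ])
  if (is.null(crop)) soStop("crop is empty after clamping", "emptyRegionError")
  # coarsest level whose rendering of the crop is still >= targetPx, so the
  # exact-size step below only ever downsamples; a crop smaller than
  # targetPx at level 0 returns the finest available data (no upsampling)
  ext <- max(crop@w, crop@h)
  ok <- which(ext / slide@levelDownsamples >= targetPx)
  level <- if (length(ok)) max(ok) - 1L else 0L
  img <- readRegion(slide, crop, level)
  d <- dim(img@pixels)
  arr <- img@pixels
  if (max(d[1:2]) > targetPx) {
    s <- targetPx / max(d[1:2])
    if (d[1] >= d[2]) arr <- areaResample(arr, targetPx, max(1L, round(d[2] * s)))
    else arr <- areaResample(arr, max(1L, round(d[1] * s)), targetPx)
  }
  preW <- dim(arr)[2]; preH <- dim(arr)[1]
  eff <- crop@w / preW
  out <- applyTransform(RasterImage(arr, provenance = img@provenance), transform)
  bar <- NULL
  if (withScaleBar) {
    if (!hasMpp(slide)) {
      soWarn("slide has no micron calibration: overview rendered without scale bar",
             "calibrationMissingWarning")
    } else {
      # µm/px along the displayed x axis (source y axis after odd quarter turns)
      dispW <- dim(out@pixels)[2]
      dispUmPerPx <- if (transform@rotate90 %% 2L == 1L)
        slide@mpp[2] * (crop@h / preH) else slide@mpp[1] * eff
      bar <- computeScaleBar(dispUmPerPx, dispW)
    }
  }
  new("OverviewImage", image = out, sourceLevel = as.integer(level),
      effectiveDownsample = eff, crop = crop, transform = transform,
      scaleBar = bar)
}

#' Extract a high-magnification inset at a physical width
#'
#' The region of interest is specified either by its centre (level-0 pixels)
#' plus a physical width in microns — requiring calibration: for example
#' 250 um at 0.25 um/px reads a 1000 level-0-px window — or as an explicit
#' \linkS4class{RegionL0} when no calibration exists. The window is read at
#' the coarsest level still wider than \code{outPx} and area-averaged down to
#' exactly \code{outPx} wide.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param roiCenter numeric (x, y) level-0 centre of the ROI (with
#'   \code{physicalWidthUm}).
#' @param physicalWidthUm physical ROI width in microns; the inset is square
#'   in physical units on this call path.
#' @param roi alternative: explicit \linkS4class{RegionL0} (pixel units, no
#'   calibration needed).
#' @param outPx output width in pixels (>= 64).
#' @param transform a \linkS4class{Transform}.
#' @return A \linkS4class{RasterImage}.
#' @export
extractInset <- function(slide, roiCenter = NULL, physicalWidthUm = NULL,
                         roi = NULL, outPx = 256L, transform = Transform()) {
  if (outPx < 64L) soStop("outPx must be >= 64", "parameterError")
  if (is.null(roi)) {
    if (is.null(roiCenter) || is.null(physicalWidthUm))
      soStop("need either roi or roiCenter + physicalWidthUm", "parameterError")
    if (!hasMpp(slide))
      soStop(paste("slide has no micron calibration: a physical ROI width cannot",
                   "be honoured; pass roi = RegionL0(...) in pixel units instead"),
             "calibrationMissingError")
    wl0 <- round(physicalWidthUm / slide@mpp[1])
    hl0 <- round(physicalWidthUm / slide@mpp[2])
    roi <- RegionL0(round(roiCenter[1] - wl0 / 2), round(roiCenter[2] - hl0 / 2),
                    wl0, hl0)
  }
  roi <- clampRegion(roi, slide@levelDims[1, ])
  if (is.null(roi)) soStop("ROI empty after clamping", "emptyRegionError")
  # coarsest level still at least outPx wide, so the final step downsamples
  widths <- roi@w / slide@levelDownsamples
  ok <- which(widths >= outPx)
  level <- if (length(ok)) max(ok) - 1L else 0L
  img <- readRegion(slide, roi, level)
  d <- dim(img@pixels)
  arr <- img@pixels
  if (d[2] > outPx)
    arr <- areaResample(arr, max(1L, round(d[1] * outPx / d[2])), outPx)
  applyTransform(RasterImage(arr, provenance = sprintf("inset %s", img@provenance)),
                 transform)
}

#' Annotate the ROI rectangle on an overview
#'
#' Draws a 2 px black rectangle at the ROI's position mapped through the
#' overview's crop offset, downsample and transform. The input object is not
#' modified; a copy is returned. A ROI that does not intersect the crop
#' yields an unannotated copy with a warning.
#'
#' @param ov an \linkS4class{OverviewImage}.
#' @param roi a \linkS4class{RegionL0}.
#' @return A new \linkS4class{OverviewImage} with the rectangle drawn.
#' @export
annotateRoi <- function(ov, roi) {
  if (!regionsIntersect(ov@crop, roi)) {
    soWarn("ROI does not intersect the overview crop: no annotation drawn",
           "roiDisjointWarning")
    return(ov)
  }
  eff <- ov@effectiveDownsample
  # image dims before the transform was applied
  d <- dim(ov@image@pixels)
  if (ov@transform@rotate90 %% 2L == 1L) { preW <- d[1]; preH <- d[2] }
  else { preW <- d[2]; preH <- d[1] }
  rx <- round((roi@x - ov@crop@x) / eff)
  ry <- round((roi@y - ov@crop@y) / eff)
  rw <- max(2L, round(roi@w / eff))
  rh <- max(2L, round(roi@h / eff))
  tr <- transformRect(c(rx, ry, rw, rh), preW, preH, ov@transform)
  arr <- strokeRect(ov@image@pixels, tr$rect[1], tr$rect[2], tr$rect[3],
                    tr$rect[4], stroke = 2L)
  new("OverviewImage", image = RasterImage(arr, ov@image@provenance),
      sourceLevel = ov@sourceLevel, effectiveDownsample = eff,
      crop = ov@crop, transform = ov@transform, scaleBar = ov@scaleBar)
}

#' Render an overview to a final raster with its scale bar
#'
#' Appends a white margin band (6\% of the image height by default, enough
#' for the bundled bitmap font) below the tissue pixels and draws the scale
#' bar and its label in the band's lower-left — the bar never occludes
#' tissue. Without a scale bar the band is omitted.
#'
#' @param ov an \linkS4class{OverviewImage}.
#' @param bandFrac margin band height as a fraction of the image height.
#' @return A \linkS4class{RasterImage} ready to write as PNG.
#' @export
renderOverview <- function(ov, bandFrac = 0.06) {
  arr <- ov@image@pixels
  bar <- ov@scaleBar
  if (is.null(bar)) return(RasterImage(arr, ov@image@provenance))
  H <- dim(arr)[1]; W <- dim(arr)[2]
  scale <- max(1L, floor(H * bandFrac / 12))
  bandH <- max(as.integer(round(H * bandFrac)), textHeightPx(scale) + 6L)
  out <- array(255L, c(H + bandH, W, 3L))
  out[1:H, , ] <- arr
  pad <- max(4L, round(0.02 * W))
  barTh <- max(2L, round(bandH * 0.2))
  barY <- H + bandH - barTh - 2L
  out <- fillRect(out, pad, barY, bar@lengthPx, barTh, c(0L, 0L, 0L))
  out <- drawText(out, bar@label, pad + bar@lengthPx + 6L,
                  H + bandH - textHeightPx(scale) - 2L, scale)
  RasterImage(out, paste0(ov@image@provenance, " [scale bar ", bar@label, "]"))
}

#' Write a raster to a lossless PNG
#'
#' @param image a \linkS4class{RasterImage}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeRasterPng <- function(image, path) {
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}

#' Read a PNG into a RasterImage
#'
#' @param path PNG path.
#' @return A \linkS4class{RasterImage}.
#' @export
readRasterPng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  RasterImage(round(img * 255), provenance = path)
}
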