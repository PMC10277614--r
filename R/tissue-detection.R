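#' Binary tissue mask computed on a slide thumbnail
#'
#' The automatic half of semi-automatic overview generation. Each thumbnail
#' pixel gets a tissue score \code{s = max(saturation, 1 - brightness)},
#' which responds both to chromogenic stains (brown/purple: saturated) and to
#' dark hematoxylin on a white background. The score histogram is thresholded
#' by Otsu's method, the mask is closed with a 2 px disc, and connected
#' components smaller than \code{minComponentFrac} of the thumbnail area are
#' dropped.
#'
#' @slot mask logical matrix, same dims as the thumbnail (rows = y).
#' @slot thumbDownsample numeric, level-0 px per thumbnail px.
#' @slot params list echoing threshold method and post-processing parameters.
#' @export
setClass("TissueMask", representation(mask = "matrix",
                                      thumbDownsample = "numeric",
                                      params = "list"))

#' @rdname TissueMask-class
#' @param mask a \code{TissueMask}.
#' @export
maskMatrix <- function(mask) mask@mask

# Per-pixel tissue score in [0, 1] from an 8-bit RGB array.
tissueScore <- function(arr) {
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3]) / 255
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3]) / 255
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  pmax(sat, 1 - mx)
}

#' Compute a tissue mask from a thumbnail
#'
#' @param thumb a \linkS4class{RasterImage} thumbnail, max dimension >= 64.
#' @param thumbDownsample level-0 px per thumbnail px (from
#'   \code{\link{thumbnail}}); recorded for later scaling.
#' @param minComponentFrac connected components smaller than this fraction of
#'   the thumbnail area are removed (default 0.005).
#' @param closingRadiusPx radius of the morphological closing disc (default 2).
#' @return A \linkS4class{TissueMask}. A blank thumbnail (near-zero score
#'   variance) yields an empty mask with a warning, never an error.
#' @export
tissueMask <- function(thumb, thumbDownsample = 1,
                       minComponentFrac = 0.005, closingRadiusPx = 2L) {
  arr <- thumb@pixels
  if (max(dim(arr)[1:2]) < 64L)
    soStop("thumbnail max dimension must be >= 64 px", "parameterError")
  score <- tissueScore(arr)
  params <- list(threshold = "otsu", min_component_frac = minComponentFrac,
                 closing_radius_px = closingRadiusPx)
  if (stats::sd(score) < 1e-4) {
    soWarn("blank thumbnail: tissue score has no contrast, returning empty mask",
           "blankThumbnailWarning")
    return(new("TissueMask", mask = matrix(FALSE, nrow(score), ncol(score)),
               thumbDownsample = thumbDownsample, params = params))
  }
  thr <- EBImage::otsu(EBImage::Image(score), range = c(0, 1), levels = 256)
  m <- score > thr
  brush <- EBImage::makeBrush(2L * closingRadiusPx + 1L, shape = "disc")
  m <- EBImage::closing(m, brush) > 0
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= minComponentFrac * length(m))
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  new("TissueMask", mask = m, thumbDownsample = thumbDownsample, params = params)
}

#' Level-0 bounding box of detected tissue
#'
#' Tight bounding box of the retained foreground, scaled to level 0 through
#' the thumbnail downsample, optionally expanded on every side by
#' \code{marginFrac} times the larger box dimension, and clamped to the slide
#' bounds. An empty mask falls back to the whole slide (with a warning) so
#' figure rendering always proceeds.
#'
#' @param mask a \linkS4class{TissueMask}.
#' @param marginFrac margin per side as a fraction of max(box w, box h), in
#'   [0, 0.5].
#' @param slideDims level-0 (width, height) used for scaling the fallback and
#'   clamping; defaults to thumbnail dims times the recorded downsample.
#' @return A \linkS4class{RegionL0}.
#' @export
tissueBbox <- function(mask, marginFrac = 0, slideDims = NULL) {
  if (marginFrac < 0 || marginFrac > 0.5)
    soStop("marginFrac must lie in [0, 0.5]", "parameterError")
  m <- mask@mask
  ds <- mask@thumbDownsample
  if (is.null(slideDims))
    slideDims <- c(round(ncol(m) * ds), round(nrow(m) * ds))
  if (!any(m)) {
    soWarn("empty tissue mask: falling back to whole-slide bounding box",
           "emptyMaskWarning")
    return(RegionL0(0, 0, slideDims[1], slideDims[2]))
  }
  cols <- which(apply(m, 2, any)); rows <- which(apply(m, 1, any))
  x0 <- floor((min(cols) - 1) * ds); x1 <- ceiling(max(cols) * ds)
  y0 <- floor((min(rows) - 1) * ds); y1 <- ceiling(max(rows) * ds)
  mar <- marginFrac * max(x1 - x0, y1 - y0)
  x0 <- x0 - mar; y0 <- y0 - mar; x1 <- x1 + mar; y1 <- y1 + mar
  out <- clampRegion(RegionL0(round(x0), round(y0),
                              round(x1 - x0), round(y1 - y0)), slideDims)
  if (is.null(out)) RegionL0(0, 0, slideDims[1], slideDims[2]) else out
}

#' One-call tissue bounding box for a slide
#'
#' Convenience wrapper: thumbnail (max dim 1024 px, fixed so the morphology
#' parameters are scale-stable), mask, bounding box.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param marginFrac margin per side, see \code{\link{tissueBbox}}.
#' @param maxPx thumbnail size used for detection.
#' @return A \linkS4class{RegionL0}.
#' @export
detectTissueBbox <- function(slide, marginFrac = 0, maxPx = 1024L) {
  th <- thumbnail(slide, maxPx)
  m <- tissueMask(th$image, thumbDownsample = th$effectiveDownsample)
  tissueBbox(m, marginFrac, slideDims = slide@levelDims[1, ])
}
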