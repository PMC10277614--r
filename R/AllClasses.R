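#' @import methods
NULL

# Classed conditions: every error the package raises carries a class so callers
# (and the CLI) can dispatch on failure kind rather than parse messages.
soStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "slideOverviewError")))
}

soWarn <- function(msg, class = "slideOverviewWarning") {
  warning(warningCondition(msg, class = c(class, "slideOverviewWarning")))
}

#' Rectangular region in level-0 pixel coordinates
#'
#' The single spatial reference frame of the package: all public spatial
#' arguments are half-open rectangles \code{[x, x+w) x [y, y+h)} in level-0
#' pixels, origin at the slide's top-left corner. Level-space coordinates are
#' internal only.
#'
#' @slot x,y integer top-left corner (0-based).
#' @slot w,h integer extent in pixels, at least 1.
#' @export
setClass("RegionL0", representation(x = "integer", y = "integer",
                                    w = "integer", h = "integer"),
         validity = function(object) {
           if (length(object@x) != 1L || length(object@y) != 1L ||
               length(object@w) != 1L || length(object@h) != 1L)
             return("x, y, w, h must be scalars")
           if (is.na(object@w) || is.na(object@h) || object@w < 1L || object@h < 1L)
             return("w and h must be >= 1")
           TRUE
         })

#' Construct a RegionL0
#'
#' @param x,y top-left corner in level-0 pixels (0-based).
#' @param w,h width and height in level-0 pixels (>= 1).
#' @return A \linkS4class{RegionL0} object.
#' @examples
#' RegionL0(1000, 2000, 160, 160)
#' @export
RegionL0 <- function(x, y, w, h) {
  new("RegionL0", x = as.integer(round(x)), y = as.integer(round(y)),
      w = as.integer(round(w)), h = as.integer(round(h)))
}

setMethod("show", "RegionL0", function(object) {
  cat(sprintf("RegionL0 [%d, %d) x [%d, %d)  (w=%d, h=%d)\n",
              object@x, object@x + object@w, object@y, object@y + object@h,
              object@w, object@h))
})

#' @rdname RegionL0
#' @param region a \code{RegionL0}.
#' @export
regionX <- function(region) region@x
#' @rdname RegionL0
#' @export
regionY <- function(region) region@y
#' @rdname RegionL0
#' @export
regionW <- function(region) region@w
#' @rdname RegionL0
#' @export
regionH <- function(region) region@h

# Clamp a region to [0,w0) x [0,h0); NULL when clamping empties it.
clampRegion <- function(region, dims) {
  x0 <- max(region@x, 0L); y0 <- max(region@y, 0L)
  x1 <- min(region@x + region@w, as.integer(dims[1]))
  y1 <- min(region@y + region@h, as.integer(dims[2]))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  RegionL0(x0, y0, x1 - x0, y1 - y0)
}

regionsIntersect <- function(a, b) {
  !(a@x + a@w <= b@x || b@x + b@w <= a@x ||
    a@y + a@h <= b@y || b@y + b@h <= a@y)
}

#' 8-bit RGB raster image
#'
#' Plain in-memory RGB raster: an H x W x 3 integer array with values in
#' 0..255, plus a free-text provenance note recording where the pixels came
#' from.
#'
#' @slot pixels integer array, dim H x W x 3, values in [0, 255].
#' @slot provenance character origin note.
#' @export
setClass("RasterImage", representation(pixels = "array", provenance = "character"),
         validity = function(object) {
           d <- dim(object@pixels)
           if (length(d) != 3L || d[3] != 3L) return("pixels must be H x W x 3")
           if (d[1] < 1L || d[2] < 1L) return("H and W must be >= 1")
           r <- range(object@pixels)
           if (is.na(r[1]) || r[1] < 0 || r[2] > 255)
             return("pixel values must lie in [0, 255]")
           TRUE
         })

#' Construct a RasterImage
#'
#' @param pixels numeric or integer H x W x 3 array, values in [0, 255]
#'   (numeric input is rounded to integers).
#' @param provenance character note recording the origin of the pixels.
#' @return A \linkS4class{RasterImage}.
#' @export
RasterImage <- function(pixels, provenance = "unspecified") {
  storage.mode(pixels) <- "integer"
  new("RasterImage", pixels = pixels, provenance = provenance)
}

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %d x %d (H x W), 8-bit RGB\n  provenance: %s\n",
              d[1], d[2], object@provenance))
})

#' @rdname RasterImage
#' @param image a \code{RasterImage}.
#' @export
imagePixels <- function(image) image@pixels

#' @rdname RasterImage
#' @export
imageDims <- function(image) {
  d <- dim(image@pixels)
  c(width = d[2], height = d[1])
}

#' Quarter-turn/mirror transform for slide orientation harmonisation
#'
#' Serial sections scanned in different orientations are harmonised with
#' quarter turns and a horizontal mirror; free-angle rotation is deliberately
#' excluded so that coordinate mapping stays exact. Applied after cropping,
#' before any annotation.
#'
#' @slot rotate90 integer in 0..3, counter-clockwise quarter turns.
#' @slot flipH logical, horizontal mirror (applied before the rotation).
#' @export
setClass("Transform", representation(rotate90 = "integer", flipH = "logical"),
         validity = function(object) {
           if (!(object@rotate90 %in% 0:3)) return("rotate90 must be in 0..3")
           if (length(object@flipH) != 1L || is.na(object@flipH))
             return("flipH must be TRUE or FALSE")
           TRUE
         })

#' @rdname Transform-class
#' @param rotate90 counter-clockwise quarter turns, 0..3.
#' @param flipH horizontal mirror.
#' @export
Transform <- function(rotate90 = 0L, flipH = FALSE) {
  new("Transform", rotate90 = as.integer(rotate90), flipH = flipH)
}

#' Physically calibrated scale bar
#'
#' Scale-bar lengths are restricted to the "nice" set \{1, 2, 5\} x 10^k
#' microns; labels print millimetres with one decimal at or above 1000 um and
#' integer microns below.
#'
#' @slot lengthUm numeric physical length in microns.
#' @slot lengthPx integer drawn length in pixels.
#' @slot label character, e.g. "1.0 mm" or "250 µm".
#' @export
setClass("ScaleBar", representation(lengthUm = "numeric", lengthPx = "integer",
                                    label = "character"))

#' Downsampled, cropped, transformed overview of one slide
#'
#' The rendered overview raster together with its full provenance: the pyramid
#' level read, the effective downsample relative to level 0, the level-0 crop,
#' the orientation transform, and the scale bar (when calibration allowed one).
#'
#' @slot image a \linkS4class{RasterImage} (tissue area only, no margin band).
#' @slot sourceLevel integer pyramid level the pixels were read from.
#' @slot effectiveDownsample numeric, crop width / image width.
#' @slot crop \linkS4class{RegionL0} actually used (after clamping).
#' @slot transform \linkS4class{Transform} applied.
#' @slot scaleBar a \linkS4class{ScaleBar}, or NULL when calibration was
#'   absent or the bar was not requested.
#' @export
setClass("OverviewImage", representation(image = "RasterImage",
                                         sourceLevel = "integer",
                                         effectiveDownsample = "numeric",
                                         crop = "RegionL0",
                                         transform = "Transform",
                                         scaleBar = "ANY"))

setMethod("show", "OverviewImage", function(object) {
  d <- dim(object@image@pixels)
  cat(sprintf("OverviewImage %d x %d px, level %d, downsample %.3f\n",
              d[2], d[1], object@sourceLevel, object@effectiveDownsample))
  cat(sprintf("  crop: (%d, %d, %d, %d) level-0 px\n", object@crop@x,
              object@crop@y, object@crop@w, object@crop@h))
  if (!is.null(object@scaleBar))
    cat(sprintf("  scale bar: %s (%d px)\n", object@scaleBar@label,
                object@scaleBar@lengthPx))
  else cat("  scale bar: none\n")
})

#' @rdname OverviewImage-class
#' @param ov an \code{OverviewImage}.
#' @export
overviewRaster <- function(ov) ov@image
#' @rdname OverviewImage-class
#' @export
overviewScaleBar <- function(ov) ov@scaleBar
#' @rdname OverviewImage-class
#' @export
overviewCrop <- function(ov) ov@crop
#' @rdname OverviewImage-class
#' @export
overviewDownsample <- function(ov) ov@effectiveDownsample
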