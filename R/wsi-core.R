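#' Pyramidal whole-slide image
#'
#' Metadata handle for a multi-resolution slide scan: per-level dimensions,
#' downsample factors relative to level 0, and the micron-per-pixel
#' calibration when the source carries one. Pixels are read on demand with
#' \code{\link{readRegion}}; the object itself holds no raster data.
#'
#' @slot sourcePath path of the backing file.
#' @slot levelCount integer >= 1.
#' @slot levelDims integer matrix, one row per level, columns (width, height),
#'   level 0 first.
#' @slot levelDownsamples numeric, strictly increasing, first element 1.
#' @slot mpp numeric length-2 (mpp_x, mpp_y) microns per level-0 pixel, or
#'   length-0 when the source carries no calibration. Never guessed.
#' @slot vendor character tag, e.g. "generic-tiff" or "synthetic".
#' @export
setClass("SlidePyramid",
         representation(sourcePath = "character", levelCount = "integer",
                        levelDims = "matrix", levelDownsamples = "numeric",
                        mpp = "numeric", vendor = "character"),
         validity = function(object) {
  n <- object@levelCount
  if (n < 1L) return("level_count must be >= 1")
  if (nrow(object@levelDims) != n) return("levelDims must have one row per level")
  d <- object@levelDownsamples
  if (length(d) != n) return("one downsample per level required")
  if (abs(d[1] - 1) > 1e-9) return("first downsample must be 1.0")
  if (n > 1L && any(diff(d) <= 0)) return("downsamples must be strictly increasing")
  for (k in seq_len(n)) {
    expect <- object@levelDims[1, ] / d[k]
    if (any(abs(object@levelDims[k, ] - expect) > 1 + 1e-6))
      return(sprintf("level %d dims inconsistent with downsample %.3f", k - 1L, d[k]))
  }
  if (length(object@mpp) == 2L && (any(object@mpp <= 0) || any(object@mpp >= 100)))
    return("mpp values must lie in (0, 100) microns per pixel")
  if (!(length(object@mpp) %in% c(0L, 2L))) return("mpp must be absent or length 2")
  TRUE
})

setMethod("show", "SlidePyramid", function(object) {
  cat(sprintf("SlidePyramid (%s): %d level(s)\n", object@vendor, object@levelCount))
  for (k in seq_len(object@levelCount))
    cat(sprintf("  level %d: %d x %d px, downsample %.2f\n", k - 1L,
                object@levelDims[k, 1], object@levelDims[k, 2],
                object@levelDownsamples[k]))
  if (length(object@mpp) == 2L)
    cat(sprintf("  calibration: %.4g x %.4g µm/px\n", object@mpp[1], object@mpp[2]))
  else cat("  calibration: absent\n")
})

#' @rdname SlidePyramid-class
#' @param slide a \code{SlidePyramid}.
#' @export
levelCount <- function(slide) slide@levelCount
#' @rdname SlidePyramid-class
#' @export
levelDims <- function(slide) slide@levelDims
#' @rdname SlidePyramid-class
#' @export
levelDownsamples <- function(slide) slide@levelDownsamples
#' @rdname SlidePyramid-class
#' @export
slideMpp <- function(slide) slide@mpp
#' @rdname SlidePyramid-class
#' @export
hasMpp <- function(slide) length(slide@mpp) == 2L

# Per-level downsample estimation. Level dims are floors of level0/d, so a
# single-axis ratio can overstate d enough to break the other axis's +/-1 px
# invariant on coarse levels; pick the first candidate consistent with both.
estimateDownsamples <- function(dims, path) {
  vapply(seq_len(nrow(dims)), function(k) {
    if (k == 1L) return(1.0)
    w0 <- dims[1, 1]; h0 <- dims[1, 2]
    wk <- dims[k, 1]; hk <- dims[k, 2]
    cand <- c(w0 / wk, h0 / hk, (w0 / wk + h0 / hk) / 2)
    for (d in cand) {
      if (abs(wk - w0 / d) <= 1 + 1e-6 && abs(hk - h0 / d) <= 1 + 1e-6)
        return(d)
    }
    soStop(sprintf("level %d dims inconsistent with any downsample: %s",
                   k - 1L, path), "invalidPyramidError")
  }, 0.0)
}

# Sidecar convention: <slide>.meta.json beside the file, keys mpp_x/mpp_y,
# authoritative over TIFF resolution tags (whose unit dialects are ambiguous).
sidecarPath <- function(path) paste0(path, ".meta.json")

readMppSidecar <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) return(numeric(0))
  meta <- jsonlite::fromJSON(sc)
  if (is.null(meta$mpp_x) || is.null(meta$mpp_y)) return(numeric(0))
  c(as.numeric(meta$mpp_x), as.numeric(meta$mpp_y))
}

#' Open a pyramidal whole-slide image
#'
#' Reads the level structure of a pyramidal (multi-page) TIFF without loading
#' pixel data. Micron calibration is taken from a JSON sidecar
#' (\code{<slide>.meta.json} with keys \code{mpp_x}, \code{mpp_y}) when
#' present; a slide without calibration gets \code{mpp} absent — the package
#' never invents a value, and downstream scale bars are then suppressed.
#'
#' @param path path to a pyramidal TIFF file.
#' @return A \linkS4class{SlidePyramid}.
#' @examples
#' spec <- SlideSpec(level0Dims = c(512, 384), downsamples = c(1, 4),
#'                   mpp = c(0.5, 0.5))
#' f <- file.path(tempdir(), "example.tiff")
#' generateSlide(spec, f)
#' openSlide(f)
#' @export
openSlide <- function(path) {
  if (!file.exists(path))
    soStop(sprintf("slide file not found: %s", path), "formatError")
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e) NULL)
  if (is.null(info))
    soStop(sprintf("not a readable TIFF slide: %s", path), "formatError")
  if (!is.data.frame(info)) info <- do.call(rbind.data.frame, info)
  if (nrow(info) < 1L)
    soStop(sprintf("slide has no pyramid levels: %s", path), "invalidPyramidError")
  dims <- cbind(width = as.integer(info$width), height = as.integer(info$length))
  # levels must arrive finest-first; sort defensively by width
  ord <- order(dims[, 1], decreasing = TRUE)
  dims <- dims[ord, , drop = FALSE]
  ds <- estimateDownsamples(dims, path)
  slide <- new("SlidePyramid", sourcePath = path,
               levelCount = nrow(dims), levelDims = dims,
               levelDownsamples = ds, mpp = readMppSidecar(path),
               vendor = "generic-tiff")
  v <- validObject(slide, test = TRUE)
  if (!isTRUE(v))
    soStop(sprintf("not a valid image pyramid (%s): %s", v, path),
           "invalidPyramidError")
  slide
}

#' Map a level-0 region into level coordinates
#'
#' x and y are floored; w and h are rounded and clamped to at least 1 px so a
#' region never vanishes. The round trip back to level 0 drifts by less than
#' one downsample per coordinate.
#'
#' @param region a \linkS4class{RegionL0}.
#' @param downsample downsample factor (>= 1) of the target level.
#' @return A \code{RegionL0}-shaped rectangle in level coordinates.
#' @examples
#' mapL0ToLevel(RegionL0(1000, 2000, 160, 160), 16)  # (62, 125, 10, 10)
#' @export
mapL0ToLevel <- function(region, downsample) {
  stopifnot(downsample >= 1)
  RegionL0(floor(region@x / downsample), floor(region@y / downsample),
           max(1, round(region@w / downsample)),
           max(1, round(region@h / downsample)))
}

# Read one pyramid level fully, as an integer 0..255 H x W x 3 array.
readLevelArray <- function(slide, level) {
  pg <- tiff::readTIFF(slide@sourcePath, all = level + 1L)
  img <- if (is.list(pg)) pg[[1]] else pg
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Read a region of a slide at a pyramid level
#'
#' The region is given in level-0 coordinates (the package's single spatial
#' frame) and clamped to the slide bounds; the returned raster covers its
#' level-0 footprint at the requested level's resolution.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param region a \linkS4class{RegionL0}.
#' @param level pyramid level index, 0-based.
#' @return A \linkS4class{RasterImage} with dims approximately
#'   (w/d, h/d) where d is the level's downsample.
#' @export
readRegion <- function(slide, region, level = 0L) {
  if (level < 0L || level >= slide@levelCount)
    soStop(sprintf("level %d out of range [0, %d)", level, slide@levelCount),
           "indexError")
  region <- clampRegion(region, slide@levelDims[1, ])
  if (is.null(region))
    soStop("region is empty after clamping to slide bounds", "emptyRegionError")
  d <- slide@levelDownsamples[level + 1L]
  lv <- mapL0ToLevel(region, d)
  arr <- readLevelArray(slide, level)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  x0 <- min(lv@x, W - 1L); y0 <- min(lv@y, H - 1L)
  x1 <- min(lv@x + lv@w, W); y1 <- min(lv@y + lv@h, H)
  RasterImage(arr[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE],
              provenance = sprintf("%s level %d region (%d,%d,%d,%d)",
                                   basename(slide@sourcePath), level,
                                   region@x, region@y, region@w, region@h))
}

#' Whole-slide thumbnail
#'
#' Reads the coarsest pyramid level still at least \code{maxPx} wide/high and
#' area-averages it down so the maximum dimension equals \code{maxPx}. Slides
#' already smaller than \code{maxPx} are returned at native resolution —
#' never upsampled.
#'
#' @param slide a \linkS4class{SlidePyramid}.
#' @param maxPx maximum output dimension in pixels (>= 64).
#' @return A list with elements \code{image} (\linkS4class{RasterImage}) and
#'   \code{effectiveDownsample} (level-0 max dim / output max dim).
#' @export
thumbnail <- function(slide, maxPx = 1024L) {
  if (maxPx < 64L) soStop("maxPx must be >= 64", "parameterError")
  maxDims <- pmax(slide@levelDims[, 1], slide@levelDims[, 2])
  cand <- which(maxDims >= maxPx)
  if (length(cand) == 0L) {
    arr <- readLevelArray(slide, 0L)
    return(list(image = RasterImage(arr, provenance = "thumbnail (native level 0)"),
                effectiveDownsample = 1.0))
  }
  level <- max(cand) - 1L   # coarsest level still >= maxPx
  arr <- readLevelArray(slide, level)
  d <- dim(arr)
  if (max(d[1:2]) > maxPx) {
    s <- maxPx / max(d[1:2])
    arr <- areaResample(arr, max(1L, round(d[1] * s)), max(1L, round(d[2] * s)))
  }
  eff <- max(slide@levelDims[1, ]) / max(dim(arr)[1:2])
  list(image = RasterImage(arr, provenance = sprintf("thumbnail from level %d", level)),
       effectiveDownsample = eff)
}

#' Effective micron calibration at a pyramid level
#'
#' @param slide a \linkS4class{SlidePyramid} with calibration present.
#' @param level pyramid level index, 0-based.
#' @return Numeric length-2: microns per pixel (x, y) at that level.
#' @export
effectiveMpp <- function(slide, level) {
  if (!hasMpp(slide))
    soStop("slide carries no micron calibration; scale bars must be suppressed, never fabricated",
           "calibrationMissingError")
  if (level < 0L || level >= slide@levelCount)
    soStop(sprintf("level %d out of range [0, %d)", level, slide@levelCount),
           "indexError")
  slide@mpp * slide@levelDownsamples[level + 1L]
}
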