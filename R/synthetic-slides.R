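#' Specification of a synthetic pyramidal slide
#'
#' Deterministic fixture generator standing in for scanned slides: a white
#' background carrying elliptical "tissue" shapes and, optionally, a
#' checkerboard region-of-interest pattern with known period. Every pyramid
#' level is rendered analytically at its own scale (never resampled from
#' level 0), so reader-side level-consistency checks exercise the reader, not
#' the generator. Geometry is exactly reproducible; the seed only drives
#' optional speckle noise, which is off by default.
#'
#' @slot level0Dims integer (width, height) of level 0 in pixels.
#' @slot downsamples numeric, strictly increasing from 1.
#' @slot mpp numeric (x, y) microns per level-0 pixel; length 0 for an
#'   uncalibrated slide.
#' @slot backgroundRgb integer length-3, 0..255.
#' @slot tissueShapes list of ellipses, each
#'   \code{list(center = c(x, y), semiAxes = c(a, b), fillRgb = c(r, g, b))}
#'   in level-0 pixels.
#' @slot roiPattern \code{NULL} or \code{list(region = RegionL0, kind =
#'   "checkerboard", periodPx, rgbA, rgbB)}.
#' @slot seed integer; drives speckle noise only.
#' @slot noiseSd numeric, standard deviation of optional additive speckle in
#'   8-bit counts (0 disables).
#' @export
setClass("SlideSpec",
         representation(level0Dims = "integer", downsamples = "numeric",
                        mpp = "numeric", backgroundRgb = "integer",
                        tissueShapes = "list", roiPattern = "ANY",
                        seed = "integer", noiseSd = "numeric"),
         validity = function(object) {
  w0 <- object@level0Dims[1]; h0 <- object@level0Dims[2]
  if (w0 < 1L || h0 < 1L) return("level0Dims must be positive")
  d <- object@downsamples
  if (abs(d[1] - 1) > 1e-9 || (length(d) > 1 && any(diff(d) <= 0)))
    return("downsamples must start at 1 and strictly increase")
  for (sh in object@tissueShapes) {
    cx <- sh$center[1]; cy <- sh$center[2]; a <- sh$semiAxes[1]; b <- sh$semiAxes[2]
    if (a <= 0 || b <= 0) return("ellipse semi-axes must be positive")
    if (cx - a < 0 || cx + a > w0 || cy - b < 0 || cy + b > h0)
      return("tissue shape exceeds level-0 bounds")
  }
  if (!is.null(object@roiPattern)) {
    if (!identical(object@roiPattern$kind, "checkerboard"))
      return("only checkerboard roi patterns are supported")
    if (object@roiPattern$periodPx < 2) return("periodPx must be >= 2")
  }
  TRUE
})

#' @rdname SlideSpec-class
#' @param level0Dims,downsamples,mpp,backgroundRgb,tissueShapes,roiPattern,seed,noiseSd
#'   see slot documentation.
#' @export
SlideSpec <- function(level0Dims = c(8000L, 6000L),
                      downsamples = c(1, 4, 16, 64),
                      mpp = c(0.25, 0.25),
                      backgroundRgb = c(255L, 255L, 255L),
                      tissueShapes = list(),
                      roiPattern = NULL,
                      seed = 0L, noiseSd = 0) {
  new("SlideSpec", level0Dims = as.integer(level0Dims),
      downsamples = as.numeric(downsamples), mpp = as.numeric(mpp),
      backgroundRgb = as.integer(backgroundRgb), tissueShapes = tissueShapes,
      roiPattern = roiPattern, seed = as.integer(seed),
      noiseSd = as.numeric(noiseSd))
}

#' Ground truth emitted beside every generated slide
#'
#' @slot tissueBbox \linkS4class{RegionL0}: exact union bounding box of all
#'   tissue shapes (integer arithmetic, no rasterisation involved).
#' @slot roiRegion \linkS4class{RegionL0} of the checkerboard pattern, or NULL.
#' @slot spec echo of the generating \linkS4class{SlideSpec} as a plain list.
#' @export
setClass("GroundTruth", representation(tissueBbox = "RegionL0",
                                       roiRegion = "ANY", spec = "list"))

#' @rdname GroundTruth-class
#' @param truth a \code{GroundTruth}.
#' @export
truthBbox <- function(truth) truth@tissueBbox
#' @rdname GroundTruth-class
#' @export
truthRoi <- function(truth) truth@roiRegion

# Analytic union bbox of the ellipse extents, in exact integer arithmetic.
analyticBbox <- function(spec) {
  if (length(spec@tissueShapes) == 0L)
    return(RegionL0(0, 0, spec@level0Dims[1], spec@level0Dims[2]))
  x0 <- min(vapply(spec@tissueShapes, function(s) s$center[1] - s$semiAxes[1], 0))
  x1 <- max(vapply(spec@tissueShapes, function(s) s$center[1] + s$semiAxes[1], 0))
  y0 <- min(vapply(spec@tissueShapes, function(s) s$center[2] - s$semiAxes[2], 0))
  y1 <- max(vapply(spec@tissueShapes, function(s) s$center[2] + s$semiAxes[2], 0))
  RegionL0(x0, y0, x1 - x0, y1 - y0)
}

# Render one pyramid level at downsample d, sampling shape membership at
# pixel centres in level-0 coordinates. Returns numeric H x W x 3 in [0, 1]
# ready for tiff::writeTIFF.
renderLevel <- function(spec, d) {
  W <- as.integer(floor(spec@level0Dims[1] / d))
  H <- as.integer(floor(spec@level0Dims[2] / d))
  xs <- (seq_len(W) - 0.5) * d
  ys <- (seq_len(H) - 0.5) * d
  arr <- array(0, c(H, W, 3L))
  for (ch in 1:3) arr[, , ch] <- spec@backgroundRgb[ch] / 255
  for (sh in spec@tissueShapes) {
    ex <- ((xs - sh$center[1]) / sh$semiAxes[1])^2
    ey <- ((ys - sh$center[2]) / sh$semiAxes[2])^2
    mask <- outer(ey, ex, "+") <= 1
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[mask] <- sh$fillRgb[ch] / 255
      arr[, , ch] <- plane
    }
  }
  rp <- spec@roiPattern
  if (!is.null(rp)) {
    r <- rp$region
    inx <- xs >= r@x & xs < r@x + r@w
    iny <- ys >= r@y & ys < r@y + r@h
    if (any(inx) && any(iny)) {
      px <- floor((xs[inx] - r@x) / rp$periodPx)
      py <- floor((ys[iny] - r@y) / rp$periodPx)
      parity <- outer(py, px, "+") %% 2
      for (ch in 1:3) {
        tile <- ifelse(parity == 0, rp$rgbA[ch], rp$rgbB[ch]) / 255
        plane <- arr[, , ch]
        plane[iny, inx] <- tile
        arr[, , ch] <- plane
      }
    }
  }
  if (spec@noiseSd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec@seed + as.integer(round(d)))
    arr <- arr + array(stats::rnorm(length(arr), 0, spec@noiseSd / 255), dim(arr))
    arr[arr < 0] <- 0; arr[arr > 1] <- 1
  }
  # snap to the 8-bit grid so every level round-trips exactly through TIFF
  round(arr * 255) / 255
}

specAsList <- function(spec) {
  list(level0_dims = as.integer(spec@level0Dims),
       downsamples = spec@downsamples,
       mpp = if (length(spec@mpp)) spec@mpp else NULL,
       background_rgb = spec@backgroundRgb,
       tissue_shapes = lapply(spec@tissueShapes, function(s)
         list(center = s$center, semi_axes = s$semiAxes, fill_rgb = s$fillRgb)),
       roi_pattern = if (is.null(spec@roiPattern)) NULL else
         list(x = spec@roiPattern$region@x, y = spec@roiPattern$region@y,
              w = spec@roiPattern$region@w, h = spec@roiPattern$region@h,
              kind = spec@roiPattern$kind, period_px = spec@roiPattern$periodPx,
              rgb_a = spec@roiPattern$rgbA, rgb_b = spec@roiPattern$rgbB),
       seed = spec@seed, noise_sd = spec@noiseSd)
}

#' Generate a synthetic pyramidal slide fixture
#'
#' Writes an uncompressed multi-page TIFF (one page per pyramid level,
#' finest first), a JSON calibration sidecar (\code{<slide>.meta.json}) and a
#' machine-readable ground-truth file (\code{<slide>.truth.json}). The same
#' spec and seed always produce byte-identical files.
#'
#' @param spec a \linkS4class{SlideSpec}.
#' @param outPath output TIFF path.
#' @return A \linkS4class{GroundTruth}, invisibly identical to the contents
#'   of the truth sidecar.
#' @examples
#' spec <- SlideSpec(level0Dims = c(800, 600), downsamples = c(1, 4),
#'   tissueShapes = list(list(center = c(400, 300), semiAxes = c(250, 150),
#'                            fillRgb = c(180, 90, 140))))
#' truth <- generateSlide(spec, file.path(tempdir(), "fix.tiff"))
#' truthBbox(truth)  # (150, 150, 500, 300)
#' @export
generateSlide <- function(spec, outPath) {
  v <- validObject(spec, test = TRUE)
  if (!isTRUE(v)) soStop(paste("invalid slide spec:", v), "specError")
  levels <- lapply(spec@downsamples, function(d) renderLevel(spec, d))
  tiff::writeTIFF(levels, outPath, bits.per.sample = 8L, compression = "none")
  if (length(spec@mpp) == 2L)
    jsonlite::write_json(list(mpp_x = spec@mpp[1], mpp_y = spec@mpp[2]),
                         sidecarPath(outPath), auto_unbox = TRUE, digits = NA)
  bbox <- analyticBbox(spec)
  roi <- if (is.null(spec@roiPattern)) NULL else spec@roiPattern$region
  truthList <- list(
    tissue_bbox_l0 = list(x = bbox@x, y = bbox@y, w = bbox@w, h = bbox@h),
    roi_region = if (is.null(roi)) NULL else
      list(x = roi@x, y = roi@y, w = roi@w, h = roi@h),
    spec = specAsList(spec))
  jsonlite::write_json(truthList, paste0(outPath, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(new("GroundTruth", tissueBbox = bbox, roiRegion = roi,
                spec = specAsList(spec)))
}

# Stain labels of the immunophenotyping panel the fixtures emulate: H&E plus
# the screening (CD45, keratin) and phenotyping markers, Ig light chains, and
# EBER in-situ hybridisation.
panelStainLabels <- function() {
  c("H&E", "CD45", "AE1/AE3", "CD20", "CD79A", "CD3", "BCL2", "CD56",
    "CD10", "BCL6", "MUM1", "CD138", "CD30", "EBER", "IgK", "IgL")
}

# Distinct, saturated fill colour per stain (chromogen-like browns/purples
# plus H&E pink); distinctness is what the fixtures need, not realism.
stainFillRgb <- function(stain) {
  palette <- list(
    "H&E"     = c(220, 120, 170), "CD45"  = c(150,  90,  40),
    "AE1/AE3" = c(170, 100,  50), "CD20"  = c(130,  70,  30),
    "CD79A"   = c(160,  80,  60), "CD3"   = c(140, 100,  70),
    "BCL2"    = c(120,  60,  20), "CD56"  = c(180, 140, 100),
    "CD10"    = c(190, 150, 110), "BCL6"  = c(150, 110,  80),
    "MUM1"    = c(110,  50,  10), "CD138" = c(200, 160, 120),
    "CD30"    = c(130,  90,  50), "EBER"  = c( 60,  60, 120),
    "IgK"     = c(100,  40,  30), "IgL"   = c( 90,  50,  70))
  palette[[stain]]
}

#' Generate the full stain-panel fixture suite
#'
#' One synthetic slide per stain of the immunophenotyping panel (16 labels:
#' H&E, CD45, AE1/AE3, CD20, CD79A, CD3, BCL2, CD56, CD10, BCL6, MUM1, CD138,
#' CD30, EBER, IgK, IgL), all sharing identical tissue geometry so that
#' cross-stain layout tests have a single ground truth, with a distinct
#' stain-specific fill colour per slide.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer passed through to each \linkS4class{SlideSpec}.
#' @param level0Dims,downsamples,mpp pyramid geometry shared by all fixtures.
#' @return A data.frame with columns \code{path}, \code{stain}, plus the
#'   shared \code{truth} (a \linkS4class{GroundTruth}) as an attribute.
#' @export
stainPanelSuite <- function(outDir, seed = 0L,
                            level0Dims = c(1600L, 1200L),
                            downsamples = c(1, 4, 16),
                            mpp = c(0.25, 0.25)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- level0Dims[1]; h <- level0Dims[2]
  labels <- panelStainLabels()
  paths <- character(length(labels))
  truth <- NULL
  for (i in seq_along(labels)) {
    st <- labels[i]
    spec <- SlideSpec(
      level0Dims = level0Dims, downsamples = downsamples, mpp = mpp,
      tissueShapes = list(
        list(center = c(w * 0.5, h * 0.5), semiAxes = c(w * 0.31, h * 0.28),
             fillRgb = stainFillRgb(st)),
        list(center = c(w * 0.68, h * 0.42), semiAxes = c(w * 0.10, h * 0.12),
             fillRgb = pmax(stainFillRgb(st) - 30L, 0L))),
      seed = seed)
    safe <- gsub("[^A-Za-z0-9]+", "_", st)
    paths[i] <- file.path(outDir, sprintf("panel_%02d_%s.tiff", i, safe))
    truth <- generateSlide(spec, paths[i])
  }
  out <- data.frame(path = paths, stain = labels, stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}
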