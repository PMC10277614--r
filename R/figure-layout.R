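#' One panel of a patient-level figure
#'
#' A panel shows either one slide (overview, optional ROI inset, labels) or a
#' placeholder — exactly one of \code{slidePath} / \code{placeholderText} is
#' set. Placeholders keep the figure grid intact when a histology sample is
#' unavailable.
#'
#' @slot rowLabel character, e.g. a sample identifier.
#' @slot stain character stain label, e.g. "CD20".
#' @slot slidePath character path, or NA for a placeholder panel.
#' @slot roi NULL, a \linkS4class{RegionL0}, or
#'   \code{list(center = c(x, y), widthUm = w)} for a physically sized ROI.
#' @slot bbox NULL for automatic tissue detection, or a manual
#'   \linkS4class{RegionL0} override (the human half of "semi-automatic").
#' @slot transform a \linkS4class{Transform}.
#' @slot placeholderText character, or NA when a slide is given.
#' @export
setClass("PanelSpec",
         representation(rowLabel = "character", stain = "character",
                        slidePath = "character", roi = "ANY", bbox = "ANY",
                        transform = "Transform", placeholderText = "character"),
         validity = function(object) {
           hasSlide <- !is.na(object@slidePath)
           hasPlaceholder <- !is.na(object@placeholderText)
           if (hasSlide == hasPlaceholder)
             return("exactly one of slidePath / placeholderText must be set")
           TRUE
         })

#' @rdname PanelSpec-class
#' @param rowLabel,stain,slidePath,roi,bbox,transform,placeholderText see
#'   slot documentation.
#' @export
PanelSpec <- function(rowLabel, stain, slidePath = NA_character_, roi = NULL,
                      bbox = NULL, transform = Transform(),
                      placeholderText = NA_character_) {
  new("PanelSpec", rowLabel = rowLabel, stain = stain,
      slidePath = as.character(slidePath), roi = roi, bbox = bbox,
      transform = transform, placeholderText = as.character(placeholderText))
}

#' Declarative description of a patient's figure grid
#'
#' Panels are placed row-major in list order: the config author groups rows
#' (e.g. primary region vs xenograft passage) purely by ordering. Each grid
#' cell is \code{panelPx} plus a label band below it.
#'
#' @slot patientId character.
#' @slot panels list of \linkS4class{PanelSpec}, length >= 1.
#' @slot cols integer >= 1.
#' @slot panelPx integer (width, height) of the image cell, >= 128.
#' @slot insetFrac inset edge as a fraction of panel width (default 0.3).
#' @slot gutterPx gap between cells.
#' @slot labelBandPx label band height under each panel.
#' @slot scaleBar logical: draw scale bars where calibration allows.
#' @slot output list(path, format) or empty list.
#' @export
setClass("FigureConfig",
         representation(patientId = "character", panels = "list",
                        cols = "integer", panelPx = "integer",
                        insetFrac = "numeric", gutterPx = "integer",
                        labelBandPx = "integer", scaleBar = "logical",
                        output = "list"),
         validity = function(object) {
           if (length(object@panels) < 1L) return("at least one panel required")
           if (object@cols < 1L) return("cols must be >= 1")
           if (any(object@panelPx < 128L)) return("panel dims must be >= 128 px")
           TRUE
         })

#' @rdname FigureConfig-class
#' @param patientId,panels,cols,panelPx,insetFrac,gutterPx,labelBandPx,scaleBar,output
#'   see slot documentation.
#' @export
FigureConfig <- function(patientId, panels, cols = 4L,
                         panelPx = c(400L, 320L), insetFrac = 0.3,
                         gutterPx = 10L, labelBandPx = 24L, scaleBar = TRUE,
                         output = list()) {
  new("FigureConfig", patientId = patientId, panels = panels,
      cols = as.integer(cols), panelPx = as.integer(panelPx),
      insetFrac = insetFrac, gutterPx = as.integer(gutterPx),
      labelBandPx = as.integer(labelBandPx), scaleBar = scaleBar,
      output = output)
}

#' Canvas dimensions of a figure config
#'
#' \code{rows = ceiling(n_panels / cols)};
#' \code{w = cols * panel_w + (cols - 1) * gutter};
#' \code{h = rows * (panel_h + label_band) + (rows - 1) * gutter}.
#'
#' @param cfg a \linkS4class{FigureConfig}.
#' @return Integer (canvas width, canvas height) in pixels.
#' @export
layoutDims <- function(cfg) {
  n <- length(cfg@panels)
  rows <- ceiling(n / cfg@cols)
  w <- cfg@cols * cfg@panelPx[1] + (cfg@cols - 1L) * cfg@gutterPx
  h <- rows * (cfg@panelPx[2] + cfg@labelBandPx) + (rows - 1L) * cfg@gutterPx
  as.integer(c(w, h))
}

placeholderPanel <- function(text, pw, ph) {
  arr <- array(230L, c(ph, pw, 3L))
  scale <- 1L
  tw <- textWidthPx(text, scale)
  drawText(arr, text, max(0L, round((pw - tw) / 2)),
           round((ph - textHeightPx(scale)) / 2), scale)
}

# Paste src array into dst at 0-based (x, y), clipping at the canvas edge.
pasteArray <- function(dst, src, x, y) {
  h <- min(dim(src)[1], dim(dst)[1] - y)
  w <- min(dim(src)[2], dim(dst)[2] - x)
  if (h < 1L || w < 1L) return(dst)
  dst[(y + 1L):(y + h), (x + 1L):(x + w), ] <- src[1:h, 1:w, , drop = FALSE]
  dst
}

#' Render one figure panel
#'
#' The slide's tissue bounding box (detected, unless a manual override is
#' given) is extracted as an overview that fills the panel; when a ROI is
#' present the overview is annotated with its rectangle and a square inset of
#' width \code{insetFrac * panel_w} with a 2 px black border is composited in
#' the top-right corner. The label band below shows row label and stain. An
#' unreadable slide degrades to a placeholder panel carrying the error text,
#' with a warning recorded — the figure always completes.
#'
#' @param spec a \linkS4class{PanelSpec}.
#' @param cfg the enclosing \linkS4class{FigureConfig}.
#' @return A list: \code{image} (panel raster incl. label band),
#'   \code{manifest} (provenance entry), \code{warnings} (character vector).
#' @export
renderPanel <- function(spec, cfg) {
  pw <- cfg@panelPx[1]; ph <- cfg@panelPx[2]
  warns <- character(0)
  manifest <- list(row_label = spec@rowLabel, stain = spec@stain)
  if (!is.na(spec@placeholderText)) {
    panel <- placeholderPanel(spec@placeholderText, pw, ph)
    manifest$placeholder <- spec@placeholderText
  } else {
    res <- withCallingHandlers(
      tryCatch({
        slide <- openSlide(spec@slidePath)
        crop <- if (!is.null(spec@bbox)) spec@bbox else detectTissueBbox(slide)
        ov <- extractOverview(slide, crop, targetPx = max(pw, ph),
                              transform = spec@transform,
                              withScaleBar = cfg@scaleBar)
        roiRect <- NULL
        inset <- NULL
        if (!is.null(spec@roi)) {
          if (is(spec@roi, "RegionL0")) {
            roiRect <- spec@roi
            inset <- extractInset(slide, roi = spec@roi,
                                  outPx = max(64L, round(cfg@insetFrac * pw)),
                                  transform = spec@transform)
          } else {
            ctr <- spec@roi$center; wum <- spec@roi$widthUm
            wl0 <- round(wum / slide@mpp[1]); hl0 <- round(wum / slide@mpp[2])
            roiRect <- RegionL0(round(ctr[1] - wl0 / 2), round(ctr[2] - hl0 / 2),
                                wl0, hl0)
            inset <- extractInset(slide, roiCenter = ctr, physicalWidthUm = wum,
                                  outPx = max(64L, round(cfg@insetFrac * pw)),
                                  transform = spec@transform)
          }
          ov <- annotateRoi(ov, roiRect)
        }
        list(ov = ov, inset = inset)
      }, error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      warns <- c(warns, conditionMessage(res))
      panel <- placeholderPanel(conditionMessage(res), pw, ph)
      manifest$error <- conditionMessage(res)
    } else {
      rendered <- renderOverview(res$ov)
      rd <- dim(rendered@pixels)
      if (max(rd[1] / ph, rd[2] / pw) > 1) {
        s <- min(ph / rd[1], pw / rd[2])
        shr <- areaResample(rendered@pixels, max(1L, floor(rd[1] * s)),
                            max(1L, floor(rd[2] * s)))
      } else shr <- rendered@pixels
      panel <- array(255L, c(ph, pw, 3L))
      panel <- pasteArray(panel, shr,
                          max(0L, (pw - dim(shr)[2]) %/% 2L),
                          max(0L, (ph - dim(shr)[1]) %/% 2L))
      if (!is.null(res$inset)) {
        ia <- res$inset@pixels
        ia <- strokeRect(ia, 0L, 0L, dim(ia)[2], dim(ia)[1], stroke = 2L)
        panel <- pasteArray(panel, ia, pw - dim(ia)[2], 0L)
      }
      manifest$crop <- list(x = res$ov@crop@x, y = res$ov@crop@y,
                            w = res$ov@crop@w, h = res$ov@crop@h)
      manifest$level <- res$ov@sourceLevel
      manifest$downsample <- res$ov@effectiveDownsample
      manifest$scale_bar_um <- if (is.null(res$ov@scaleBar)) NULL else
        res$ov@scaleBar@lengthUm
    }
  }
  band <- array(255L, c(cfg@labelBandPx, pw, 3L))
  band <- drawText(band, paste(spec@rowLabel, spec@stain), 2L,
                   max(0L, (cfg@labelBandPx - 7L) %/% 2L), 1L)
  cell <- array(255L, c(ph + cfg@labelBandPx, pw, 3L))
  cell <- pasteArray(cell, panel, 0L, 0L)
  cell <- pasteArray(cell, band, 0L, ph)
  manifest$warnings <- warns
  list(image = RasterImage(cell, provenance = paste("panel", spec@rowLabel,
                                                    spec@stain)),
       manifest = manifest, warnings = warns)
}

#' Compose a patient-level figure
#'
#' Renders every panel, places them row-major on a white canvas sized by
#' \code{\link{layoutDims}}, and (when an output path is configured) writes a
#' lossless PNG plus a JSON provenance manifest
#' (\code{<figure>.manifest.json}) recording, per panel, the crop, level,
#' downsample, scale-bar length and warnings. Composition is pure: reruns on
#' identical inputs are byte-identical.
#'
#' @param cfg a \linkS4class{FigureConfig}.
#' @return A list: \code{image} (\linkS4class{RasterImage}), \code{manifest}
#'   (list, one entry per panel in config order), \code{warningCount}.
#' @export
composeFigure <- function(cfg) {
  v <- validObject(cfg, test = TRUE)
  if (!isTRUE(v)) soStop(paste("invalid figure config:", v), "configError")
  dims <- layoutDims(cfg)
  canvas <- array(255L, c(dims[2], dims[1], 3L))
  manifest <- vector("list", length(cfg@panels))
  nwarn <- 0L
  nfail <- 0L
  for (i in seq_along(cfg@panels)) {
    p <- renderPanel(cfg@panels[[i]], cfg)
    if (!is.null(p$manifest$error)) nfail <- nfail + 1L
    nwarn <- nwarn + length(p$warnings)
    row <- (i - 1L) %/% cfg@cols
    col <- (i - 1L) %% cfg@cols
    x <- col * (cfg@panelPx[1] + cfg@gutterPx)
    y <- row * (cfg@panelPx[2] + cfg@labelBandPx + cfg@gutterPx)
    canvas <- pasteArray(canvas, p$image@pixels, x, y)
    manifest[[i]] <- p$manifest
  }
  if (nfail == length(cfg@panels))
    soStop("all panels failed to render", "figureError")
  img <- RasterImage(canvas, provenance = paste("figure", cfg@patientId))
  if (!is.null(cfg@output$path)) {
    writeRasterPng(img, cfg@output$path)
    jsonlite::write_json(
      list(patient_id = cfg@patientId, panels = manifest,
           warning_count = nwarn),
      paste0(cfg@output$path, ".manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(image = img, manifest = manifest, warningCount = nwarn)
}

regionFromList <- function(x) RegionL0(x$x, x$y, x$w, x$h)

#' Read a figure config from YAML or JSON
#'
#' The schema mirrors \linkS4class{FigureConfig} with snake_case keys:
#' \code{patient_id}, \code{cols}, \code{panel_px: [w, h]}, \code{inset_frac},
#' \code{gutter_px}, \code{label_band_px}, \code{scale_bar},
#' \code{output: \{path, format\}} and a \code{panels} list whose entries
#' carry \code{row_label}, \code{stain}, and either \code{slide} or
#' \code{placeholder}, plus optional \code{roi: \{x,y,w,h\}} or
#' \code{roi_um: \{center: [x,y], width_um\}}, optional manual
#' \code{tissue_bbox: \{x,y,w,h\}}, and optional
#' \code{transform: \{rotate90, flip_h\}}.
#'
#' @param path YAML (.yaml/.yml) or JSON config file.
#' @return A \linkS4class{FigureConfig}.
#' @export
readFigureConfig <- function(path) {
  if (!file.exists(path))
    soStop(sprintf("figure config not found: %s", path), "configError")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  panels <- lapply(raw$panels, function(p) {
    tr <- Transform(rotate90 = if (is.null(p$transform$rotate90)) 0L else
                      p$transform$rotate90,
                    flipH = isTRUE(p$transform$flip_h))
    roi <- NULL
    if (!is.null(p$roi)) roi <- regionFromList(p$roi)
    if (!is.null(p$roi_um))
      roi <- list(center = unlist(p$roi_um$center), widthUm = p$roi_um$width_um)
    PanelSpec(rowLabel = p$row_label, stain = p$stain,
              slidePath = if (is.null(p$slide)) NA_character_ else p$slide,
              roi = roi,
              bbox = if (is.null(p$tissue_bbox)) NULL else
                regionFromList(p$tissue_bbox),
              transform = tr,
              placeholderText = if (is.null(p$placeholder)) NA_character_ else
                p$placeholder)
  })
  FigureConfig(
    patientId = raw$patient_id, panels = panels,
    cols = if (is.null(raw$cols)) 4L else raw$cols,
    panelPx = if (is.null(raw$panel_px)) c(400L, 320L) else unlist(raw$panel_px),
    insetFrac = if (is.null(raw$inset_frac)) 0.3 else raw$inset_frac,
    gutterPx = if (is.null(raw$gutter_px)) 10L else raw$gutter_px,
    labelBandPx = if (is.null(raw$label_band_px)) 24L else raw$label_band_px,
    scaleBar = if (is.null(raw$scale_bar)) TRUE else isTRUE(raw$scale_bar),
    output = if (is.null(raw$output)) list() else raw$output)
}
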