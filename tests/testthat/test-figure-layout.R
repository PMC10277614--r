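suiteDir <- NULL
localSuite <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  stainPanelSuite(dir, level0Dims = c(480L, 360L), downsamples = c(1, 4))
}

test_that("layoutDims computes the canvas arithmetic", {
  mk <- function(n, cols, pw = 1000L, ph = 800L, g = 40L, band = 60L) {
    panels <- replicate(n, PanelSpec("S", "CD20", placeholderText = "x"),
                        simplify = FALSE)
    FigureConfig("P", panels, cols = cols, panelPx = c(pw, ph), gutterPx = g,
                 labelBandPx = band)
  }
  expect_equal(layoutDims(mk(6, 3)), c(3080L, 1760L))
  expect_equal(layoutDims(mk(1, 1, g = 0L)), c(1000L, 860L))
  cfg16 <- mk(16, 4)
  expect_equal(layoutDims(cfg16)[2], 4L * 860L + 3L * 40L)  # 4 rows
})

test_that("renderPanel composes overview, single top-right inset and label band", {
  suite <- localSuite()
  cfg <- FigureConfig("P1", list(PanelSpec("S1", "CD20", placeholderText = "x")),
                      cols = 1L, panelPx = c(200L, 160L), insetFrac = 0.4,
                      labelBandPx = 20L)
  spec <- PanelSpec("S1", "CD20", slidePath = suite$path[suite$stain == "CD20"],
                    roi = RegionL0(200, 150, 80, 80))
  p <- renderPanel(spec, cfg)
  d <- dim(imagePixels(p$image))
  expect_equal(d[1:2], c(180L, 200L))
  insetW <- round(0.4 * 200)
  corner <- imagePixels(p$image)[1:insetW, (200 - insetW + 1):200, 1]
  expect_true(all(corner[1, ] == 0L))        # 2 px border, top edge
  expect_true(all(corner[, 1] == 0L))        # left edge of the inset box
  expect_length(p$warnings, 0L)

  noRoi <- renderPanel(PanelSpec("S1", "CD20",
                                 slidePath = suite$path[suite$stain == "CD20"]),
                       cfg)
  expect_false(all(imagePixels(noRoi$image)[1, (200 - insetW + 1):200, 1] == 0L))

  ph <- renderPanel(PanelSpec("S2", "CD3",
                              placeholderText = "Histology sample unavailable"),
                    cfg)
  expect_true(mean(imagePixels(ph$image)[1:160, , ] == 230L) > 0.9)
  expect_equal(ph$manifest$placeholder, "Histology sample unavailable")
})

test_that("an unreadable slide degrades to a placeholder and the figure completes", {
  cfg <- FigureConfig("P1",
                      list(PanelSpec("S1", "CD20", slidePath = "/missing.tiff"),
                           PanelSpec("S1", "CD3",
                                     placeholderText = "Histology sample unavailable")),
                      cols = 2L, panelPx = c(128L, 128L))
  res <- composeFigure(cfg)
  expect_gte(res$warningCount, 1L)
  expect_false(is.null(res$manifest[[1]]$error))
  expect_match(res$manifest[[1]]$error, "missing.tiff")
})

test_that("composeFigure places all 16 stain panels on the grid with a faithful manifest", {
  suite <- localSuite()
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fig.png")
  panels <- lapply(seq_len(nrow(suite)), function(i)
    PanelSpec("X1", suite$stain[i], slidePath = suite$path[i]))
  cfg <- FigureConfig("X1", panels, cols = 4L, panelPx = c(160L, 128L),
                      gutterPx = 8L, labelBandPx = 16L,
                      output = list(path = out, format = "png"))
  res <- composeFigure(cfg)
  expect_equal(unname(imageDims(res$image)), as.integer(layoutDims(cfg)))
  expect_length(res$manifest, 16L)
  expect_equal(vapply(res$manifest, function(m) m$stain, ""), suite$stain)
  expect_equal(res$warningCount, 0L)
  expect_true(file.exists(out))
  mf <- jsonlite::fromJSON(paste0(out, ".manifest.json"), simplifyVector = FALSE)
  expect_length(mf$panels, 16L)
  expect_equal(mf$warning_count, 0L)
})

test_that("figure composition is deterministic: reruns are byte-identical", {
  suite <- localSuite()
  dir <- withr::local_tempdir()
  panels <- lapply(1:4, function(i)
    PanelSpec("X1", suite$stain[i], slidePath = suite$path[i]))
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  cfg1 <- FigureConfig("X1", panels, cols = 2L, panelPx = c(160L, 128L),
                       output = list(path = f1))
  cfg2 <- FigureConfig("X1", panels, cols = 2L, panelPx = c(160L, 128L),
                       output = list(path = f2))
  composeFigure(cfg1)
  composeFigure(cfg2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("figure configs round-trip through YAML", {
  suite <- localSuite()
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    patient_id = "X1", cols = 2, panel_px = c(160, 128), inset_frac = 0.35,
    output = list(path = file.path(dir, "fig.png")),
    panels = list(
      list(row_label = "X1 xenograft", stain = "CD20",
           slide = suite$path[suite$stain == "CD20"],
           roi = list(x = 200, y = 150, w = 80, h = 80),
           transform = list(rotate90 = 1, flip_h = TRUE)),
      list(row_label = "X1 xenograft", stain = "CD3",
           placeholder = "Histology sample unavailable"))), cfgPath)
  cfg <- readFigureConfig(cfgPath)
  expect_s4_class(cfg, "FigureConfig")
  expect_length(cfg@panels, 2L)
  expect_equal(cfg@panels[[1]]@transform@rotate90, 1L)
  expect_true(cfg@panels[[1]]@transform@flipH)
  expect_equal(regionW(cfg@panels[[1]]@roi), 80L)
  expect_equal(cfg@panels[[2]]@placeholderText, "Histology sample unavailable")
  res <- composeFigure(cfg)
  expect_equal(unname(imageDims(res$image)), as.integer(layoutDims(cfg)))
})

test_that("panel specs enforce exactly one of slide / placeholder", {
  expect_error(PanelSpec("S", "CD20"), "exactly one")
  expect_error(PanelSpec("S", "CD20", slidePath = "a.tiff",
                         placeholderText = "x"), "exactly one")
})
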