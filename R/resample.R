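# Raster primitives shared by extraction and layout: exact area-average
# downscaling and the quarter-turn/mirror transform group. Area averaging is
# implemented as two separable overlap-weight matrix products, which is
# deterministic and anti-aliased; nearest-neighbour never appears in outputs.

# Overlap weights mapping nIn source pixels onto nOut output pixels.
# Row i holds the fraction of output interval i covered by each input pixel.
overlapWeights <- function(nIn, nOut) {
  scale <- nIn / nOut
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), nIn)
    js <- j0:j1
    W[i, js] <- pmin(hi, js) - pmax(lo, js - 1)
  }
  W / scale
}

# Area-average resample of an H x W x 3 array (0..255) to outH x outW.
# Intended for downscaling; callers enforce the no-upsampling policy.
areaResample <- function(arr, outH, outW) {
  d <- dim(arr)
  if (outH == d[1] && outW == d[2]) return(arr)
  Wr <- overlapWeights(d[1], outH)
  Wc <- overlapWeights(d[2], outW)
  out <- array(0, c(outH, outW, 3L))
  for (ch in 1:3) out[, , ch] <- Wr %*% arr[, , ch] %*% t(Wc)
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}

# One counter-clockwise quarter turn: (r, c) -> (W + 1 - c, r).
rotateCCW <- function(arr) {
  d <- dim(arr)
  out <- array(arr[, d[2]:1, , drop = FALSE], d)
  aperm(out, c(2, 1, 3))
}

flipHorizontal <- function(arr) arr[, dim(arr)[2]:1, , drop = FALSE]

#' Apply an orientation transform to a raster
#'
#' Mirror first (when requested), then counter-clockwise quarter turns.
#'
#' @param image a \linkS4class{RasterImage}.
#' @param transform a \linkS4class{Transform}.
#' @return A transformed \linkS4class{RasterImage}.
#' @export
applyTransform <- function(image, transform) {
  arr <- image@pixels
  if (transform@flipH) arr <- flipHorizontal(arr)
  r <- transform@rotate90
  while (r > 0L) { arr <- rotateCCW(arr); r <- r - 1L }
  RasterImage(arr, provenance = paste0(image@provenance, " [transformed]"))
}

# Map a half-open rect (x, y, w, h) in image pixel coords through the same
# transform applied to an image of dims (W, H). Returns c(x, y, w, h) plus
# the transformed image dims, so annotation coordinates track the pixels.
transformRect <- function(rect, W, H, transform) {
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  if (transform@flipH) x <- W - (x + w)
  r <- transform@rotate90
  while (r > 0L) {
    # CCW: point (px, py) -> (py, W - 1 - px); half-open rect follows corners
    newx <- y; newy <- W - (x + w)
    x <- newx; y <- newy
    tmp <- w; w <- h; h <- tmp
    tmp <- W; W <- H; H <- tmp
    r <- r - 1L
  }
  list(rect = c(x, y, w, h), W = W, H = H)
}
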