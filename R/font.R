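# Bundled 5x7 bitmap font so rendered labels are byte-identical across
# platforms (no system font dependency). Lowercase maps to uppercase; glyphs
# cover what slide labels and scale bars need.

fontGlyphs <- local({
  g <- list(
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "B" = c("11110","10001","10001","11110","10001","10001","11110"),
    "C" = c("01110","10001","10000","10000","10000","10001","01110"),
    "D" = c("11100","10010","10001","10001","10001","10010","11100"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "G" = c("01110","10001","10000","10111","10001","10001","01111"),
    "H" = c("10001","10001","10001","11111","10001","10001","10001"),
    "I" = c("01110","00100","00100","00100","00100","00100","01110"),
    "J" = c("00111","00010","00010","00010","00010","10010","01100"),
    "K" = c("10001","10010","10100","11000","10100","10010","10001"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "M" = c("10001","11011","10101","10101","10001","10001","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "P" = c("11110","10001","10001","11110","10000","10000","10000"),
    "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "V" = c("10001","10001","10001","10001","10001","01010","00100"),
    "W" = c("10001","10001","10001","10101","10101","10101","01010"),
    "X" = c("10001","10001","01010","00100","01010","10001","10001"),
    "Y" = c("10001","10001","01010","00100","00100","00100","00100"),
    "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11111","00010","00100","00010","00001","10001","01110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("00110","01000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00010","01100"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    "," = c("00000","00000","00000","00000","00000","00100","01000"),
    "-" = c("00000","00000","00000","01110","00000","00000","00000"),
    "+" = c("00000","00100","00100","11111","00100","00100","00000"),
    "/" = c("00001","00010","00010","00100","01000","01000","10000"),
    "&" = c("01100","10010","10100","01000","10101","10010","01101"),
    "%" = c("11001","11010","00010","00100","01000","01011","10011"),
    "(" = c("00010","00100","01000","01000","01000","00100","00010"),
    ")" = c("01000","00100","00010","00010","00010","00100","01000"),
    "#" = c("01010","01010","11111","01010","11111","01010","01010"),
    "µ" = c("00000","00000","10010","10010","10010","11101","10000"),
    " " = c("00000","00000","00000","00000","00000","00000","00000"))
  lapply(g, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]]) == 1L))
    m
  })
})

glyphFor <- function(ch) {
  up <- toupper(ch)
  if (!is.null(fontGlyphs[[ch]])) fontGlyphs[[ch]]
  else if (!is.null(fontGlyphs[[up]])) fontGlyphs[[up]]
  else fontGlyphs[[" "]]
}

# Width in px of text at integer scale (5 px glyph + 1 px spacing).
textWidthPx <- function(text, scale = 1L) {
  n <- nchar(text)
  if (n == 0L) return(0L)
  as.integer((6L * n - 1L) * scale)
}

textHeightPx <- function(scale = 1L) as.integer(7L * scale)

# Draw text into an H x W x 3 array at (x, y) (0-based top-left of the text
# box); pixels outside the array are silently dropped.
drawText <- function(arr, text, x, y, scale = 1L, rgb = c(0L, 0L, 0L)) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  chars <- strsplit(text, "")[[1]]
  cx <- x
  for (ch in chars) {
    g <- glyphFor(ch)
    for (gr in 1:7) for (gc in 1:5) {
      if (!g[gr, gc]) next
      rr <- y + (gr - 1L) * scale
      cc <- cx + (gc - 1L) * scale
      r0 <- max(rr + 1L, 1L); r1 <- min(rr + scale, H)
      c0 <- max(cc + 1L, 1L); c1 <- min(cc + scale, W)
      if (r0 > r1 || c0 > c1) next
      for (chn in 1:3) arr[r0:r1, c0:c1, chn] <- rgb[chn]
    }
    cx <- cx + 6L * scale
  }
  arr
}

# Filled axis-aligned rectangle, half-open pixel rect (x, y, w, h), 0-based.
fillRect <- function(arr, x, y, w, h, rgb) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  r0 <- max(y + 1L, 1L); r1 <- min(y + h, H)
  c0 <- max(x + 1L, 1L); c1 <- min(x + w, W)
  if (r0 > r1 || c0 > c1) return(arr)
  for (ch in 1:3) arr[r0:r1, c0:c1, ch] <- rgb[ch]
  arr
}

# Rectangle outline of given stroke width drawn just inside the rect.
strokeRect <- function(arr, x, y, w, h, stroke = 2L, rgb = c(0L, 0L, 0L)) {
  arr <- fillRect(arr, x, y, w, stroke, rgb)
  arr <- fillRect(arr, x, y + h - stroke, w, stroke, rgb)
  arr <- fillRect(arr, x, y, stroke, h, rgb)
  fillRect(arr, x + w - stroke, y, stroke, h, rgb)
}
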