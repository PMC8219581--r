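# Minimal built-in 5x7 monospace bitmap font, so text stimuli need no
# system font. Glyph coverage: digits, uppercase ASCII and basic
# punctuation; unknown glyphs render as a filled box. Exact glyph metrics
# are cosmetic, not part of the rendering contract.

font5x7 <- local({
  g <- list(
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
  "N" = c("10001","10001","11001","10101","10011","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","10001","11110","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "S" = c("01111","10000","10000","01110","00001","00001","11110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "W" = c("10001","10001","10001","10101","10101","11011","10001"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "Y" = c("10001","10001","01010","00100","00100","00100","00100"),
  "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
  " " = c("00000","00000","00000","00000","00000","00000","00000"),
  "+" = c("00000","00100","00100","11111","00100","00100","00000"),
  "-" = c("00000","00000","00000","11111","00000","00000","00000"),
  "." = c("00000","00000","00000","00000","00000","01100","01100"),
  "," = c("00000","00000","00000","00000","01100","00100","01000"),
  ":" = c("00000","01100","01100","00000","01100","01100","00000"),
  "!" = c("00100","00100","00100","00100","00100","00000","00100"),
  "?" = c("01110","10001","00001","00010","00100","00000","00100"),
  "/" = c("00001","00010","00010","00100","01000","01000","10000"),
  "=" = c("00000","00000","11111","00000","11111","00000","00000"))
  lapply(g, function(rows)
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]] == "1"))))
})

glyph_bitmap <- function(ch) {
  ch <- toupper(ch)
  font5x7[[ch]] %||% matrix(1L, 7, 5)
}

# Render a string centered in a w x h patch; scale = px per font cell.
rasterize_text <- function(text, scale, color, w, h) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  gw <- 6L * scale  # 5 columns + 1 column spacing
  gh <- 7L * scale
  mask <- matrix(0, h, w)
  total_w <- n * gw - scale
  x0 <- as.integer(round((w - total_w) / 2)) + 1L
  y0 <- as.integer(round((h - gh) / 2)) + 1L
  for (i in seq_len(n)) {
    bm <- glyph_bitmap(chars[i])
    big <- bm[rep(1:7, each = scale), rep(1:5, each = scale), drop = FALSE]
    rows <- y0:(y0 + gh - 1L)
    cols <- (x0 + (i - 1L) * gw):(x0 + (i - 1L) * gw + 5L * scale - 1L)
    ok_r <- rows >= 1 & rows <= h
    ok_c <- cols >= 1 & cols <= w
    if (any(ok_r) && any(ok_c))
      mask[rows[ok_r], cols[ok_c]] <-
        pmax(mask[rows[ok_r], cols[ok_c]], big[ok_r, ok_c, drop = FALSE])
  }
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- color[ch] * mask
  list(pixels = px, alpha = mask)
}
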