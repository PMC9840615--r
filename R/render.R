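.color_rgb <- c(white = "FFFFFF", black = "000000", yellow = "FFFF00",
                blue = "0000FF", red = "FF0000")

.rgb_of <- function(label) {
  hex <- .color_rgb[[label]]
  as.numeric(strtoi(substring(hex, c(1, 3, 5), c(2, 4, 6)), 16L)) / 255
}

#' Rasterize a dot array to an RGB image
#'
#' Binary rasterization without anti-aliasing: a pixel belongs to a dot if
#' and only if its center lies within the disc (pixel centers at the integer
#' grid, origin top-left). This keeps segmentation of the rendered image
#' unambiguous.
#'
#' @param array a [dot_array()].
#' @return numeric array height x width x 3 with values in `[0, 1]`.
#' @export
render_array <- function(array) {
  w <- array$panel[1]; h <- array$panel[2]
  bg <- .rgb_of(array$background)
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3))
  for (i in seq_along(array$r)) {
    cx <- array$x[i]; cy <- array$y[i]; r <- array$r[i]
    jj <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ii <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    inside <- outer((ii - cy)^2, (jj - cx)^2, `+`) <= r^2
    fg <- .rgb_of(array$color[i])
    for (ch in 1:3) {
      sub <- img[ii, jj, ch]
      sub[inside] <- fg[ch]
      img[ii, jj, ch] <- sub
    }
  }
  img
}

# overlay the dots of array b onto a rendering of array a (shared panel)
.render_joint <- function(a, b) {
  joint <- dot_array(c(a$x, b$x), c(a$y, b$y), c(a$r, b$r),
                     c(a$color, b$color), a$panel, a$background)
  render_array(joint)
}

#' Render a stimulus pair to PNG files
#'
#' Side-by-side and sequential styles (D1-D3) write one image per panel
#' (`<STIMID>_a.png`, `<STIMID>_b.png`); the two-color intermixed styles
#' (D4, D5) write a single joint image (`<STIMID>.png`).
#'
#' @param pair a `stimulus_pair` from [build_pair()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector with entries `a`, `b`, `joint` (absolute
#'   paths; `NA` where the style writes no such file).
#' @export
render <- function(pair, out_dir) {
  stopifnot(inherits(pair, "stimulus_pair"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- pair$spec$stim_id
  out <- c(a = NA_character_, b = NA_character_, joint = NA_character_)
  if (pair$mode == "mixed") {
    p <- file.path(out_dir, paste0(id, ".png"))
    png::writePNG(.render_joint(pair$array_a, pair$array_b), p)
    out["joint"] <- p
  } else {
    pa <- file.path(out_dir, paste0(id, "_a.png"))
    pb <- file.path(out_dir, paste0(id, "_b.png"))
    png::writePNG(render_array(pair$array_a), pa)
    png::writePNG(render_array(pair$array_b), pb)
    out["a"] <- pa; out["b"] <- pb
  }
  out
}

#' Read an image file as a numeric array
#'
#' @param path PNG file path.
#' @return numeric array height x width x 3 in `[0, 1]` (grayscale files are
#'   expanded to three identical channels; any alpha channel is dropped).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3),
                                     dim = c(dim(img)[1:2], 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Convert an image to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img numeric matrix or height x width x 3 array in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
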