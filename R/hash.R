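#' Area-average image resampling
#'
#' Downscales (or upscales) a grayscale matrix so that each target pixel is
#' the coverage-weighted mean of the source pixels it spans. Exact block
#' averaging when the sizes divide evenly.
#'
#' @param g numeric matrix.
#' @param nr,nc target numbers of rows and columns.
#' @return `nr` x `nc` numeric matrix.
#' @export
resample_area <- function(g, nr, nc) {
  wmat <- function(n_to, n_from) {
    # overlap length of target interval i with source interval j
    w <- matrix(0, n_to, n_from)
    scale <- n_from / n_to
    for (i in seq_len(n_to)) {
      lo <- (i - 1) * scale; hi <- i * scale
      j <- (floor(lo) + 1):ceiling(hi)
      w[i, j] <- pmin(hi, j) - pmax(lo, j - 1)
    }
    w / scale
  }
  wmat(nr, nrow(g)) %*% g %*% t(wmat(nc, ncol(g)))
}

# lower median: for even counts the smaller of the two middle order stats.
# Binary stimulus images are tie-heavy; with a strict '>' threshold this
# keeps the all-equal case all-zero.
.lower_median <- function(v) sort(v)[ceiling(length(v) / 2)]

.as_gray_input <- function(img) {
  if (is.character(img)) img <- read_image(img)
  as_gray(img)
}

#' Average hash (aHash) of an image
#'
#' The image is converted to grayscale, area-averaged to 8x8, and each of
#' the 64 pixels is compared with their mean: bit = 1 iff the pixel is
#' strictly above the mean. Bits are returned in row-major order.
#'
#' @param img matrix, RGB array, or file path.
#' @return integer vector of 64 bits.
#' @export
hash_average <- function(img) {
  g <- resample_area(.as_gray_input(img), 8, 8)
  v <- as.vector(t(g))  # row-major
  as.integer(v > mean(v))
}

# orthonormal DCT-II basis matrix
.dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * (2 * matrix(k, n, n, byrow = TRUE) + 1) *
                           matrix(k, n, n) / (2 * n))
  m[1, ] <- sqrt(1 / n)
  m
}

#' Perceptual hash (pHash) of an image
#'
#' The grayscale image is area-averaged to 32x32, transformed with a 2-D
#' type-II DCT, and the top-left 8x8 block of low-frequency coefficients is
#' kept; bit = 1 iff the coefficient is strictly above the (lower) median of
#' those 64 values. `literal_8x8 = TRUE` instead resamples directly to 8x8
#' and takes the DCT of that, i.e. thresholds the full 8x8 spectrum.
#'
#' @param img matrix, RGB array, or file path.
#' @param literal_8x8 use the 8x8-input variant.
#' @return integer vector of 64 bits (row-major over the 8x8 block).
#' @export
hash_perceptual <- function(img, literal_8x8 = FALSE) {
  g <- .as_gray_input(img)
  if (literal_8x8) {
    g <- resample_area(g, 8, 8)
    d <- .dct_matrix(8)
    coef <- d %*% g %*% t(d)
  } else {
    g <- resample_area(g, 32, 32)
    d <- .dct_matrix(32)
    coef <- (d %*% g %*% t(d))[1:8, 1:8]
  }
  v <- as.vector(t(coef))
  # zap numerically-zero coefficients so exact ties (constant images)
  # survive the strict '>' rule
  v[abs(v) < 1e-9 * max(1, abs(v))] <- 0
  as.integer(v > .lower_median(v))
}

# one-level 2-D orthonormal Haar transform of an even-sized matrix;
# returns the four subbands. dx = detail along x (columns), dy = along y.
.haar2 <- function(g) {
  odd_r <- seq(1, nrow(g), by = 2); odd_c <- seq(1, ncol(g), by = 2)
  lo_r <- (g[odd_r, , drop = FALSE] + g[odd_r + 1, , drop = FALSE]) / sqrt(2)
  hi_r <- (g[odd_r, , drop = FALSE] - g[odd_r + 1, , drop = FALSE]) / sqrt(2)
  band <- function(m) list(
    lo = (m[, odd_c, drop = FALSE] + m[, odd_c + 1, drop = FALSE]) / sqrt(2),
    hi = (m[, odd_c, drop = FALSE] - m[, odd_c + 1, drop = FALSE]) / sqrt(2))
  a <- band(lo_r); d <- band(hi_r)
  list(LL = a$lo, Dx = a$hi, Dy = d$lo, Dxy = d$hi)
}

#' Wavelet hash (wHash) of an image
#'
#' The grayscale image is area-averaged to 8x8 and decomposed with a
#' one-level 2-D Haar transform. All 64 coefficients — approximation (LL)
#' and the three detail subbands, concatenated in the fixed order LL, Dx
#' (detail along x), Dy (detail along y), Dxy — are compared with their
#' (lower) median: bit = 1 iff strictly above.
#'
#' @param img matrix, RGB array, or file path.
#' @return integer vector of 64 bits.
#' @export
hash_wavelet <- function(img) {
  g <- resample_area(.as_gray_input(img), 8, 8)
  h <- .haar2(g)
  v <- c(as.vector(t(h$LL)), as.vector(t(h$Dx)),
         as.vector(t(h$Dy)), as.vector(t(h$Dxy)))
  as.integer(v > .lower_median(v))
}

#' Hamming distance between two equal-length bit vectors
#'
#' @param h1,h2 integer 0/1 vectors of equal length (64 for the hashes
#'   here).
#' @return integer number of differing bits.
#' @export
hamming <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("hash length mismatch: ", length(h1), " vs ", length(h2))
  sum(h1 != h2)
}
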