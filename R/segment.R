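#' Label connected components with 8-connectivity
#'
#' Thin wrapper around [EBImage::bwlabel()] (which uses 4-connectivity)
#' that merges labels touching diagonally, yielding 8-connected components.
#'
#' @param mask logical or 0/1 matrix; nonzero pixels are foreground.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(lab))
  k <- max(lab)
  if (k < 2) return(lab)
  # union-find over diagonal adjacencies
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-1, -1]), as.vector(lab[-nr, -nc])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      a <- find(pairs[p, 1]); b <- find(pairs[p, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(k), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

.new_segmented <- function(lab, image = NULL) {
  k <- max(lab)
  if (k == 0) stop("empty panel: no foreground components")
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  areas <- tabulate(labs, k)
  cx <- unname(rowsum(as.numeric(idx[, 2]), labs)[, 1]) / areas  # x = column
  cy <- unname(rowsum(as.numeric(idx[, 1]), labs)[, 1]) / areas  # y = row
  structure(list(labels = lab, n = k,
                 pixel_areas = areas,
                 centroid_x = cx, centroid_y = cy,
                 pixels_x = idx[, 2], pixels_y = idx[, 1],
                 image = image),
            class = "segmented_array")
}

#' @export
print.segmented_array <- function(x, ...) {
  cat(sprintf("<segmented_array> %d components, %d foreground px\n",
              x$n, sum(x$pixel_areas)))
  invisible(x)
}

#' Segment a single-array panel image
#'
#' Binarizes the image against its background (majority corner color) and
#' labels 8-connected foreground components, one per dot.
#'
#' @param img image array/matrix (see [read_image()]) or a file path.
#' @return A `segmented_array`: component labels, per-component pixel areas
#'   and centroids.
#' @export
segment_panel <- function(img) {
  if (is.character(img)) img <- read_image(img)
  g <- as_gray(img)
  corners <- c(g[1, 1], g[1, ncol(g)], g[nrow(g), 1], g[nrow(g), ncol(g)])
  bg <- as.numeric(names(sort(table(corners), decreasing = TRUE))[1])
  mask <- abs(g - bg) > 0.5
  .new_segmented(label_components(mask), img)
}

#' Segment a two-color intermixed stimulus image
#'
#' Splits the foreground of a mixed-color stimulus (styles D4/D5) into the
#' two color-defined arrays: components are labeled on the whole foreground,
#' then assigned to a color by their dominant pixel color.
#'
#' @param img image array (height x width x 3) or file path.
#' @param colors character vector of the two expected foreground color
#'   labels, e.g. `c("yellow", "blue")`.
#' @return List of two `segmented_array` objects named by color, in the
#'   order given.
#' @export
segment_colors <- function(img, colors) {
  if (is.character(img)) img <- read_image(img)
  stopifnot(length(dim(img)) == 3, length(colors) == 2)
  # background = majority corner color
  corner_cols <- rbind(img[1, 1, ], img[1, dim(img)[2], ],
                       img[dim(img)[1], 1, ], img[dim(img)[1], dim(img)[2], ])
  key <- apply(round(corner_cols, 3), 1, paste, collapse = ",")
  bg <- corner_cols[which.max(tabulate(match(key, unique(key)))), ]
  dev <- sqrt((img[, , 1] - bg[1])^2 + (img[, , 2] - bg[2])^2 +
                (img[, , 3] - bg[3])^2)
  mask <- dev > 0.25
  # every foreground pixel must sit near one of the two expected colors
  targets <- vapply(colors, .rgb_of, numeric(3))
  d2col <- vapply(1:2, function(k)
    sqrt((img[, , 1] - targets[1, k])^2 + (img[, , 2] - targets[2, k])^2 +
           (img[, , 3] - targets[3, k])^2), matrix(0, dim(img)[1], dim(img)[2]))
  nearest <- (d2col[, , 2] < d2col[, , 1]) + 1L
  mind <- pmin(d2col[, , 1], d2col[, , 2])
  if (any(mask & mind > 0.25))
    stop("foreground contains colors other than the two expected")
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0) stop("empty panel: no foreground components")
  # dominant color per component
  labs <- lab[lab > 0]
  comp_col <- round(rowsum(as.numeric(nearest[lab > 0]), labs)[, 1] /
                      tabulate(labs, k))
  out <- lapply(1:2, function(kk) {
    keep <- which(comp_col == kk)
    if (!length(keep)) stop("no components of color ", colors[kk])
    sub <- matrix(match(lab, keep, nomatch = 0L), nrow(lab))
    .new_segmented(sub, img)
  })
  names(out) <- colors
  out
}

#' Render the color-isolated view of a segmented array
#'
#' Builds the grayscale image in which this array's foreground pixels are
#' white and everything else black; used as the per-array input to the image
#' hashes for two-color intermixed stimuli.
#'
#' @param seg a `segmented_array`.
#' @return numeric matrix in `{0, 1}`.
#' @export
isolate_mask <- function(seg) {
  m <- matrix(0, nrow(seg$labels), ncol(seg$labels))
  m[seg$labels > 0] <- 1
  m
}
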