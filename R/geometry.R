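#' Convex hull area of a point set
#'
#' Area of the convex hull by the shoelace formula on the hull vertices
#' returned by [grDevices::chull()]. Degenerate (collinear or single-point)
#' sets return 0.
#'
#' @param x,y point coordinates.
#' @return hull area (px^2).
#' @export
convex_hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Geometric properties of a segmented dot array
#'
#' Computes the five visual property families of one array:
#' \itemize{
#'   \item areas: per-dot pixel counts (total, mean, SD);
#'   \item perimeters: from the equivalent-circle radius
#'     \eqn{r_i = \sqrt{A_i/\pi}}, \eqn{P_i = 2\pi r_i} — so perimeter
#'     ratios between arrays reduce to radius (diameter) ratios exactly;
#'   \item convex hull: hull of all dot pixels, area by the shoelace formula;
#'   \item density: hull area per dot and hull area per unit total dot area;
#'   \item pairwise distances: Euclidean distances between all
#'     \eqn{\binom{n}{2}} dot centroids (total, mean, SD).
#' }
#' Distance statistics for a single-dot array are undefined and returned as
#' `NA`. SDs are population SDs by default (divide by n), switchable to
#' sample SDs.
#'
#' @param seg a `segmented_array` (see [segment_panel()]).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list of class `array_properties` with fields `n_dots`,
#'   `area_total`, `area_mean`, `area_sd`, `perim_total`, `perim_mean`,
#'   `perim_sd`, `convex_hull_area`, `ch_per_dot`, `ch_per_area`,
#'   `dist_total`, `dist_mean`, `dist_sd`.
#' @export
array_properties <- function(seg, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(seg, "segmented_array"))
  psd <- function(v) {
    if (length(v) < 2) return(if (sd_type == "population") 0 else NA_real_)
    if (sd_type == "sample") stats::sd(v)
    else sqrt(mean((v - mean(v))^2))
  }
  areas <- as.numeric(seg$pixel_areas)
  r_eq <- sqrt(areas / pi)
  perims <- 2 * pi * r_eq
  hull <- convex_hull_area(seg$pixels_x, seg$pixels_y)
  if (seg$n >= 2) {
    d <- as.numeric(stats::dist(cbind(seg$centroid_x, seg$centroid_y)))
    dist_total <- sum(d); dist_mean <- mean(d); dist_sd <- psd(d)
  } else {
    dist_total <- dist_mean <- dist_sd <- NA_real_
  }
  structure(list(
    n_dots = seg$n,
    area_total = sum(areas), area_mean = mean(areas), area_sd = psd(areas),
    perim_total = sum(perims), perim_mean = mean(perims),
    perim_sd = psd(perims),
    convex_hull_area = hull, ch_per_dot = hull / seg$n,
    ch_per_area = hull / sum(areas),
    dist_total = dist_total, dist_mean = dist_mean, dist_sd = dist_sd
  ), class = "array_properties")
}

#' Per-stimulus feature vector from two arrays
#'
#' The dot ratio is the smaller dot count divided by the larger. Every visual
#' index is the ratio fewer-dot array / more-dot array; orientation is
#' determined by the dot counts. With equal counts (outside the printed
#' designs) the input order is used, with a warning. A zero denominator
#' yields `NA` for that index.
#'
#' @param props_a,props_b [array_properties()] of the two arrays.
#' @param hashes optional named numeric vector/list with Hamming distances
#'   `hash_avg`, `hash_perc`, `hash_wav`.
#' @return Named list: `dot_ratio`, the 12 visual ratio indices, and the 3
#'   hash distances (`NA` if not supplied).
#' @export
feature_vector <- function(props_a, props_b, hashes = NULL) {
  stopifnot(inherits(props_a, "array_properties"),
            inherits(props_b, "array_properties"))
  if (props_a$n_dots == props_b$n_dots) {
    warning("equal dot counts: orientation falls back to array order")
    fewer <- props_a; more <- props_b
  } else if (props_a$n_dots < props_b$n_dots) {
    fewer <- props_a; more <- props_b
  } else {
    fewer <- props_b; more <- props_a
  }
  ratio_of <- function(field) {
    num <- fewer[[field]]; den <- more[[field]]
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  fields <- c(perim_total = "perim_total", perim_mean = "perim_mean",
              perim_sd = "perim_sd", area_total = "area_total",
              area_mean = "area_mean", area_sd = "area_sd",
              convex_hull = "convex_hull_area", ch_per_dot = "ch_per_dot",
              ch_per_area = "ch_per_area", dist_total = "dist_total",
              dist_mean = "dist_mean", dist_sd = "dist_sd")
  out <- c(list(dot_ratio = fewer$n_dots / more$n_dots),
           lapply(fields, ratio_of))
  for (h in .hash_indices)
    out[[h]] <- if (!is.null(hashes) && !is.null(hashes[[h]]))
      as.numeric(hashes[[h]]) else NA_real_
  out
}
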