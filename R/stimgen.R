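#' Construct a dot array
#'
#' A dot array is one comparison panel: dot centers and radii in continuous
#' pixel coordinates (origin top-left, x rightward, y downward), a color label
#' per dot, and the panel geometry.
#'
#' @param x,y,r numeric vectors of equal length: dot centers and radii (px).
#' @param color character vector (recycled) of dot color labels; one of
#'   `"white"`, `"black"`, `"yellow"`, `"blue"`, `"red"`.
#' @param panel integer vector `c(width, height)` in pixels.
#' @param background background color label.
#' @return An object of class `dot_array`.
#' @export
dot_array <- function(x, y, r, color = "white", panel = c(400L, 400L),
                      background = "black") {
  stopifnot(length(x) == length(y), length(x) == length(r), length(x) >= 1)
  if (any(r <= 0)) stop("all dot radii must be > 0")
  color <- rep_len(color, length(x))
  bad <- x - r < 0 | x + r > panel[1] | y - r < 0 | y + r > panel[2]
  if (any(bad)) stop("dot disc extends outside the panel")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), r = as.numeric(r),
         color = color, panel = as.integer(panel), background = background),
    class = "dot_array"
  )
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("<dot_array> %d dots, panel %dx%d px, total area %.1f px^2\n",
              length(x$r), x$panel[1], x$panel[2], sum(pi * x$r^2)))
  invisible(x)
}

#' Number of dots in an array
#' @param array a `dot_array`.
#' @return integer count.
#' @export
n_dots <- function(array) length(array$r)

#' Geometry configuration for stimulus generation
#'
#' Bundles the free geometric parameters of the generator. The panel size and
#' area budget are not properties of the designs themselves (only area
#' *ratios* between the two arrays are controlled); they set the rendering
#' scale.
#'
#' @param panel panel size `c(width, height)` in pixels per array.
#' @param total_area reference total dot area budget per array (px^2).
#' @param dispersion multiplicative jitter applied to dot radii before
#'   rescaling, in `[0, 1)`; 0 gives homogeneous dots.
#' @param min_gap minimum edge-to-edge gap between dot discs (px).
#' @param max_attempts rejection-sampling budget per array layout.
#' @param n_layout_retries fresh layouts tried (radii kept) before giving up.
#' @param min_radius smallest admissible dot radius (px).
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(panel = c(400L, 400L), total_area = 20000,
                            dispersion = 0.3, min_gap = 2,
                            max_attempts = 10000L, n_layout_retries = 20L,
                            min_radius = 2) {
  stopifnot(total_area > 0, dispersion >= 0, dispersion < 1, min_gap >= 0)
  structure(list(panel = as.integer(panel), total_area = total_area,
                 dispersion = dispersion, min_gap = min_gap,
                 max_attempts = as.integer(max_attempts),
                 n_layout_retries = as.integer(n_layout_retries),
                 min_radius = min_radius),
            class = "geometry_config")
}

#' Solve dot radii under a total-area constraint
#'
#' Draws `n` radii whose discs sum to `total_area` exactly (up to floating
#' point): radii are jittered multiplicatively by `dispersion`, then rescaled
#' so that the summed disc area matches the target. Uses the session RNG.
#'
#' @param n number of dots (>= 1).
#' @param total_area target summed disc area in px^2.
#' @param dispersion radius jitter fraction in `[0, 1)`; each radius is
#'   multiplied by a Uniform(1 - dispersion, 1 + dispersion) factor before
#'   rescaling.
#' @param min_radius smallest admissible radius; infeasible targets error.
#' @return numeric vector of `n` radii (px).
#' @export
solve_radii <- function(n, total_area, dispersion = 0, min_radius = 2) {
  stopifnot(n >= 1, total_area > 0, dispersion >= 0, dispersion < 1)
  if (total_area < n * pi * min_radius^2)
    stop(sprintf(
      "total_area %.1f px^2 infeasible for %d dots at minimum radius %.1f",
      total_area, n, min_radius))
  base <- sqrt(total_area / (n * pi))
  r <- base * stats::runif(n, 1 - dispersion, 1 + dispersion)
  r <- r * sqrt(total_area / sum(pi * r^2))
  if (any(r < min_radius)) {
    # clamp and rescale the rest; one pass suffices for dispersion < 1
    r[r < min_radius] <- min_radius
    free <- r > min_radius
    if (any(free)) {
      rem <- total_area - sum(pi * r[!free]^2)
      if (rem <= 0) stop("total_area infeasible after minimum-radius clamp")
      r[free] <- r[free] * sqrt(rem / sum(pi * r[free]^2))
    }
  }
  r
}

#' Place dots in a panel by rejection sampling
#'
#' Dots are placed largest-first, uniformly at random, rejecting positions
#' that overlap an already-placed disc (edge gap < `min_gap`) or the panel
#' border. Centers are kept at least `r + 1` px from every edge so the full
#' disc covers only in-panel pixel centers.
#'
#' @param radii numeric vector of dot radii (px).
#' @param panel `c(width, height)` in pixels.
#' @param min_gap minimum edge-to-edge disc gap (px).
#' @param max_attempts total placement attempts before failing.
#' @param color color label(s) for the dots.
#' @return a [dot_array()].
#' @export
place_dots <- function(radii, panel = c(400L, 400L), min_gap = 2,
                       max_attempts = 10000L, color = "white") {
  stopifnot(length(radii) >= 1, min_gap >= 0)
  ord <- order(radii, decreasing = TRUE)
  r <- radii[ord]
  color <- rep_len(color, length(radii))[ord]
  if (any(2 * r + 2 > panel[1] | 2 * r + 2 > panel[2]))
    stop("panel too small for the largest dot")
  x <- y <- numeric(length(r))
  attempts <- 0L
  for (i in seq_along(r)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("dot placement failed after %d attempts (%d/%d placed)",
                     max_attempts, i - 1L, length(r)))
      cx <- stats::runif(1, r[i] + 1, panel[1] - r[i])
      cy <- stats::runif(1, r[i] + 1, panel[2] - r[i])
      if (i == 1L) break
      j <- seq_len(i - 1L)
      d2 <- (x[j] - cx)^2 + (y[j] - cy)^2
      if (all(d2 >= (r[j] + r[i] + min_gap)^2)) break
    }
    x[i] <- cx; y[i] <- cy
  }
  dot_array(x, y, r, color = color, panel = panel)
}

.style_colors <- list(
  D1 = list(fg = c("white", "white"), bg = "black", mode = "panels"),
  D2 = list(fg = c("white", "white"), bg = "black", mode = "panels"),
  D3 = list(fg = c("black", "black"), bg = "white", mode = "sequential"),
  D4 = list(fg = c("yellow", "blue"), bg = "black", mode = "mixed"),
  D5 = list(fg = c("red", "blue"), bg = "black", mode = "mixed")
)

.area_conditions <- c("equal_total", "equal_mean", "area_ratio_2_1",
                      "area_ratio_1_1", "area_ratio_1_2", "area_ratio_2_3",
                      "area_ratio_3_2", "approx_1_1")

#' Specification of one stimulus pair
#'
#' @param style dataset style, `"D1"` to `"D5"`.
#' @param n_a,n_b dot counts of the two arrays (array b may not equal a).
#' @param area_condition one of `"equal_total"`, `"equal_mean"`,
#'   `"area_ratio_X_Y"` (larger-count array : smaller-count array) or
#'   `"approx_1_1"`.
#' @param stim_id stimulus identifier.
#' @return A list of class `pair_spec`.
#' @export
pair_spec <- function(style, n_a, n_b, area_condition, stim_id = NA_character_) {
  style <- match.arg(style, names(.style_colors))
  area_condition <- match.arg(area_condition, .area_conditions)
  stopifnot(n_a >= 1, n_b >= 1)
  ns <- min(n_a, n_b); nl <- max(n_a, n_b)
  rng <- .style_count_rules(style)
  if (ns < rng$count[1] || nl > rng$count[2])
    stop(sprintf("counts (%d, %d) outside the %s range [%d, %d]",
                 n_a, n_b, style, rng$count[1], rng$count[2]))
  if (!rng$ratio_ok(ns, nl))
    stop(sprintf("count ratio %d:%d = %.3f outside the %s design",
                 nl, ns, nl / ns, style))
  structure(list(style = style, n_a = as.integer(n_a), n_b = as.integer(n_b),
                 area_condition = area_condition, stim_id = stim_id),
            class = "pair_spec")
}

# per-style admissible counts and larger:smaller ratio rule
.style_count_rules <- function(style) {
  switch(style,
    D1 = list(count = c(5L, 32L),
              ratio_ok = function(ns, nl) {
                rt <- nl / ns; rt >= 1.12 - 1e-9 && rt <= 2.00 + 1e-9
              }),
    D2 = list(count = c(5L, 12L),
              ratio_ok = function(ns, nl)
                any(abs(nl / ns - c(3 / 2, 7 / 5, 4 / 3)) < 1e-9)),
    D3 = list(count = c(7L, 14L), ratio_ok = function(ns, nl) nl > ns),
    D4 = list(count = c(5L, 16L),
              ratio_ok = function(ns, nl) {
                rt <- nl / ns; rt >= 1.12 - 1e-9 && rt <= 2.00 + 1e-9
              }),
    D5 = list(count = c(5L, 16L),
              ratio_ok = function(ns, nl)
                any(abs(ns / nl - c(1/2, 2/3, 3/4, 5/6, 7/8)) < 1e-9))
  )
}

# total dot areas (small-count array, large-count array) for a condition
.condition_totals <- function(area_condition, ns, nl, total_area) {
  switch(area_condition,
    equal_total = c(total_area, total_area),
    # equal mean dot area: fix the per-dot area at total_area / nl so the
    # larger array stays within the budget
    equal_mean = total_area / nl * c(ns, nl),
    approx_1_1 = {
      rt <- stats::runif(1, 0.96, 1.04)  # large : small total-area ratio
      c(2 * total_area / (1 + rt), 2 * total_area * rt / (1 + rt))
    },
    {
      xy <- as.numeric(strsplit(sub("area_ratio_", "", area_condition),
                                "_")[[1]])
      # larger-count array : smaller-count array = x : y
      c(2 * total_area * xy[2], 2 * total_area * xy[1]) / sum(xy)
    })
}

#' Build a stimulus pair from a specification
#'
#' Realizes the area condition (equal total area, equal mean dot area, a fixed
#' total-area ratio, or an approximately 1:1 total area), draws radii, and
#' places the dots: in two separate panels for side-by-side and sequential
#' styles (D1-D3) or intermixed with no overlap in one shared panel for the
#' two-color styles (D4, D5). On a layout failure the placement is retried
#' with fresh positions (same radii).
#'
#' @param spec a [pair_spec()].
#' @param geometry a [geometry_config()].
#' @return A list of class `stimulus_pair` with elements `spec`, `array_a`,
#'   `array_b` and `mode` (`"panels"`, `"sequential"` or `"mixed"`).
#' @export
build_pair <- function(spec, geometry = geometry_config()) {
  stopifnot(inherits(spec, "pair_spec"))
  sc <- .style_colors[[spec$style]]
  ns <- min(spec$n_a, spec$n_b); nl <- max(spec$n_a, spec$n_b)
  tot <- .condition_totals(spec$area_condition, ns, nl, geometry$total_area)
  tot_ab <- if (spec$n_a <= spec$n_b) tot else rev(tot)
  r_a <- solve_radii(spec$n_a, tot_ab[1], geometry$dispersion,
                     geometry$min_radius)
  r_b <- solve_radii(spec$n_b, tot_ab[2], geometry$dispersion,
                     geometry$min_radius)
  place <- function(radii, color) {
    for (k in seq_len(geometry$n_layout_retries)) {
      arr <- tryCatch(
        place_dots(radii, geometry$panel, geometry$min_gap,
                   geometry$max_attempts, color = color),
        error = function(e) e)
      if (!inherits(arr, "error")) return(arr)
    }
    stop(arr)
  }
  if (sc$mode == "mixed") {
    joint <- place(c(r_a, r_b), c(rep(sc$fg[1], spec$n_a),
                                  rep(sc$fg[2], spec$n_b)))
    ia <- joint$color == sc$fg[1]
    array_a <- dot_array(joint$x[ia], joint$y[ia], joint$r[ia], sc$fg[1],
                         geometry$panel, sc$bg)
    array_b <- dot_array(joint$x[!ia], joint$y[!ia], joint$r[!ia], sc$fg[2],
                         geometry$panel, sc$bg)
  } else {
    array_a <- place(r_a, sc$fg[1])
    array_b <- place(r_b, sc$fg[2])
    array_a$background <- array_b$background <- sc$bg
  }
  structure(list(spec = spec, array_a = array_a, array_b = array_b,
                 mode = sc$mode),
            class = "stimulus_pair")
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat(sprintf("<stimulus_pair> %s %s: %d vs %d dots (%s)\n",
              x$spec$style, x$spec$stim_id, x$spec$n_a, x$spec$n_b,
              x$spec$area_condition))
  invisible(x)
}

# count-pair grid with larger:smaller ratio inside [lo, hi]
.ratio_grid <- function(nmin, nmax, lo = 1.12, hi = 2.00) {
  g <- expand.grid(ns = nmin:nmax, nl = nmin:nmax)
  g <- g[g$nl > g$ns, ]
  rt <- g$nl / g$ns
  g[rt >= lo - 1e-9 & rt <= hi + 1e-9, ]
}

# count pairs at an exact small:large rational ratio within [nmin, nmax]
.exact_ratio_pairs <- function(num, den, nmin, nmax) {
  k <- seq_len(nmax)
  ns <- num * k; nl <- den * k
  ok <- ns >= nmin & nl <= nmax
  data.frame(ns = ns[ok], nl = nl[ok])
}

#' Generate a full stimulus set in one of the five designs
#'
#' The five designs: D1, 120 side-by-side pairs, 5-32 dots, larger:smaller
#' count ratio in 1.12-2.00, 60 equal-total-area and 60 equal-mean-area
#' pairs; D2, 36 pairs, 5-12 dots, count ratios 2:3, 5:7 and 3:4, total-area
#' ratios 2:1, 1:1 and 1:2 with 12 pairs each; D3, 138 sequential pairs, 7-14
#' dots, total-area ratios 2:3, 1:1 and 3:2 (46 each); D4, 100 two-color
#' (yellow/blue) intermixed stimuli, 5-16 dots per color, 50 equal-total and
#' 50 equal-mean; D5, 100 two-color (red/blue) intermixed stimuli, 5-16 dots,
#' color-count ratios 1:2, 2:3, 3:4, 5:6 and 7:8 (20 each) with total-area
#' ratio close to 1:1.
#'
#' @param style `"D1"` to `"D5"` (or 1-5).
#' @param seed integer seed; the full set (geometry included) is a
#'   deterministic function of it.
#' @param out_dir if non-`NULL`, images are rendered there and a stimulus
#'   list CSV (`stimlist_<style>.csv`) is written.
#' @param geometry a [geometry_config()].
#' @return A list with `pairs` (list of `stimulus_pair`) and `stimlist`
#'   (data frame: STIMID, style, file_a, file_b, file_joint, n_a, n_b,
#'   area_condition, seed).
#' @export
generate_dataset <- function(style, seed, out_dir = NULL,
                             geometry = geometry_config()) {
  if (is.numeric(style)) style <- paste0("D", style)
  style <- match.arg(style, names(.style_colors))
  set.seed(as.integer(seed))
  specs <- switch(style,
    D1 = {
      grid <- .ratio_grid(5L, 32L)
      idx <- sample.int(nrow(grid), 120, replace = TRUE)
      cond <- rep(c("equal_total", "equal_mean"), each = 60)
      Map(function(i, cc, k) pair_spec("D1", grid$ns[i], grid$nl[i], cc,
                                       sprintf("D1_%03d", k)),
          idx, cond, seq_len(120))
    },
    D2 = {
      ratios <- list(c(2, 3), c(5, 7), c(3, 4))
      conds <- c("area_ratio_2_1", "area_ratio_1_1", "area_ratio_1_2")
      specs <- list(); k <- 0L
      for (cc in conds) for (rep_i in 1:4) for (rr in ratios) {
        pp <- .exact_ratio_pairs(rr[1], rr[2], 5L, 12L)
        i <- sample.int(nrow(pp), 1)
        k <- k + 1L
        specs[[k]] <- pair_spec("D2", pp$ns[i], pp$nl[i], cc,
                                sprintf("D2_%03d", k))
      }
      specs
    },
    D3 = {
      grid <- expand.grid(ns = 7:14, nl = 7:14)
      grid <- grid[grid$nl > grid$ns, ]
      conds <- rep(c("area_ratio_2_3", "area_ratio_1_1", "area_ratio_3_2"),
                   each = 46)
      idx <- sample.int(nrow(grid), 138, replace = TRUE)
      Map(function(i, cc, k) pair_spec("D3", grid$ns[i], grid$nl[i], cc,
                                       sprintf("D3_%03d", k)),
          idx, conds, seq_len(138))
    },
    D4 = {
      grid <- .ratio_grid(5L, 16L)
      idx <- sample.int(nrow(grid), 100, replace = TRUE)
      cond <- rep(c("equal_total", "equal_mean"), each = 50)
      Map(function(i, cc, k) pair_spec("D4", grid$ns[i], grid$nl[i], cc,
                                       sprintf("D4_%03d", k)),
          idx, cond, seq_len(100))
    },
    D5 = {
      ratios <- list(c(1, 2), c(2, 3), c(3, 4), c(5, 6), c(7, 8))
      specs <- list(); k <- 0L
      for (rr in ratios) for (rep_i in 1:20) {
        pp <- .exact_ratio_pairs(rr[1], rr[2], 5L, 16L)
        i <- sample.int(nrow(pp), 1)
        k <- k + 1L
        specs[[k]] <- pair_spec("D5", pp$ns[i], pp$nl[i], "approx_1_1",
                                sprintf("D5_%03d", k))
      }
      specs
    })
  pairs <- lapply(specs, build_pair, geometry = geometry)
  stimlist <- data.frame(
    STIMID = vapply(specs, function(s) s$stim_id, character(1)),
    style = style,
    file_a = "", file_b = "", file_joint = "",
    n_a = vapply(specs, function(s) s$n_a, integer(1)),
    n_b = vapply(specs, function(s) s$n_b, integer(1)),
    area_condition = vapply(specs, function(s) s$area_condition,
                            character(1)),
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(pairs)) {
      paths <- render(pairs[[i]], out_dir)
      stimlist$file_a[i] <- if (!is.na(paths["a"])) basename(paths["a"]) else ""
      stimlist$file_b[i] <- if (!is.na(paths["b"])) basename(paths["b"]) else ""
      stimlist$file_joint[i] <-
        if (!is.na(paths["joint"])) basename(paths["joint"]) else ""
    }
    write_stimlist(stimlist, file.path(out_dir,
                                       sprintf("stimlist_%s.csv", style)))
  }
  list(pairs = pairs, stimlist = stimlist)
}
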