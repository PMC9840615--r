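# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# convex hull area by gift wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- order(pts[, 2], pts[, 1])[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      further <- sum((pts[j, ] - pts[cur, ])^2) >
        sum((pts[cand, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && further)) cand <- j
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping did not terminate")
  }
  xs <- pts[hull, 1]; ys <- pts[hull, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# Hamming distance by explicit XOR bit loop
oracle_hamming <- function(h1, h2) {
  d <- 0L
  for (i in seq_along(h1)) d <- d + bitwXor(h1[i], h2[i])
  d
}

# pairwise-distance statistics by an explicit O(n^2) double loop
oracle_dist_stats <- function(x, y) {
  d <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  list(total = sum(d), mean = mean(d),
       sd_pop = sqrt(mean((d - mean(d))^2)))
}

# build a segmented_array from isolated single-pixel dots at integer
# coordinates (x = column, y = row); pixels must be pairwise non-adjacent
seg_from_points <- function(x, y, pad = 2) {
  m <- matrix(0, max(y) + pad, max(x) + pad)
  m[cbind(y, x)] <- 1
  numerosity::segment_panel(m_to_img(m))
}

m_to_img <- function(m) array(rep(m, 3), dim = c(dim(m), 3))

# a small in-memory stimulus list (no images) for behavior simulations
design_stimlist <- function(n_pairs = 60, seed = 1) {
  set.seed(seed)
  ns <- sample(5:16, n_pairs, replace = TRUE)
  mult <- sample(c(1.2, 1.4, 1.6, 1.8, 2.0), n_pairs, replace = TRUE)
  nl <- pmin(32L, pmax(ns + 1L, round(ns * mult)))
  data.frame(STIMID = sprintf("S%03d", seq_len(n_pairs)),
             n_a = ns, n_b = nl, stringsAsFactors = FALSE)
}
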