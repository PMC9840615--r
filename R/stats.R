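#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha family-wise error rate (e.g. 0.05).
#' @param m number of tests in the family (>= 1).
#' @return per-test significance threshold `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  if (m < 1) stop("family size m must be >= 1")
  family_alpha / m
}

#' Pearson correlations of every visual property with the dot ratio
#'
#' For each of the 15 visual indices (12 geometric ratio indices and 3 hash
#' distances), the Pearson correlation with `dot_ratio` and its two-sided
#' p-value (t distribution, df = n - 2). Rows with a missing value in either
#' column are dropped pairwise; zero-variance properties are reported with
#' `NA` and a reason.
#'
#' @param features feature table (see [extract_dataset()]).
#' @param alpha per-test threshold for the significance flag; use
#'   [bonferroni_alpha()] for a corrected family, e.g. `0.05 / 75` for the
#'   15-property x 5-dataset family.
#' @return Data frame: `property`, `r`, `p`, `n`, `significant`, `note`.
#' @export
correlate_with_ratio <- function(features, alpha = bonferroni_alpha(0.05, 75)) {
  props <- c(.visual_indices, .hash_indices)
  out <- lapply(props, function(pn) {
    ok <- stats::complete.cases(features[[pn]], features$dot_ratio)
    x <- features[[pn]][ok]; y <- features$dot_ratio[ok]
    if (sum(ok) < 3)
      return(data.frame(property = pn, r = NA_real_, p = NA_real_,
                        n = sum(ok), significant = NA,
                        note = "fewer than 3 complete rows"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(property = pn, r = NA_real_, p = NA_real_,
                        n = sum(ok), significant = NA,
                        note = "zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(property = pn, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), significant = ct$p.value < alpha, note = "")
  })
  do.call(rbind, out)
}

#' Explained variance of one predictor on one outcome
#'
#' Ordinary least squares of the outcome on a single predictor plus
#' intercept; R-squared (the squared Pearson correlation) and the model
#' F-test p-value.
#'
#' @param x predictor vector.
#' @param y outcome vector.
#' @return List: `r2`, `p`, `n`.
#' @export
r2_single <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete rows")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  pval <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
  list(r2 = unname(sm$r.squared), p = unname(pval), n = length(x))
}

#' Incremental R-squared of dot ratio after control predictors
#'
#' Hierarchical regression: model A regresses the outcome on the control
#' column(s) (plus dataset dummy indicators, when pooling datasets); model B
#' adds the dot ratio. Returns the increment `R2_B - R2_A` and the 1-df
#' incremental F-test p-value
#' \deqn{F = \frac{R^2_B - R^2_A}{(1 - R^2_B)/(n - p_B - 1)}.}
#' A control collinear with the dot ratio (|r| = 1) gives a zero increment
#' with a warning.
#'
#' @param control numeric vector or matrix/data frame of control columns.
#' @param dot_ratio dot-ratio vector.
#' @param outcome outcome vector.
#' @param dataset optional factor of dataset labels, entered as k - 1 dummy
#'   indicators in both models.
#' @return List: `delta_r2`, `p`, `r2_control`, `r2_full`, `n`.
#' @export
delta_r2 <- function(control, dot_ratio, outcome, dataset = NULL) {
  control <- as.matrix(control)
  ok <- stats::complete.cases(control, dot_ratio, outcome)
  if (!is.null(dataset)) ok <- ok & !is.na(dataset)
  control <- control[ok, , drop = FALSE]
  dot_ratio <- dot_ratio[ok]; outcome <- outcome[ok]
  n <- length(outcome)
  if (n < ncol(control) + 3) stop("too few complete rows")
  dat <- data.frame(.y = outcome, control, .ratio = dot_ratio)
  rhs_a <- paste(colnames(dat)[-c(1, ncol(dat))], collapse = " + ")
  if (!is.null(dataset)) {
    dat$.dataset <- factor(dataset[ok])
    if (nlevels(dat$.dataset) > 1) rhs_a <- paste(rhs_a, "+ .dataset")
  }
  fit_a <- stats::lm(stats::as.formula(paste(".y ~", rhs_a)), data = dat)
  fit_b <- stats::update(fit_a, . ~ . + .ratio)
  r2a <- summary(fit_a)$r.squared
  r2b <- summary(fit_b)$r.squared
  # collinearity: dot ratio adds no rank
  if (fit_b$rank == fit_a$rank || is.na(stats::coef(fit_b)[".ratio"])) {
    warning("dot ratio collinear with the control predictors; delta R2 = 0")
    return(list(delta_r2 = 0, p = NA_real_, r2_control = r2a, r2_full = r2b,
                n = n))
  }
  d <- max(0, r2b - r2a)
  df2 <- n - fit_b$rank
  f <- (d / 1) / ((1 - r2b) / df2)
  list(delta_r2 = d, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       r2_control = r2a, r2_full = r2b, n = n)
}
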