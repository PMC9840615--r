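test_that("Bonferroni thresholds reduce to family_alpha / m", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 75) * 75, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})

test_that("correlations with dot ratio match the closed-form oracle", {
  set.seed(41)
  n <- 120
  feat <- as.data.frame(matrix(rnorm(n * 15), n,
                               dimnames = list(NULL, c(
    "perim_total", "perim_mean", "perim_sd", "area_total", "area_mean",
    "area_sd", "convex_hull", "ch_per_dot", "ch_per_area", "dist_total",
    "dist_mean", "dist_sd", "hash_avg", "hash_perc", "hash_wav"))))
  feat$dot_ratio <- runif(n, 0.5, 0.9)
  feat$perim_total <- feat$dot_ratio + rnorm(n, 0, 0.2)
  feat$perim_mean <- -feat$dot_ratio + 3
  ct <- correlate_with_ratio(feat)
  # closed-form Pearson: cov / (sd * sd), population or sample cancels
  r_oracle <- function(x, y)
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  expect_equal(ct$r[ct$property == "perim_total"],
               r_oracle(feat$perim_total, feat$dot_ratio),
               tolerance = 1e-12)
  expect_equal(ct$r[ct$property == "perim_mean"], -1)
  feat$dist_mean <- feat$dot_ratio
  ct2 <- correlate_with_ratio(feat)
  expect_equal(ct2$r[ct2$property == "dist_mean"], 1)
  expect_lt(ct2$p[ct2$property == "dist_mean"], 1e-100)
  # zero-variance property reported missing with a reason
  feat$hash_avg <- 7
  ct3 <- correlate_with_ratio(feat)
  expect_true(is.na(ct3$r[ct3$property == "hash_avg"]))
  expect_match(ct3$note[ct3$property == "hash_avg"], "zero variance")
})

test_that("r2_single is the squared correlation with an F-test p", {
  set.seed(43)
  x <- rnorm(50); y <- 2 * x + 1
  r <- suppressWarnings(r2_single(x, y))  # exact fit by construction
  expect_equal(r$r2, 1)
  y2 <- rnorm(1000); x2 <- rnorm(1000)
  r2 <- r2_single(x2, y2)
  expect_lt(r2$r2, 0.01)
  expect_equal(r2$r2, cor(x2, y2)^2, tolerance = 1e-12)
  expect_error(r2_single(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("delta_r2 obeys the orthogonal-decomposition oracle", {
  set.seed(47)
  n <- 200
  ctrl <- rnorm(n)
  ratio <- rnorm(n)
  ratio <- residuals(lm(ratio ~ ctrl))  # orthogonalize against control
  y <- 0.5 * ctrl + 0.8 * ratio + rnorm(n)
  d <- delta_r2(ctrl, ratio, y)
  expect_equal(d$delta_r2, cor(ratio, y)^2, tolerance = 1e-10)
  # outcome equal to the control: nothing left to explain
  expect_equal(suppressWarnings(delta_r2(ctrl, ratio, ctrl))$delta_r2, 0,
               tolerance = 1e-12)
})

test_that("incremental F equals the squared t of the added coefficient", {
  set.seed(53)
  n <- 150
  ctrl <- cbind(a = rnorm(n), b = rnorm(n))
  ratio <- rnorm(n) + 0.4 * ctrl[, 1]
  y <- 0.3 * ctrl[, 1] - 0.2 * ctrl[, 2] + 0.5 * ratio + rnorm(n)
  d <- delta_r2(ctrl, ratio, y)
  fit_b <- lm(y ~ ctrl + ratio)
  tstat <- summary(fit_b)$coefficients["ratio", "t value"]
  f_from_d <- d$delta_r2 / ((1 - d$r2_full) / (n - 4))
  expect_equal(f_from_d, tstat^2, tolerance = 1e-10)
  expect_equal(d$p, 2 * pt(-abs(tstat), n - 4), tolerance = 1e-10)
})

test_that("delta_r2 is non-negative on random designs", {
  set.seed(59)
  for (i in 1:500) {
    n <- sample(20:60, 1)
    k <- sample(1:3, 1)
    ctrl <- matrix(rnorm(n * k), n)
    d <- delta_r2(ctrl, rnorm(n), rnorm(n))
    expect_gte(d$delta_r2, 0)
    expect_lte(d$r2_full, 1)
  }
})

test_that("pooled dummies are invariant to the reference level", {
  set.seed(61)
  n <- 240
  ds <- rep(c("D1", "D2", "D3"), each = n / 3)
  ctrl <- rnorm(n); ratio <- rnorm(n)
  y <- 0.4 * ratio + 0.2 * ctrl + 0.3 * (ds == "D2") + rnorm(n)
  d1 <- delta_r2(ctrl, ratio, y, dataset = factor(ds))
  d2 <- delta_r2(ctrl, ratio, y,
                 dataset = factor(ds, levels = c("D3", "D1", "D2")))
  expect_equal(d1$delta_r2, d2$delta_r2, tolerance = 1e-10)
  expect_equal(d1$p, d2$p, tolerance = 1e-10)
})

test_that("a control collinear with dot ratio yields zero increment", {
  set.seed(67)
  ratio <- rnorm(50)
  expect_warning(d <- delta_r2(2 * ratio + 1, ratio, rnorm(50)),
                 "collinear")
  expect_identical(d$delta_r2, 0)
})

test_that("run_validation reports the printed family sizes in paper mode", {
  set.seed(71)
  sl <- design_stimlist(40, seed = 71)
  feat <- as.data.frame(matrix(runif(40 * 15, 10, 20), 40,
                               dimnames = list(NULL, c(
    "perim_total", "perim_mean", "perim_sd", "area_total", "area_mean",
    "area_sd", "convex_hull", "ch_per_dot", "ch_per_area", "dist_total",
    "dist_mean", "dist_sd", "hash_avg", "hash_perc", "hash_wav"))))
  feat$STIMID <- sl$STIMID
  feat$dot_ratio <- pmin(sl$n_a, sl$n_b) / pmax(sl$n_a, sl$n_b)
  beh <- aggregate_behavior(simulate_trials(sl, participant_panel(30)))
  rep <- run_validation(list(A = feat, B = feat), list(A = beh, B = beh))
  expect_identical(unname(rep$family_sizes), c(75, 80, 75))
  expect_equal(unname(rep$alphas),
               c(0.05 / 75, 0.05 / 80, 0.05 / 75))
  expect_identical(nrow(rep$correlations), 30L)       # 15 x 2 datasets
  expect_identical(nrow(rep$r2_grid), 64L)            # 16 x 2 x 2
  expect_identical(nrow(rep$delta_r2_grid), 60L)      # 15 x 2 x 2
  expect_identical(nrow(rep$pooled_delta_r2), 30L)
  # flags are pure functions of (p, alpha)
  with(rep$r2_grid[!is.na(rep$r2_grid$p), ],
       expect_identical(significant, p < 0.05 / 80))
  rep2 <- run_validation(list(A = feat), list(A = beh), paper_mode = FALSE)
  expect_identical(unname(rep2$family_sizes), c(15, 16, 15))
})

test_that("with dot ratio as its own control every increment vanishes", {
  set.seed(73)
  ratio <- runif(60, 0.5, 0.9)
  y <- 1 - ratio + rnorm(60, 0, 0.05)
  expect_warning(d <- delta_r2(ratio, ratio, y), "collinear")
  expect_identical(d$delta_r2, 0)
})
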