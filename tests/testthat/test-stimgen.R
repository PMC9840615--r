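test_that("solve_radii hits the total-area target exactly", {
  expect_equal(solve_radii(1, pi * 100), 10)
  expect_equal(solve_radii(4, 4 * pi * 25), rep(5, 4))
  set.seed(42)
  r <- solve_radii(7, 1000, dispersion = 0.3)
  expect_length(r, 7)
  expect_gt(sum(pi * r^2), 999)
  expect_lt(sum(pi * r^2), 1001)
  expect_gt(stats::sd(r), 0)  # dispersion actually jitters
})

test_that("solve_radii rejects infeasible area budgets", {
  expect_error(solve_radii(10, 10, min_radius = 2), "infeasible")
})

test_that("place_dots respects the panel and the minimum gap", {
  set.seed(1)
  arr <- place_dots(5, panel = c(100, 100))
  expect_s3_class(arr, "dot_array")
  expect_identical(n_dots(arr), 1L)
  expect_true(arr$x - arr$r >= 0 && arr$x + arr$r <= 100)

  expect_error(place_dots(c(10, 10), panel = c(25, 25), min_gap = 2),
               "attempts")

  set.seed(7)
  radii <- solve_radii(8, 8000, dispersion = 0.3)
  arr <- place_dots(radii, panel = c(400, 400), min_gap = 2)
  # exhaustive O(n^2) gap check
  for (i in 1:7) for (j in (i + 1):8) {
    gap <- sqrt((arr$x[i] - arr$x[j])^2 + (arr$y[i] - arr$y[j])^2) -
      arr$r[i] - arr$r[j]
    expect_gte(gap, 2)
  }
})

test_that("pair_spec enforces the printed count designs", {
  expect_error(pair_spec("D1", 10, 10, "equal_total"), "ratio")
  expect_error(pair_spec("D1", 10, 21, "equal_total"), "ratio")  # 2.1 > 2.00
  expect_error(pair_spec("D1", 3, 5, "equal_total"), "range")
  expect_error(pair_spec("D2", 5, 8, "area_ratio_1_1"), "ratio")
  expect_silent(pair_spec("D2", 5, 7, "area_ratio_2_1"))
  expect_silent(pair_spec("D5", 7, 8, "approx_1_1"))
})

test_that("build_pair realizes the area conditions on continuous areas", {
  set.seed(3)
  area_of <- function(a) sum(pi * a$r^2)

  p <- build_pair(pair_spec("D2", 8, 12, "area_ratio_1_1"))
  expect_lt(abs(area_of(p$array_a) / area_of(p$array_b) - 1), 0.005)

  # 2:1 larger-count : smaller-count
  p <- build_pair(pair_spec("D2", 8, 12, "area_ratio_2_1"))
  expect_lt(abs(area_of(p$array_b) / area_of(p$array_a) - 2), 0.01)

  p <- build_pair(pair_spec("D4", 6, 9, "equal_mean"))
  expect_lt(abs((area_of(p$array_a) / 6) / (area_of(p$array_b) / 9) - 1),
            0.005)
  expect_setequal(unique(c(p$array_a$color, p$array_b$color)),
                  c("yellow", "blue"))
  expect_identical(p$mode, "mixed")

  p <- build_pair(pair_spec("D5", 8, 12, "approx_1_1"))
  rat <- area_of(p$array_b) / area_of(p$array_a)
  expect_gte(rat, 0.95); expect_lte(rat, 1.05)
})

test_that("two-color pairs share one panel with no overlap across colors", {
  set.seed(9)
  p <- build_pair(pair_spec("D4", 8, 12, "equal_total"))
  x <- c(p$array_a$x, p$array_b$x); y <- c(p$array_a$y, p$array_b$y)
  r <- c(p$array_a$r, p$array_b$r)
  n <- length(r)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    expect_gte(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) - r[i] - r[j], 2)
})

test_that("generate_dataset reproduces the D2/D3/D5 design tables", {
  d2 <- generate_dataset("D2", seed = 11)
  expect_identical(nrow(d2$stimlist), 36L)
  expect_true(all(table(d2$stimlist$area_condition) == 12))
  rt <- pmin(d2$stimlist$n_a, d2$stimlist$n_b) /
    pmax(d2$stimlist$n_a, d2$stimlist$n_b)
  expect_true(all(sapply(rt, function(x)
    any(abs(x - c(2/3, 5/7, 3/4)) < 1e-9))))
  expect_true(all(d2$stimlist$n_a >= 5 & d2$stimlist$n_b <= 12))

  d3 <- generate_dataset("D3", seed = 11)
  expect_identical(nrow(d3$stimlist), 138L)
  expect_true(all(table(d3$stimlist$area_condition) == 46))
  expect_true(all(d3$stimlist$n_a >= 7 & d3$stimlist$n_b <= 14))

  d5 <- generate_dataset("D5", seed = 11)
  expect_identical(nrow(d5$stimlist), 100L)
  rt <- pmin(d5$stimlist$n_a, d5$stimlist$n_b) /
    pmax(d5$stimlist$n_a, d5$stimlist$n_b)
  expect_true(all(sapply(rt, function(x)
    any(abs(x - c(1/2, 2/3, 3/4, 5/6, 7/8)) < 1e-9))))
})

test_that("identical seeds give byte-identical stimulus sets", {
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  a <- generate_dataset("D2", seed = 5, out_dir = dir_a)
  b <- generate_dataset("D2", seed = 5, out_dir = dir_b)
  expect_identical(a$stimlist, b$stimlist)
  fa <- sort(list.files(dir_a)); fb <- sort(list.files(dir_b))
  expect_identical(fa, fb)
  pngs <- grep("png$", fa, value = TRUE)
  expect_identical(unname(tools::md5sum(file.path(dir_a, pngs))),
                   unname(tools::md5sum(file.path(dir_b, pngs))))
  c_ <- generate_dataset("D2", seed = 6)
  expect_false(identical(a$stimlist$n_a, c_$stimlist$n_a) &&
                 identical(a$stimlist$n_b, c_$stimlist$n_b))
})
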