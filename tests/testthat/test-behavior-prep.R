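trial_row <- function(stim, user, rt, err)
  data.frame(STIMID = stim, USERID = user, RT = rt, ERR = err,
             USERAGE = 120, GENDER = 1L, stringsAsFactors = FALSE)

test_that("aggregation computes mean error and correct-trial RT", {
  tr <- trial_row("S1", c("a", "b", "c"), c(500, 900, 600), c(0L, 1L, 0L))
  agg <- aggregate_behavior(tr)
  expect_equal(agg$mean_err, 1 / 3)
  expect_equal(agg$mean_rt_correct, 550)
  expect_identical(agg$n_participants, 3L)
  expect_identical(agg$n_correct_trials, 2L)

  # all-error stimulus keeps its row with missing RT
  tr2 <- rbind(tr, trial_row("S2", c("a", "b"), c(700, 800), c(1L, 1L)))
  agg2 <- aggregate_behavior(tr2)
  expect_identical(nrow(agg2), 2L)
  expect_equal(agg2$mean_err[agg2$STIMID == "S2"], 1)
  expect_true(is.na(agg2$mean_rt_correct[agg2$STIMID == "S2"]))
})

test_that("aggregation is invariant to trial order and conserves counts", {
  set.seed(17)
  sl <- design_stimlist(36)
  tr <- simulate_trials(sl, participant_panel(40))
  agg <- aggregate_behavior(tr)
  perm <- tr[sample.int(nrow(tr)), ]
  expect_equal(aggregate_behavior(perm), agg)
  expect_identical(sum(agg$n_trials), nrow(tr))
  expect_identical(sum(agg$n_correct_trials), sum(tr$ERR == 0L))
  expect_identical(nrow(agg), 36L)
  expect_true(all(agg$n_participants == 40L))
})

test_that("a planted slow participant is excluded, and only that one", {
  set.seed(23)
  mean_rts <- c(rnorm(100, 600, 50), 3000)
  users <- sprintf("u%03d", 1:101)
  tr <- do.call(rbind, Map(function(u, m)
    trial_row(sprintf("S%d", 1:20), u, rnorm(20, m, 10), 0L),
    users, mean_rts))
  ex <- exclude_outliers(tr)
  expect_identical(ex$excluded$USERID, "u101")
  # oracle: recompute the rule directly from participant means
  pm <- tapply(tr$RT, tr$USERID, mean)
  out <- names(pm)[abs(pm - mean(pm)) > 3 * sd(pm)]
  expect_setequal(ex$excluded$USERID, out)
  # the rule is single-pass: bounds were computed once; re-applying to the
  # kept set of this panel removes no one further
  ex2 <- exclude_outliers(ex$kept)
  expect_identical(nrow(ex2$excluded), 0L)
})

test_that("degenerate panels are handled without exclusion", {
  tr <- do.call(rbind, lapply(sprintf("u%02d", 1:10), function(u)
    trial_row(c("S1", "S2"), u, c(500, 500), 0L)))
  ex <- exclude_outliers(tr)   # SD = 0: bounds collapse to the mean
  expect_identical(nrow(ex$excluded), 0L)
  expect_identical(nrow(ex$kept), nrow(tr))
  expect_warning(exclude_outliers(trial_row("S1", c("a", "b"),
                                            c(500, 700), 0L)),
                 "fewer than 3")
})

test_that("error trials stay out of the RT side of the exclusion rule", {
  set.seed(29)
  users <- sprintf("u%02d", 1:20)
  tr <- do.call(rbind, lapply(users, function(u)
    trial_row(sprintf("S%d", 1:10), u, rnorm(10, 600, 20), 0L)))
  # one participant answers fast but always wrongly, plus huge error RTs
  slowerr <- trial_row(sprintf("S%d", 1:10), "u21", 5000, 1L)
  ex <- exclude_outliers(rbind(tr, slowerr), rt_trials = "correct")
  expect_false("u21" %in% ex$excluded$USERID)
  ex_all <- exclude_outliers(rbind(tr, slowerr), rt_trials = "all")
  expect_true("u21" %in% ex_all$excluded$USERID)
})

test_that("binned accuracy agrees with the generating psychometric curve", {
  set.seed(37)
  sl <- design_stimlist(120, seed = 37)
  panel <- participant_panel(150, weber_median = 0.25, weber_sdlog = 0)
  tr <- simulate_trials(sl, panel)
  agg <- aggregate_behavior(exclude_outliers(tr)$kept)
  m <- merge(agg, sl, by = "STIMID")
  p_true <- p_correct(m$n_a, m$n_b, 0.25)
  # per-stimulus binomial 99% CI around the model accuracy
  half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / m$n_trials)
  inside <- abs((1 - m$mean_err) - p_true) <= half + 1e-9
  expect_gt(mean(inside), 0.95)
})
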