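#' Exclude participants with outlying mean reaction times
#'
#' Computes each participant's mean RT (correct trials only, by default,
#' matching the RT definition used downstream) and excludes participants
#' whose mean lies outside mean +/- 3 SD of the participant means within the
#' dataset. Single pass: the bounds are computed once, never re-estimated on
#' the kept set.
#'
#' @param trials trial table with `STIMID`, `USERID`, `RT`, `ERR`.
#' @param sd_limit exclusion bound in SD units (default 3).
#' @param rt_trials `"correct"` (default) to base participant means on
#'   correct trials only, `"all"` to include error trials.
#' @return List: `kept` (filtered trial table), `excluded` (data frame of
#'   excluded USERIDs with their mean RT), `bounds` (the numeric interval
#'   used).
#' @export
exclude_outliers <- function(trials, sd_limit = 3,
                             rt_trials = c("correct", "all")) {
  rt_trials <- match.arg(rt_trials)
  stopifnot(nrow(trials) >= 1)
  base <- if (rt_trials == "correct") trials[trials$ERR == 0, ] else trials
  means <- tapply(base$RT, base$USERID, mean)
  if (length(means) < 3) {
    warning("fewer than 3 participants: no outlier exclusion applied")
    return(list(kept = trials,
                excluded = data.frame(USERID = character(0),
                                      mean_rt = numeric(0)),
                bounds = c(-Inf, Inf)))
  }
  m <- mean(means); s <- stats::sd(means)
  bounds <- c(m - sd_limit * s, m + sd_limit * s)
  out <- names(means)[means < bounds[1] | means > bounds[2]]
  list(kept = trials[!(trials$USERID %in% out), , drop = FALSE],
       excluded = data.frame(USERID = out,
                             mean_rt = as.numeric(means[out]),
                             stringsAsFactors = FALSE),
       bounds = bounds)
}

#' Aggregate trials into per-stimulus behavior
#'
#' Per stimulus: the mean error rate over all trials, and the mean RT over
#' correct trials only. A stimulus with no correct trials keeps its row with
#' `mean_rt_correct = NA`.
#'
#' @param trials (outlier-filtered) trial table.
#' @return Data frame: `STIMID`, `mean_err`, `mean_rt_correct`,
#'   `n_participants`, `n_trials`, `n_correct_trials`.
#' @export
aggregate_behavior <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  ids <- sort(unique(trials$STIMID))
  f <- factor(trials$STIMID, levels = ids)
  n_trials <- as.integer(table(f))
  mean_err <- as.numeric(tapply(trials$ERR, f, mean))
  correct <- trials[trials$ERR == 0, ]
  fc <- factor(correct$STIMID, levels = ids)
  rt <- as.numeric(tapply(correct$RT, fc, mean))
  n_correct <- as.integer(table(fc))
  n_part <- as.integer(tapply(trials$USERID, f,
                              function(u) length(unique(u))))
  data.frame(STIMID = ids, mean_err = mean_err, mean_rt_correct = rt,
             n_participants = n_part, n_trials = n_trials,
             n_correct_trials = n_correct, stringsAsFactors = FALSE)
}
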