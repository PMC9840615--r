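#' Probability of a correct numerosity comparison under Weber-law noise
#'
#' Linear approximate-number-system model: the two numerosities are
#' represented as Gaussians with SD proportional to their magnitude
#' (Weber fraction `w`), and the response is correct when the sampled
#' difference has the right sign:
#' \deqn{p = 1 - \tfrac12\,\mathrm{erfc}\!\left(\frac{|n_1 - n_2|}
#'   {\sqrt{2}\, w \sqrt{n_1^2 + n_2^2}}\right)
#'   = \Phi\!\left(\frac{|n_1 - n_2|}{w \sqrt{n_1^2 + n_2^2}}\right).}
#' Accuracy rises with the count difference at fixed overall magnitude and
#' tends to 0.5 as the counts approach each other.
#'
#' @param n1,n2 dot counts (>= 1); vectorized.
#' @param w Weber fraction (> 0).
#' @return probability of a correct response.
#' @export
p_correct <- function(n1, n2, w) {
  if (any(w <= 0)) stop("weber fraction w must be > 0")
  stopifnot(all(n1 >= 1), all(n2 >= 1))
  stats::pnorm(abs(n1 - n2) / (w * sqrt(n1^2 + n2^2)))
}

#' Draw a panel of simulated participants
#'
#' Weber fractions are log-normal across participants around a configurable
#' median, creating realistic individual differences; reaction-time
#' parameters and demographics are drawn independently.
#'
#' @param n number of participants.
#' @param weber_median median Weber fraction.
#' @param weber_sdlog log-scale SD of the Weber fraction (0 gives a
#'   homogeneous panel).
#' @param rt_base_mean,rt_base_sd base RT intercept distribution (ms).
#' @param rt_ratio_slope RT increase per unit dot ratio (ms); harder
#'   (closer-to-1) ratios are slower.
#' @param rt_sigma log-scale SD of multiplicative RT noise.
#' @param age_range age range in months.
#' @return Data frame: `USERID`, `weber_w`, `rt_base`, `rt_ratio_slope`,
#'   `rt_sigma`, `USERAGE`, `GENDER` (1 male, 2 female).
#' @export
participant_panel <- function(n, weber_median = 0.25, weber_sdlog = 0.3,
                              rt_base_mean = 500, rt_base_sd = 80,
                              rt_ratio_slope = 300, rt_sigma = 0.25,
                              age_range = c(60, 480)) {
  stopifnot(n >= 1, weber_median > 0, weber_sdlog >= 0)
  data.frame(
    USERID = sprintf("U%05d", seq_len(n)),
    weber_w = stats::rlnorm(n, log(weber_median), weber_sdlog),
    rt_base = pmax(200, stats::rnorm(n, rt_base_mean, rt_base_sd)),
    rt_ratio_slope = rt_ratio_slope,
    rt_sigma = rt_sigma,
    USERAGE = round(stats::runif(n, age_range[1], age_range[2])),
    GENDER = sample(c(1L, 2L), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate trial-level behavior for a stimulus set
#'
#' One trial per participant x stimulus. Errors are Bernoulli with success
#' probability [p_correct()] at the participant's Weber fraction; RT has
#' median `rt_base + rt_ratio_slope * dot_ratio` with multiplicative
#' log-normal noise, truncated to `[150, 5000]` ms.
#'
#' @param stimlist stimulus-list data frame with `STIMID`, `n_a`, `n_b`.
#' @param participants data frame from [participant_panel()].
#' @return Trial table with columns `STIMID`, `USERID`, `RT`, `ERR`
#'   (0 correct, 1 error), `USERAGE`, `GENDER`.
#' @export
simulate_trials <- function(stimlist, participants) {
  stopifnot(nrow(stimlist) >= 1, nrow(participants) >= 1)
  ratio <- pmin(stimlist$n_a, stimlist$n_b) / pmax(stimlist$n_a, stimlist$n_b)
  ns <- nrow(stimlist); np <- nrow(participants)
  pid <- rep(seq_len(np), each = ns)
  sid <- rep(seq_len(ns), times = np)
  p <- p_correct(stimlist$n_a[sid], stimlist$n_b[sid],
                 participants$weber_w[pid])
  err <- as.integer(stats::runif(ns * np) > p)
  rt_med <- participants$rt_base[pid] +
    participants$rt_ratio_slope[pid] * ratio[sid]
  rt <- rt_med * exp(stats::rnorm(ns * np, 0, participants$rt_sigma[pid]))
  data.frame(
    STIMID = stimlist$STIMID[sid],
    USERID = participants$USERID[pid],
    RT = pmin(5000, pmax(150, rt)),
    ERR = err,
    USERAGE = participants$USERAGE[pid],
    GENDER = participants$GENDER[pid],
    stringsAsFactors = FALSE
  )
}

#' Slow down a random subset of participants
#'
#' Multiplies every RT of a random `fraction` of participants by
#' `slowdown_factor` (re-truncated at 5000 ms); used to exercise the
#' participant-level outlier-exclusion rule.
#'
#' @param trials trial table (see [simulate_trials()]).
#' @param fraction fraction of participants affected, in `[0, 1)`.
#' @param slowdown_factor RT multiplier (> 1).
#' @return The trial table with modified RTs; affected USERIDs in
#'   `attr(, "outlier_users")`.
#' @export
inject_outliers <- function(trials, fraction, slowdown_factor = 6) {
  stopifnot(fraction >= 0, fraction < 1)
  users <- unique(trials$USERID)
  n_aff <- round(fraction * length(users))
  affected <- if (n_aff > 0) sample(users, n_aff) else character(0)
  hit <- trials$USERID %in% affected
  trials$RT[hit] <- pmin(5000, trials$RT[hit] * slowdown_factor)
  attr(trials, "outlier_users") <- affected
  trials
}

#' Maximum-likelihood Weber fraction from per-stimulus accuracy
#'
#' Fits the [p_correct()] model by 1-D bounded maximization of the binomial
#' log-likelihood of the per-stimulus correct counts.
#'
#' @param acc data frame with columns `n1`, `n2`, `accuracy` (mean
#'   proportion correct) and `n_trials`.
#' @param bounds search interval for `w`.
#' @return List: `w` (the estimate), `loglik`, `boundary` (TRUE with a
#'   warning when the estimate sits at a search bound, as with all-perfect
#'   or all-chance data).
#' @export
fit_weber <- function(acc, bounds = c(1e-4, 10)) {
  stopifnot(all(c("n1", "n2", "accuracy", "n_trials") %in% names(acc)))
  acc <- acc[acc$n1 != acc$n2, ]
  ratios <- unique(pmin(acc$n1, acc$n2) / pmax(acc$n1, acc$n2))
  if (length(ratios) < 3) stop("need accuracy at >= 3 distinct dot ratios")
  k <- round(acc$accuracy * acc$n_trials)
  nll <- function(w) {
    p <- pmin(1 - 1e-12, pmax(1e-12, p_correct(acc$n1, acc$n2, w)))
    -sum(stats::dbinom(k, acc$n_trials, p, log = TRUE))
  }
  opt <- stats::optimize(nll, bounds)
  boundary <- opt$minimum < bounds[1] * 1.05 || opt$minimum > bounds[2] * 0.95
  if (boundary)
    warning("Weber estimate at the search boundary; data may be all-perfect ",
            "or all-chance")
  list(w = opt$minimum, loglik = -opt$objective, boundary = boundary)
}
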