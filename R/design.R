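#' Default timing parameters of the trial design
#'
#' The design uses a 2-s visual CS, a 15-s stimulus-free trace interval, a
#' ~1-s electric US (acquisition only, 100% reinforcement of CS+), a 30 +/- 2 s
#' inter-trial interval, and at most three same-type CS in a row. In the
#' recall session no US is delivered and a startle probe sounds on every
#' trial 13 s after CS offset (2 s before the expected US).
#'
#' @param session `"acquisition"` (40 trials, 20 CS+ / 20 CS-) or
#'   `"recall"` (30 trials, 15 / 15).
#' @return Named list of timing parameters (all durations in seconds).
#' @export
schedule_params <- function(session = c("acquisition", "recall")) {
  session <- match.arg(session)
  list(
    n_plus = if (session == "acquisition") 20L else 15L,
    n_minus = if (session == "acquisition") 20L else 15L,
    cs_duration = 2.0,
    trace_duration = 15.0,
    us_duration = 1.0,
    probe_delay = 13.0,       # after CS offset, recall only
    iti_mean = 30.0,
    iti_jitter = 2.0,         # uniform on [-jitter, +jitter]
    max_run = 3L,
    lead_in = 10.0,           # quiet recording before the first CS
    iti_task_min = 5.0,       # digit-stream task onset window after
    iti_task_max = 10.0       # (expected-)US offset
  )
}

sample_condition_sequence <- function(n_plus, n_minus, max_run, max_tries = 10000L) {
  if (max_run < 1L) stop("run limit must be at least 1")
  n_major <- max(n_plus, n_minus)
  n_minor <- min(n_plus, n_minus)
  if (n_major > max_run * (n_minor + 1L))
    stop("run-length constraint unsatisfiable for these trial counts")
  labels <- c(rep("CS+", n_plus), rep("CS-", n_minus))
  for (i in seq_len(max_tries)) {
    cand <- sample(labels)
    if (max(rle(cand)$lengths) <= max_run) return(cand)
  }
  stop("failed to sample an admissible condition sequence")
}

#' Generate a session schedule
#'
#' Draws a condition order uniformly over all orders satisfying the
#' run-length constraint (rejection sampling of random shuffles), then lays
#' out CS, US, probe, and incidental-task onsets on a common session clock
#' with a uniformly jittered inter-trial interval. Identical `seed` and
#' `params` give a byte-identical schedule.
#'
#' @param session `"acquisition"` or `"recall"`.
#' @param seed Integer seed for the schedule's private RNG stream.
#' @param params Timing parameters; see [schedule_params()]. Partial lists
#'   override the defaults field-wise.
#' @return A `trial_schedule`: the session label, a data frame of trials
#'   (`trial_index`, `condition`, `cs_onset`, `us_onset`, `probe_onset`,
#'   `iti_task_onset`, `iti_duration`), the parameters and the seed.
#' @export
generate_schedule <- function(session = c("acquisition", "recall"), seed,
                              params = list()) {
  session <- match.arg(session)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  p <- utils::modifyList(schedule_params(session), params)
  n <- p$n_plus + p$n_minus
  res <- withr_seed(seed, {
    cond <- sample_condition_sequence(p$n_plus, p$n_minus, p$max_run)
    iti <- stats::runif(n, p$iti_mean - p$iti_jitter, p$iti_mean + p$iti_jitter)
    task_jit <- stats::runif(n, p$iti_task_min, p$iti_task_max)
    list(cond = cond, iti = iti, task_jit = task_jit)
  })
  trial_len <- p$cs_duration + p$trace_duration + p$us_duration
  cs_onset <- p$lead_in + cumsum(c(0, (trial_len + res$iti)[-n]))
  us_onset <- rep(NA_real_, n)
  probe_onset <- rep(NA_real_, n)
  if (session == "acquisition") {
    plus <- res$cond == "CS+"
    us_onset[plus] <- cs_onset[plus] + p$cs_duration + p$trace_duration
  } else {
    probe_onset <- cs_onset + p$cs_duration + p$probe_delay
  }
  # incidental digit-stream task: onset after the (expected-)US offset
  expected_us_off <- cs_onset + trial_len
  trials <- data.frame(
    trial_index = seq_len(n),
    condition = res$cond,
    cs_onset = cs_onset,
    us_onset = us_onset,
    probe_onset = probe_onset,
    iti_task_onset = expected_us_off + res$task_jit,
    iti_duration = res$iti,
    stringsAsFactors = FALSE
  )
  sched <- structure(
    list(session = session, trials = trials, params = p,
         rng_seed = as.integer(seed)),
    class = "trial_schedule"
  )
  validate_schedule(sched)
  sched
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's.
# `seed` is forced *before* the caller state is saved: a lazily evaluated
# seed expression may itself consume random numbers (e.g. sample.int()), and
# that draw must not be rolled back on exit.
withr_seed <- function(seed, expr) {
  seed <- as.integer(seed) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pain calibration curve
#'
#' Ratings (0-100) of a series of electric-stimulus intensities, used to set
#' the US current at a fraction of the individually "clearly painful" level.
#'
#' @param intensity Stimulus intensities in mA (strictly positive).
#' @param rating Perceived-intensity ratings on a 0-100 scale.
#' @param painful_rating Rating value anchoring "clearly painful"
#'   (default 100).
#' @return A `pain_calibration_curve`.
#' @export
pain_calibration_curve <- function(intensity, rating, painful_rating = 100) {
  stopifnot(length(intensity) == length(rating), length(intensity) >= 2L,
            all(is.finite(intensity)), all(intensity > 0),
            all(is.finite(rating)), is.finite(painful_rating))
  ord <- order(intensity)
  structure(
    list(intensity = intensity[ord], rating = rating[ord],
         painful_rating = painful_rating),
    class = "pain_calibration_curve"
  )
}

#' US intensity at a fraction of the pain threshold
#'
#' Linearly interpolates the rating-intensity curve to find the current
#' whose rating equals `fraction` times the clearly-painful rating (the
#' experiment used 90%). If ratings are not monotone in intensity, the
#' curve is first replaced by its isotonic (monotone nondecreasing)
#' regression. No extrapolation: a target rating outside the observed range
#' is an error.
#'
#' @param curve A [pain_calibration_curve()].
#' @param fraction Fraction of the painful rating in (0, 1].
#' @return Interpolated intensity in mA.
#' @export
calibrate_us_intensity <- function(curve, fraction = 0.9) {
  stopifnot(inherits(curve, "pain_calibration_curve"),
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  x <- curve$intensity
  r <- curve$rating
  if (any(diff(r) < 0)) r <- stats::isoreg(x, r)$yf
  target <- fraction * curve$painful_rating
  if (target < min(r) - 1e-12 || target > max(r) + 1e-12)
    stop(sprintf("target rating %.3g outside observed range [%.3g, %.3g]",
                 target, min(r), max(r)))
  # first segment bracketing the target; flat runs return their left edge
  for (i in seq_len(length(r) - 1L)) {
    lo <- r[i]; hi <- r[i + 1L]
    if (target >= lo - 1e-12 && target <= hi + 1e-12) {
      if (abs(target - lo) <= 1e-12) return(x[i])
      if (hi > lo) return(x[i] + (target - lo) / (hi - lo) * (x[i + 1L] - x[i]))
    }
  }
  x[which.min(abs(r - target))]
}
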