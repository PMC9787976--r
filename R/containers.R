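#' Continuous physiological signal container
#'
#' A uniformly sampled single-channel recording with an explicit missing-data
#' mask. This is the common currency of the synthesis and preprocessing
#' layers: every generator returns one and every preprocessing chain consumes
#' and returns one.
#'
#' @param samples Numeric vector of samples. May contain `NA` where data are
#'   missing; any `NA` is reflected in the mask.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel One of `"emg"`, `"scr"`, `"pupil_l"`, `"pupil_r"`,
#'   `"gaze_x"`, `"gaze_y"`, `"ecg"`, `"respiration"`.
#' @param units Unit string (e.g. `"uS"`, `"mm"`, `"mV"`, `"a.u."`).
#' @param missing_mask Logical vector, same length as `samples`; `TRUE`
#'   marks a missing sample. Defaults to `is.na(samples)`.
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, sampling_rate, channel, units = "a.u.",
                              missing_mask = NULL) {
  channels <- c("emg", "scr", "pupil_l", "pupil_r", "gaze_x", "gaze_y",
                "ecg", "respiration")
  channel <- match.arg(channel, channels)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (is.null(missing_mask)) missing_mask <- is.na(samples)
  missing_mask <- as.logical(missing_mask) | is.na(samples)
  if (length(missing_mask) != length(samples)) {
    stop("missing_mask must have the same length as samples")
  }
  if (any(!is.finite(samples[!missing_mask]))) {
    stop("non-missing samples must be finite")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel = channel, units = units, missing_mask = missing_mask),
    class = "continuous_signal"
  )
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> channel=%s, %d samples @ %g Hz (%s), %.1f%% missing\n",
              x$channel, length(x$samples), x$sampling_rate, x$units,
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
length.continuous_signal <- function(x) length(x$samples)

#' Time stamps of a continuous signal
#'
#' @param x A `continuous_signal`.
#' @return Numeric vector of sample times in seconds (first sample at 0).
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "continuous_signal"))
  (seq_along(x$samples) - 1) / x$sampling_rate
}

sig_index <- function(x, t) {
  # nearest on-grid sample index for time t (1-based)
  pmin(pmax(1L, as.integer(round(t * x$sampling_rate)) + 1L), length(x$samples))
}

#' Validate a trial schedule
#'
#' Checks the structural invariants of a session schedule: per-condition
#' trial counts, US placement (acquisition: every CS+ reinforced at CS
#' offset + trace interval), probe placement (recall: 13 s after CS offset
#' on every trial), the run-length randomization constraint, the inter-trial
#' interval bounds, and strictly increasing non-overlapping onsets.
#'
#' @param schedule A `trial_schedule`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  tr <- schedule$trials
  p <- schedule$params
  n_plus <- sum(tr$condition == "CS+")
  n_minus <- sum(tr$condition == "CS-")
  if (schedule$session == "acquisition") {
    if (n_plus != p$n_plus || n_minus != p$n_minus)
      stop("acquisition schedule must have the configured CS+/CS- counts")
    plus <- tr[tr$condition == "CS+", ]
    if (any(is.na(plus$us_onset)))
      stop("every acquisition CS+ trial must be reinforced")
    expected <- plus$cs_onset + p$cs_duration + p$trace_duration
    if (any(abs(plus$us_onset - expected) > 1e-9))
      stop("US onset must equal CS onset + CS duration + trace interval")
    if (any(!is.na(tr$us_onset[tr$condition == "CS-"])))
      stop("CS- trials must not be reinforced")
    if (any(!is.na(tr$probe_onset)))
      stop("acquisition trials carry no startle probe")
  } else {
    if (n_plus != p$n_plus || n_minus != p$n_minus)
      stop("recall schedule must have the configured CS+/CS- counts")
    if (any(!is.na(tr$us_onset)))
      stop("recall trials are never reinforced")
    expected <- tr$cs_onset + p$cs_duration + p$probe_delay
    if (any(is.na(tr$probe_onset)) || any(abs(tr$probe_onset - expected) > 1e-9))
      stop("every recall trial must carry a probe 13 s after CS offset")
  }
  runs <- rle(as.character(tr$condition))
  if (max(runs$lengths) > p$max_run)
    stop("run-length constraint violated")
  if (any(tr$iti_duration < p$iti_mean - p$iti_jitter - 1e-9 |
          tr$iti_duration > p$iti_mean + p$iti_jitter + 1e-9))
    stop("ITI outside configured bounds")
  if (any(diff(tr$cs_onset) <= 0)) stop("onsets must be strictly increasing")
  trial_end <- tr$cs_onset + p$cs_duration + p$trace_duration + p$us_duration
  if (nrow(tr) > 1 && any(tr$cs_onset[-1] < trial_end[-nrow(tr)] - 1e-9))
    stop("trials overlap")
  invisible(TRUE)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s session, %d trials (%d CS+ / %d CS-), seed %d\n",
              x$session, nrow(x$trials), sum(x$trials$condition == "CS+"),
              sum(x$trials$condition == "CS-"), x$rng_seed))
  invisible(x)
}
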