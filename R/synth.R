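#' Default ground-truth parameters of the synthetic cohort
#'
#' The generator emulates the study conditions of the trial design: 40
#' acquisition trials (20 CS+ with 100% reinforcement), 30 unreinforced
#' recall trials with a startle probe, exponential habituation of
#' conditioned responses across trials, a multiplicative CS+ effect, and
#' trial-to-trial lognormal amplitude variability. Amplitudes are in the
#' units consumed by the preprocessing contracts: skin conductance in uS,
#' pupil diameter in mm, heart period in ms, EMG in arbitrary volts.
#'
#' `snr` is the ratio of the modality's mean response amplitude to the
#' noise standard deviation on the scale where responses are scored.
#'
#' @return Nested list of per-modality truth parameters.
#' @export
truth_params <- function() {
  list(
    sebr = list(amp = 1.0, lambda = 0.04, delta_mean = 0.3, trial_cv = 0.4,
                snr = 10, form = "exponential"),
    scr = list(amp_cs = 0.3, amp_trace = 0.4, amp_us = 0.8, lambda = 0.03,
               delta_mean = 0.5, trial_cv = 0.4, snr = 10, sigma = 0.3,
               delta_cs = 1.0, delta_us = 1.0, form = "exponential",
               latency_lo = 8, latency_hi = 1),
    pupil = list(amp = 0.3, lambda = 0.01, delta_mean = 0.5, trial_cv = 0.3,
                 noise_sd = 0.02, eye_noise_sd = 0.01,
                 blink_rate = 8 / 60, excursion_rate = 1 / 60,
                 form = "exponential"),
    hpr = list(amp = 8, lambda = 0.01, delta_mean = 0.3, trial_cv = 0.3,
               base_period = 800, hrv_sd = 10, form = "exponential"),
    rar = list(amp = 0.10, lambda = 0.01, delta_mean = 0.3, trial_cv = 0.3,
               base_amp = 0.5, base_period = 4, form = "exponential")
  )
}

hab_factor <- function(trial, lambda, form = "exponential") {
  if (form == "linear") pmax(0, 1 - lambda * (trial - 1))
  else exp(-lambda * (trial - 1))
}

#' Draw per-trial ground truth for one session
#'
#' Instantiates, per trial and modality, the true response amplitudes that
#' the downstream quantifiers should recover: baseline amplitude times an
#' exponential (or linear) habituation factor, a multiplicative CS+ effect
#' (`delta_mean` in CS- units), and lognormal trial-to-trial variability.
#' The skin-conductance truth additionally carries a free trace-burst
#' latency, drawn uniformly inside the trace-interval window.
#'
#' @param schedule A [generate_schedule()] result.
#' @param params See [truth_params()]; partial lists override field-wise.
#' @param seed Integer seed.
#' @return A `ground_truth` object with one data frame per modality.
#' @export
ground_truth <- function(schedule, params = list(), seed) {
  p <- utils::modifyList(truth_params(), params)
  tr <- schedule$trials
  sp <- schedule$params
  n <- nrow(tr)
  plus <- as.numeric(tr$condition == "CS+")
  amp_of <- function(base, m) {
    base * hab_factor(tr$trial_index, m$lambda, m$form) *
      (1 + m$delta_mean * plus) *
      stats::rlnorm(n, meanlog = -log(1 + m$trial_cv^2) / 2,
                    sdlog = sqrt(log(1 + m$trial_cv^2)))
  }
  withr_seed(seed, {
    us_time <- tr$cs_onset + sp$cs_duration + sp$trace_duration
    lat_lo <- sp$cs_duration + p$scr$latency_lo
    lat_hi <- sp$cs_duration + sp$trace_duration - p$scr$latency_hi
    trials <- list(
      sebr = data.frame(trial_index = tr$trial_index, condition = tr$condition,
                        amplitude = amp_of(p$sebr$amp, p$sebr)),
      scr = data.frame(trial_index = tr$trial_index, condition = tr$condition,
                       amp_cs = amp_of(p$scr$amp_cs, p$scr),
                       amp_trace = amp_of(p$scr$amp_trace, p$scr),
                       amp_us = ifelse(is.na(tr$us_onset), 0,
                                       p$scr$amp_us *
                                         stats::rlnorm(n, 0, 0.2)),
                       latency = stats::runif(n, lat_lo + 0.5, lat_hi - 0.5)),
      pupil = data.frame(trial_index = tr$trial_index, condition = tr$condition,
                         amplitude = amp_of(p$pupil$amp, p$pupil)),
      hpr = data.frame(trial_index = tr$trial_index, condition = tr$condition,
                       amplitude = amp_of(p$hpr$amp, p$hpr)),
      rar = data.frame(trial_index = tr$trial_index, condition = tr$condition,
                       amplitude = amp_of(p$rar$amp, p$rar))
    )
    structure(list(trials = trials, params = p, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

session_duration <- function(schedule, pad = 20) {
  tr <- schedule$trials
  p <- schedule$params
  max(tr$cs_onset + p$cs_duration + p$trace_duration + p$us_duration,
      na.rm = TRUE) + pad
}

# rectified + 20-ms moving-average envelope peak of a burst template,
# used to calibrate generated burst amplitudes to the scoring scale
burst_envelope_peak <- function(burst, fs) {
  max(moving_average(abs(burst), round(0.020 * fs)))
}

#' Synthesize orbicularis oculi EMG with startle blink bursts
#'
#' Broadband baseline noise (band-limited to 50-470 Hz) plus, at each
#' startle probe, an amplitude-modulated carrier burst whose
#' rectified-and-smoothed envelope peaks at the trial's true amplitude, at
#' a peak latency drawn uniformly in 30-80 ms after probe onset. An
#' optional 50 Hz mains component can be injected.
#'
#' @param schedule Recall schedule (must carry probe onsets).
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (>= 1000; the digitizer ran at 2000).
#' @param mains_amp Amplitude of an additive 50 Hz mains component.
#' @return A `continuous_signal` (channel `"emg"`).
#' @export
synth_emg <- function(schedule, truth, seed, fs = 2000, mains_amp = 0) {
  tr <- schedule$trials
  if (all(is.na(tr$probe_onset))) stop("schedule has no probe onsets")
  p <- truth$params$sebr
  dur <- session_duration(schedule)
  n <- ceiling(dur * fs)
  withr_seed(seed, {
    noise_sd <- p$amp / p$snr
    x <- butter_apply(stats::rnorm(n), 4, c(50, 470), "pass", fs)
    x <- x * noise_sd / stats::sd(x)
    amps <- truth$trials$sebr$amplitude
    blen <- round(0.100 * fs)
    tb <- seq_len(blen) / fs
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(blen) - 1) / (blen - 1))
    pad <- numeric(round(0.2 * fs))
    for (i in seq_len(nrow(tr))) {
      if (amps[i] <= 0) next
      lat <- stats::runif(1, 0.030, 0.080)
      phase <- stats::runif(1, 0, 2 * pi)
      burst <- hann * sin(2 * pi * 125 * tb + phase)
      # calibrate so the scored envelope (high-pass, notch, rectify,
      # 20-ms moving average) peaks at the trial's true amplitude
      templ <- notch_apply(butter_apply(c(pad, burst, pad), 4, 30, "high", fs),
                           fs, 50, Q = 35)
      burst <- burst * amps[i] / burst_envelope_peak(templ, fs)
      # envelope peaks at the Hann center: onset = probe + latency - blen/2
      i0 <- round((tr$probe_onset[i] + lat) * fs) - blen %/% 2L
      idx <- i0 + seq_len(blen)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + burst[keep]
    }
    if (mains_amp > 0) x <- x + mains_amp * sin(2 * pi * 50 * seq_len(n) / fs)
    continuous_signal(x, fs, "emg", units = "a.u.")
  })
}

# open (linear) convolution, zero-padded to an FFT-friendly length
conv_open <- function(a, b) {
  n <- length(a) + length(b) - 1L
  N <- stats::nextn(n, c(2L, 3L, 5L))
  A <- stats::fft(c(a, numeric(N - length(a))))
  B <- stats::fft(c(b, numeric(N - length(b))))
  Re(stats::fft(A * B, inverse = TRUE))[seq_len(n)] / N
}

.scr_norm_cache <- new.env(parent = emptyenv())

# unit-peak skin conductance response to one sudomotor burst: a Gaussian
# bump of dispersion sigma centered at `center`, convolved with the
# canonical conductance kernel; shared by the generator and the inverter
scr_burst_response <- function(time_grid, center, sigma, kernel_rf, fs) {
  kv <- rf_resample(kernel_rf, fs)$values
  bump <- exp(-0.5 * ((time_grid - center) / sigma)^2)
  resp <- conv_open(bump, kv)[seq_along(time_grid)]
  # latency-independent normalization: peak of an on-grid aligned response
  key <- paste(fs, sigma, kernel_rf$kind,
               paste(unlist(kernel_rf$params), collapse = ","), length(kv),
               sep = "|")
  norm <- .scr_norm_cache[[key]]
  if (is.null(norm)) {
    ref_bump <- exp(-0.5 * ((seq(-4 * sigma, 4 * sigma, by = 1 / fs)) / sigma)^2)
    norm <- max(conv_open(ref_bump, kv))
    assign(key, norm, envir = .scr_norm_cache)
  }
  resp / norm
}

#' Synthesize a skin conductance recording
#'
#' Forward model of the three-burst trial structure: CS-locked and
#' (acquisition) US-locked sudomotor bursts at fixed latencies plus a
#' trace-interval burst at the trial's true latency, each a Gaussian bump
#' convolved with the canonical conductance kernel, on top of a slow
#' baseline drift and AR(1) noise. An electric-stimulation artifact can be
#' injected around US onsets.
#'
#' @inheritParams synth_emg
#' @param fs Sampling rate in Hz (default 100; a slow channel).
#' @param us_artifact Inject a stimulation artifact spike on
#'   `[us - 0.2 s, us + 1.6 s]` of reinforced trials.
#' @param noise Logical; set `FALSE` for a noise- and drift-free signal.
#' @return A `continuous_signal` (channel `"scr"`, uS).
#' @export
synth_scr <- function(schedule, truth, seed, fs = 100, us_artifact = FALSE,
                      noise = TRUE) {
  tr <- schedule$trials
  sp <- schedule$params
  p <- truth$params$scr
  g <- truth$trials$scr
  dur <- session_duration(schedule)
  tg <- seq(0, dur, by = 1 / fs)
  kern <- scr_kernel_rf(fs = fs)
  x <- numeric(length(tg))
  add_burst <- function(x, center, amp) {
    if (amp <= 0) return(x)
    # bursts have compact support: add on a local window only
    i0 <- max(1L, floor((center - 4 * p$sigma) * fs) + 1L)
    i1 <- min(length(tg),
              ceiling((center + 4 * p$sigma + max(kern$grid)) * fs) + 1L)
    x[i0:i1] <- x[i0:i1] +
      amp * scr_burst_response(tg[i0:i1], center, p$sigma, kern, fs)
    x
  }
  for (i in seq_len(nrow(tr))) {
    cs <- tr$cs_onset[i]
    x <- add_burst(x, cs + p$delta_cs, g$amp_cs[i])
    x <- add_burst(x, cs + g$latency[i], g$amp_trace[i])
    if (!is.na(tr$us_onset[i]) && g$amp_us[i] > 0) {
      x <- add_burst(x, tr$us_onset[i] + p$delta_us, g$amp_us[i])
    }
  }
  withr_seed(seed, {
    if (noise) {
      phi <- exp(-1 / (0.5 * fs))
      x <- x + (p$amp_trace / p$snr) * ar1_noise(length(tg), phi)
      x <- x + 2 + 0.1 * sin(2 * pi * tg / 300 + stats::runif(1, 0, 2 * pi))
    }
    if (us_artifact) {
      for (us in tr$us_onset[!is.na(tr$us_onset)]) {
        win <- tg >= us - 0.2 & tg <= us + 1.6
        x[win] <- x[win] + 5 * stats::runif(sum(win), -1, 1)
      }
    }
    continuous_signal(x, fs, "scr", units = "uS")
  })
}

#' Synthesize binocular pupil and gaze channels
#'
#' Smooth baseline plus a CS-locked dilation response scaled by the trial's
#' true amplitude; both eyes share a common signal with independent
#' per-eye noise. Injected artifacts: blinks (dropouts in both eyes),
#' single-sample speed spikes, and gaze excursions beyond +/-5 degrees.
#'
#' @inheritParams synth_emg
#' @param fs Sampling rate in Hz (the eyetracker ran at 500).
#' @return Named list of `continuous_signal`s: `pupil_l`, `pupil_r`,
#'   `gaze_x`, `gaze_y` (pupil in mm, gaze in degrees).
#' @export
synth_pupil <- function(schedule, truth, seed, fs = 100) {
  tr <- schedule$trials
  p <- truth$params$pupil
  g <- truth$trials$pupil
  dur <- session_duration(schedule)
  tg <- seq(0, dur, by = 1 / fs)
  n <- length(tg)
  rfv <- rf_resample(pupil_canonical_rf(fs = fs), fs)$values
  resp <- numeric(n)
  for (i in seq_len(nrow(tr))) {
    i0 <- round(tr$cs_onset[i] * fs)
    idx <- i0 + seq_along(rfv)
    keep <- idx >= 1 & idx <= n
    resp[idx[keep]] <- resp[idx[keep]] + g$amplitude[i] * rfv[keep]
  }
  withr_seed(seed, {
    phi <- exp(-1 / (2 * fs))
    common <- 4 + 0.02 * ar1_noise(n, exp(-1 / (30 * fs))) + resp +
      p$noise_sd * ar1_noise(n, phi)
    pl <- common + p$eye_noise_sd * stats::rnorm(n)
    pr <- common + p$eye_noise_sd * stats::rnorm(n)
    gx <- 0.8 * ar1_noise(n, phi)
    gy <- 0.8 * ar1_noise(n, phi)
    # blinks: both eyes drop out
    n_blink <- stats::rpois(1, p$blink_rate * dur)
    for (b in seq_len(n_blink)) {
      t0 <- stats::runif(1, 0, dur)
      len <- round(stats::runif(1, 0.1, 0.4) * fs)
      idx <- round(t0 * fs) + seq_len(len)
      idx <- idx[idx >= 1 & idx <= n]
      pl[idx] <- NA; pr[idx] <- NA
    }
    # speed spikes: isolated implausible jumps
    n_spk <- stats::rpois(1, dur / 60)
    idx <- sample.int(n, min(n_spk, n))
    pl[idx] <- pl[idx] + 1.5
    # gaze excursions beyond the +/-5 degree fixation window
    n_exc <- stats::rpois(1, p$excursion_rate * dur)
    for (b in seq_len(n_exc)) {
      t0 <- stats::runif(1, 0, dur)
      len <- round(stats::runif(1, 0.5, 2) * fs)
      idx <- round(t0 * fs) + seq_len(len)
      idx <- idx[idx >= 1 & idx <= n]
      gx[idx] <- gx[idx] + sample(c(-1, 1), 1) * stats::runif(1, 6, 10)
    }
    list(
      pupil_l = continuous_signal(pl, fs, "pupil_l", units = "mm"),
      pupil_r = continuous_signal(pr, fs, "pupil_r", units = "mm"),
      gaze_x = continuous_signal(gx, fs, "gaze_x", units = "deg"),
      gaze_y = continuous_signal(gy, fs, "gaze_y", units = "deg")
    )
  })
}

#' Synthesize an ECG-like recording with known beat times
#'
#' QRS-like impulse train whose instantaneous heart period follows a
#' baseline plus a US-locked bradycardia kernel scaled by the trial's true
#' amplitude (recall sessions anchor at the would-be US time). Periods are
#' constrained to [600, 1200] ms unless ectopic beats are requested.
#'
#' @inheritParams synth_emg
#' @param fs Sampling rate in Hz.
#' @param hrv Logical; add slow heart-period variability.
#' @param ectopic_at Optional vector of beat indices whose period is
#'   stretched to 1400 ms (outside the plausible range) to test rejection.
#' @return A `continuous_signal` (channel `"ecg"`). The true beat times are
#'   attached as attribute `"beat_times"`.
#' @export
synth_ecg <- function(schedule, truth, seed, fs = 1000, hrv = TRUE,
                      ectopic_at = integer(0)) {
  tr <- schedule$trials
  sp <- schedule$params
  p <- truth$params$hpr
  g <- truth$trials$hpr
  dur <- session_duration(schedule)
  anchors <- ifelse(is.na(tr$us_onset),
                    tr$cs_onset + sp$cs_duration + sp$trace_duration,
                    tr$us_onset)
  rf <- hpr_canonical_rf(fs = 10)
  period_at <- function(t) {
    pd <- p$base_period
    for (i in seq_len(nrow(tr))) {
      dt <- t - anchors[i]
      if (dt >= 0 && dt <= max(rf$grid)) {
        pd <- pd + g$amplitude[i] *
          stats::approx(rf$grid, rf$values, xout = dt, rule = 2)$y
      }
    }
    pd
  }
  withr_seed(seed, {
    hrv_t <- seq(0, dur, by = 1)
    hrv_v <- if (hrv) p$hrv_sd * ar1_noise(length(hrv_t), 0.9) else numeric(length(hrv_t))
    beats <- numeric(0)
    t <- 0.3
    k <- 0L
    while (t < dur) {
      beats <- c(beats, t)
      k <- k + 1L
      pd <- period_at(t) + stats::approx(hrv_t, hrv_v, xout = t, rule = 2)$y
      pd <- min(max(pd, 600), 1200)
      if (k %in% ectopic_at) pd <- 1400
      t <- t + pd / 1000
    }
    n <- ceiling(dur * fs)
    x <- 0.02 * stats::rnorm(n)
    tq <- seq(-0.02, 0.02, by = 1 / fs)
    qrs <- (1 - (tq / 0.008)^2) * exp(-0.5 * (tq / 0.008)^2)  # R wave with
    qrs <- qrs / max(abs(qrs))                                # Q/S side lobes
    for (b in beats) {
      i0 <- round(b * fs) - length(tq) %/% 2L
      idx <- i0 + seq_along(tq)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + qrs[keep]
    }
    out <- continuous_signal(x, fs, "ecg", units = "mV")
    attr(out, "beat_times") <- beats
    out
  })
}

#' Synthesize a respiration belt signal
#'
#' Quasi-sinusoidal breathing with cycle-amplitude modulation: the
#' instantaneous half-amplitude is the baseline times one plus an
#' anchor-locked modulation scaled by the trial's true (relative)
#' amplitude.
#'
#' @inheritParams synth_emg
#' @param fs Sampling rate in Hz.
#' @param period_jitter Standard deviation of slow breathing-period
#'   variability in seconds (0 gives a strictly periodic signal).
#' @return A `continuous_signal` (channel `"respiration"`).
#' @export
synth_respiration <- function(schedule, truth, seed, fs = 100,
                              period_jitter = 0.2) {
  tr <- schedule$trials
  sp <- schedule$params
  p <- truth$params$rar
  g <- truth$trials$rar
  dur <- session_duration(schedule)
  tg <- seq(0, dur, by = 1 / fs)
  n <- length(tg)
  anchors <- ifelse(is.na(tr$us_onset),
                    tr$cs_onset + sp$cs_duration + sp$trace_duration,
                    tr$us_onset)
  rf <- rar_early_rf(fs = 10)
  mod <- numeric(n)
  for (i in seq_len(nrow(tr))) {
    seg <- stats::approx(rf$grid + anchors[i], g$amplitude[i] * rf$values,
                         xout = tg, rule = 1)$y
    seg[is.na(seg)] <- 0
    mod <- mod + seg
  }
  withr_seed(seed, {
    per <- rep(p$base_period, n) +
      if (period_jitter > 0) period_jitter * ar1_noise(n, exp(-1 / (10 * fs))) else 0
    phase <- cumsum(2 * pi / (per * fs))
    amp <- p$base_amp * (1 + mod)
    x <- amp * sin(phase) + 0.005 * stats::rnorm(n)
    continuous_signal(x, fs, "respiration", units = "a.u.")
  })
}

#' Synthesize a full session dataset
#'
#' @inheritParams synth_emg
#' @param channels Subset of
#'   `c("emg", "scr", "pupil", "ecg", "respiration")`; `"pupil"` expands to
#'   the four eyetracker channels. EMG requires probe onsets (recall).
#' @param fs Named list of per-channel sampling-rate overrides.
#' @param subject_id Subject label stored with the dataset.
#' @return A `session_dataset`: schedule, named signal list, ground truth.
#' @export
synth_session <- function(schedule, truth, seed,
                          channels = c("scr", "pupil", "ecg", "respiration"),
                          fs = list(), subject_id = "S01") {
  rates <- utils::modifyList(
    list(emg = 2000, scr = 100, pupil = 100, ecg = 1000, respiration = 100), fs)
  signals <- list()
  for (ch in channels) {
    s <- child_seed(seed, match(ch, c("emg", "scr", "pupil", "ecg", "respiration")))
    signals <- c(signals, switch(
      ch,
      emg = list(emg = synth_emg(schedule, truth, s, fs = rates$emg)),
      scr = list(scr = synth_scr(schedule, truth, s, fs = rates$scr)),
      pupil = synth_pupil(schedule, truth, s, fs = rates$pupil),
      ecg = list(ecg = synth_ecg(schedule, truth, s, fs = rates$ecg)),
      respiration = list(respiration = synth_respiration(schedule, truth, s,
                                                         fs = rates$respiration)),
      stop("unknown channel: ", ch)))
  }
  structure(list(schedule = schedule, signals = signals, ground_truth = truth,
                 subject_id = subject_id),
            class = "session_dataset")
}

#' Population distributions for a synthetic cohort
#'
#' Per-subject baseline amplitudes are lognormal around the modality
#' defaults; the CS+ effect (`delta_mean`) is normal across subjects.
#'
#' @param delta_mu,delta_sd Mean and between-subject SD of the
#'   multiplicative CS+ effect.
#' @param amp_sdlog Lognormal SD of subject baseline amplitude scaling.
#' @export
cohort_population <- function(delta_mu = 0.3, delta_sd = 0.4,
                              amp_sdlog = 0.4) {
  list(delta_mu = delta_mu, delta_sd = delta_sd, amp_sdlog = amp_sdlog)
}

#' Synthesize a cohort of session datasets
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; subject-level seeds are derived from it.
#' @param session `"acquisition"` or `"recall"`.
#' @param channels Passed to [synth_session()].
#' @param population See [cohort_population()].
#' @param params Truth-parameter overrides shared by all subjects.
#' @param fs Per-channel sampling-rate overrides.
#' @return List of `session_dataset`s.
#' @export
synth_cohort <- function(n_subjects, seed, session = "recall",
                         channels = c("emg", "scr"),
                         population = cohort_population(), params = list(),
                         fs = list()) {
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- child_seed(seed, s)
    subj <- withr_seed(child_seed(sseed, 999L), {
      list(scale = stats::rlnorm(1, 0, population$amp_sdlog),
           delta = stats::rnorm(1, population$delta_mu, population$delta_sd))
    })
    base <- truth_params()
    ovr <- list(
      sebr = list(amp = base$sebr$amp * subj$scale, delta_mean = subj$delta),
      scr = list(amp_cs = base$scr$amp_cs * subj$scale,
                 amp_trace = base$scr$amp_trace * subj$scale,
                 amp_us = base$scr$amp_us * subj$scale,
                 delta_mean = subj$delta),
      pupil = list(delta_mean = subj$delta),
      hpr = list(delta_mean = subj$delta),
      rar = list(delta_mean = subj$delta)
    )
    sched <- generate_schedule(session, seed = child_seed(sseed, 1L))
    truth <- ground_truth(sched, utils::modifyList(utils::modifyList(base, ovr), params),
                          seed = child_seed(sseed, 2L))
    out[[s]] <- synth_session(sched, truth, sseed, channels = channels, fs = fs,
                              subject_id = sprintf("S%02d", s))
  }
  out
}

#' Simulate a cohort of normalized trial estimates directly
#'
#' Bypasses signal synthesis and draws CS--normalized response estimates at
#' the trial level: per subject, estimate = habituation factor times (1 +
#' subject effect for CS+) plus Gaussian trial noise, with the condition
#' order drawn under the run-length constraint. The population effect mean
#' is solved so that the expected paired Cohen's d of the full
#' first-`n_per_cond` average equals `d`.
#'
#' @param n_subjects Subjects per cohort.
#' @param d Target paired effect size at the full trial average (0 gives an
#'   exchangeable null cohort).
#' @param seed Integer seed.
#' @param n_per_cond Trials per condition (recall: 15).
#' @param lambda Exponential habituation rate per trial.
#' @param trial_sd Trial-level noise SD (normalized units).
#' @param delta_sd Between-subject SD of the CS+ effect.
#' @return A trial-estimate data frame (modality `"emg"`, method `"peak"`)
#'   with attribute `"target_d"`.
#' @export
simulate_estimate_cohort <- function(n_subjects, d, seed, n_per_cond = 15,
                                     lambda = 0.04, trial_sd = 0.6,
                                     delta_sd = 0.6) {
  n_trials <- 2L * n_per_cond
  # expected habituation factor of the t-th trial of a condition
  hbar <- mean(exp(-lambda * (2 * seq_len(n_per_cond) - 1.5)))
  sd_diff <- sqrt(delta_sd^2 * hbar^2 + 2 * trial_sd^2 / n_per_cond)
  mu_delta <- if (d == 0) 0 else d * sd_diff / hbar
  withr_seed(seed, {
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      cond <- sample_condition_sequence(n_per_cond, n_per_cond, 3L)
      delta_s <- stats::rnorm(1, mu_delta, delta_sd)
      h <- exp(-lambda * (seq_len(n_trials) - 1))
      y <- h * (1 + delta_s * (cond == "CS+")) +
        stats::rnorm(n_trials, 0, trial_sd)
      rows[[s]] <- data.frame(
        subject = sprintf("S%02d", s), session = "recall",
        trial_index = seq_len(n_trials), condition = cond,
        modality = "emg", method = "peak", component = "cs",
        amplitude = y, latency = NA_real_, normalized = TRUE,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "target_d") <- d
    out
  })
}
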