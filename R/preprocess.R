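#' EMG preprocessing for GLM-based startle scoring
#'
#' Band-pass (50-470 Hz, 4th-order Butterworth), 50 Hz notch, full-wave
#' rectification, then a 4th-order Butterworth low-pass with a 3-ms time
#' constant (first-order-equivalent cutoff 1/(2*pi*0.003) ~ 53.05 Hz). All
#' stages are causal (forward filtering); length is preserved.
#'
#' @param emg A `continuous_signal` (channel `"emg"`), sampling rate at
#'   least twice the 470 Hz upper band edge.
#' @return A `continuous_signal` holding the smoothed rectified envelope.
#' @export
emg_preprocess_glm <- function(emg) {
  stopifnot(inherits(emg, "continuous_signal"), emg$channel == "emg")
  fs <- emg$sampling_rate
  if (fs < 2 * 470) stop("sampling rate must be at least 940 Hz")
  x <- butter_apply(emg$samples, 4, c(50, 470), "pass", fs)
  x <- notch_apply(x, fs, 50, Q = 35)
  x <- abs(x)
  fc <- 1 / (2 * pi * 0.003)
  x <- butter_apply(x, 4, fc, "low", fs)
  continuous_signal(x, fs, "emg", units = emg$units,
                    missing_mask = emg$missing_mask)
}

#' EMG preprocessing for peak scoring
#'
#' High-pass at 30 Hz (4th-order Butterworth), 50 Hz notch, full-wave
#' rectification, then a centered 20-ms moving average.
#'
#' @inheritParams emg_preprocess_glm
#' @return A `continuous_signal` holding the smoothed rectified envelope.
#' @export
emg_preprocess_peak <- function(emg) {
  stopifnot(inherits(emg, "continuous_signal"), emg$channel == "emg")
  fs <- emg$sampling_rate
  x <- butter_apply(emg$samples, 4, 30, "high", fs)
  x <- notch_apply(x, fs, 50, Q = 35)
  x <- moving_average(abs(x), round(0.020 * fs))
  continuous_signal(x, fs, "emg", units = emg$units,
                    missing_mask = emg$missing_mask)
}

#' Skin conductance preprocessing
#'
#' Causal (forward-only) first-order Butterworth band-pass at
#' 0.0159-5 Hz, anti-aliased decimation to 10 Hz (4 Hz low-pass before
#' subsampling), and masking of the electric-stimulation artifact window
#' `[US - 0.2 s, US + 1.6 s)` on every reinforced trial.
#'
#' @param scr A `continuous_signal` (channel `"scr"`).
#' @param schedule The session's `trial_schedule` (US onsets drive the
#'   artifact mask; schedules without US leave the mask empty).
#' @param fs_out Output rate in Hz (default 10; must divide the input rate).
#' @return A 10 Hz `continuous_signal` with the artifact mask set.
#' @export
scr_preprocess <- function(scr, schedule, fs_out = 10) {
  stopifnot(inherits(scr, "continuous_signal"), scr$channel == "scr")
  fs <- scr$sampling_rate
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-9 || dec < 1)
    stop("input rate must be an integer multiple of the output rate")
  dec <- as.integer(round(dec))
  x <- butter_apply(scr$samples, 1, c(0.0159, 5), "pass", fs)
  if (dec > 1L) {
    x <- butter_apply(x, 4, 0.8 * fs_out / 2, "low", fs)
    keep <- seq(1, length(x), by = dec)
    mask <- vapply(keep, function(i) {
      any(scr$missing_mask[i:min(i + dec - 1L, length(x))])
    }, logical(1))
    x <- x[keep]
  } else {
    mask <- scr$missing_mask
  }
  t10 <- (seq_along(x) - 1) / fs_out
  us <- schedule$trials$us_onset
  for (u in us[!is.na(us)]) {
    mask[t10 >= u - 0.2 - 1e-9 & t10 < u + 1.6 - 1e-9] <- TRUE
  }
  continuous_signal(x, fs_out, "scr", units = scr$units, missing_mask = mask)
}

#' Pupil validity-filter configuration
#'
#' Thresholds of the valid-sample determination: plausible diameter range,
#' maximum dilation speed (median-absolute-deviation multiplier on the
#' two-sided sample-to-sample speed), an edge margin removed around gaps, a
#' trendline-deviation pass, and a minimum valid-island length. Defaults
#' follow the common defaults of the cited preprocessing literature.
#'
#' @param range_mm Plausible diameter range in mm.
#' @param speed_mad_mult MAD multiplier of the speed threshold.
#' @param edge_margin_s Margin invalidated around gaps, seconds.
#' @param trend_mad_mult MAD multiplier of the trendline-deviation
#'   threshold.
#' @param trend_window_s Moving-average window of the trendline, seconds.
#' @param island_min_s Minimum length of a valid island, seconds.
#' @param gaze_limit_deg Fixation window half-width in visual degrees.
#' @param exclusion_fraction Trials with a missing fraction strictly above
#'   this (CS onset to US timepoint) are flagged excluded.
#' @export
pupil_filter_config <- function(range_mm = c(1.5, 9), speed_mad_mult = 16,
                                edge_margin_s = 0.05, trend_mad_mult = 16,
                                trend_window_s = 0.3, island_min_s = 0.05,
                                gaze_limit_deg = 5, exclusion_fraction = 0.5) {
  list(range_mm = range_mm, speed_mad_mult = speed_mad_mult,
       edge_margin_s = edge_margin_s, trend_mad_mult = trend_mad_mult,
       trend_window_s = trend_window_s, island_min_s = island_min_s,
       gaze_limit_deg = gaze_limit_deg, exclusion_fraction = exclusion_fraction)
}

valid_filter_one_eye <- function(x, fs, cfg) {
  valid <- is.finite(x)
  valid[valid] <- x[valid] >= cfg$range_mm[1] & x[valid] <= cfg$range_mm[2]
  # two-sided dilation speed
  d <- abs(diff(x)) * fs
  spd <- pmax(c(d, NA), c(NA, d))
  thr <- stats::median(spd, na.rm = TRUE) +
    cfg$speed_mad_mult * stats::mad(spd, na.rm = TRUE)
  if (is.finite(thr)) valid[!is.na(spd) & spd > thr] <- FALSE
  # edge margin around gaps
  m <- max(1L, round(cfg$edge_margin_s * fs))
  gaps <- which(!valid)
  if (length(gaps)) {
    edge <- unique(unlist(lapply(gaps, function(i) (i - m):(i + m))))
    edge <- edge[edge >= 1 & edge <= length(x)]
    valid[edge] <- FALSE
  }
  # trendline deviation
  if (any(valid)) {
    interp <- stats::approx(which(valid), x[valid], xout = seq_along(x),
                            rule = 2)$y
    trend <- moving_average(interp, round(cfg$trend_window_s * fs))
    dev <- abs(x - trend)
    thr <- stats::median(dev[valid], na.rm = TRUE) +
      cfg$trend_mad_mult * stats::mad(dev[valid], na.rm = TRUE)
    if (is.finite(thr) && thr > 0) valid[!is.na(dev) & dev > thr] <- FALSE
  }
  # isolated-sample (short island) removal
  r <- rle(valid)
  min_len <- max(1L, round(cfg$island_min_s * fs))
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

#' Pupil preprocessing
#'
#' Applies, in order and per eye: range, speed, edge, trendline, and
#' isolated-sample validity filtering; combines both eyes by averaging
#' valid samples (single-eye fallback); marks samples with gaze outside
#' the +/-5 degree fixation window as missing; linearly interpolates and
#' smoothes with a 1-s moving average for time-course analysis; and flags
#' trials whose missing fraction between CS onset and the (expected) US
#' timepoint exceeds 50%.
#'
#' @param pupil_l,pupil_r,gaze_x,gaze_y `continuous_signal`s on a common
#'   grid (pupil in mm, gaze in degrees).
#' @param schedule The session's `trial_schedule`.
#' @param config See [pupil_filter_config()].
#' @return A `pupil_series`: `time`, `diameter` (NA where missing),
#'   `missing_mask`, `smoothed` (interpolated + 1-s moving average),
#'   `sampling_rate`, and a per-trial data frame with `missing_fraction`
#'   and `excluded`.
#' @export
pupil_preprocess <- function(pupil_l, pupil_r, gaze_x, gaze_y, schedule,
                             config = pupil_filter_config()) {
  fs <- pupil_l$sampling_rate
  stopifnot(pupil_r$sampling_rate == fs, gaze_x$sampling_rate == fs,
            gaze_y$sampling_rate == fs)
  n <- length(pupil_l$samples)
  xl <- pupil_l$samples; xl[pupil_l$missing_mask] <- NA
  xr <- pupil_r$samples; xr[pupil_r$missing_mask] <- NA
  vl <- valid_filter_one_eye(xl, fs, config)
  vr <- valid_filter_one_eye(xr, fs, config)
  num <- ifelse(vl, xl, 0) + ifelse(vr, xr, 0)
  den <- as.numeric(vl) + as.numeric(vr)
  diam <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  ecc <- sqrt(gaze_x$samples^2 + gaze_y$samples^2)
  off_fix <- !is.finite(ecc) | ecc > config$gaze_limit_deg
  diam[off_fix] <- NA
  missing <- !is.finite(diam)
  tgrid <- (seq_len(n) - 1) / fs
  interp <- rep(NA_real_, n)
  smoothed <- rep(NA_real_, n)
  if (any(!missing)) {
    interp <- stats::approx(tgrid[!missing], diam[!missing], xout = tgrid,
                            rule = 2)$y
    smoothed <- moving_average(interp, round(1 * fs))
  }
  tr <- schedule$trials
  sp <- schedule$params
  us_time <- tr$cs_onset + sp$cs_duration + sp$trace_duration
  frac <- vapply(seq_len(nrow(tr)), function(i) {
    win <- tgrid >= tr$cs_onset[i] & tgrid <= us_time[i]
    if (!any(win)) return(NA_real_)
    mean(missing[win])
  }, numeric(1))
  structure(
    list(time = tgrid, diameter = diam, missing_mask = missing,
         interpolated = interp, smoothed = smoothed, sampling_rate = fs,
         trials = data.frame(trial_index = tr$trial_index,
                             condition = tr$condition,
                             missing_fraction = frac,
                             excluded = !is.na(frac) &
                               frac > config$exclusion_fraction),
         config = config),
    class = "pupil_series"
  )
}

#' @export
print.pupil_series <- function(x, ...) {
  cat(sprintf("<pupil_series> %d samples @ %g Hz, %.1f%% missing, %d/%d trials excluded\n",
              length(x$diameter), x$sampling_rate, 100 * mean(x$missing_mask),
              sum(x$trials$excluded), nrow(x$trials)))
  invisible(x)
}

# Pan-Tompkins style QRS detection: band-pass, derivative, squaring,
# moving-window integration, adaptive thresholding with search-back
detect_r_peaks <- function(x, fs, refractory = 0.2, integration = 0.150) {
  bp <- butter_apply(x, 3, c(5, 15), "pass", fs, zero_phase = TRUE)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  mwi <- moving_average(sq, round(integration * fs))
  refr <- round(refractory * fs)
  n <- length(mwi)
  # candidate local maxima
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) return(numeric(0))
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  peaks <- integer(0)
  rr_avg <- NA_real_
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    c0 <- cand[i]
    thr <- npki + 0.25 * (spki - npki)
    if (c0 - last >= refr && mwi[c0] > thr) {
      peaks <- c(peaks, c0)
      spki <- 0.125 * mwi[c0] + 0.875 * spki
      if (length(peaks) >= 2L) {
        rrs <- diff(utils::tail(peaks, 8))
        rr_avg <- mean(rrs)
      }
      last <- c0
    } else {
      npki <- 0.125 * mwi[c0] + 0.875 * npki
      # search-back: no beat within 1.66 expected RR intervals
      if (!is.na(rr_avg) && c0 - last > 1.66 * rr_avg) {
        win <- cand[cand > last + refr & cand <= c0]
        if (length(win)) {
          best <- win[which.max(mwi[win])]
          if (mwi[best] > thr / 2) {
            peaks <- c(peaks, best)
            spki <- 0.25 * mwi[best] + 0.75 * spki
            last <- best
          }
        }
      }
    }
    i <- i + 1L
  }
  peaks <- sort(unique(peaks))
  # the integration stage flattens each beat into a plateau, so candidate
  # positions jitter; refine to the raw-signal R peak on both sides
  half <- round(integration * fs)
  refined <- vapply(peaks, function(pk) {
    lo <- max(1L, pk - half)
    hi <- min(n, pk + half)
    (lo:hi)[which.max(x[lo:hi])]
  }, integer(1))
  refined <- sort(unique(refined))
  # collapse refinements that landed on the same beat
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  refined / fs
}

# 0.015-0.5 Hz zero-phase band-pass on the 10 Hz grid. The band edges sit
# so close to DC that an 8-pole transfer-function band-pass is numerically
# ill-conditioned; the 4th-order response is realized as a cascade of
# well-conditioned 2nd-order high-pass and low-pass Butterworth stages.
heart_period_bandpass <- function(x, fs) {
  butter_apply(butter_apply(x, 2, 0.015, "high", fs, zero_phase = TRUE),
               2, 0.5, "low", fs, zero_phase = TRUE)
}

#' ECG to interpolated heart period
#'
#' Detects R peaks with a Pan-Tompkins style QRS detector (band-pass,
#' derivative, squaring, 150-ms moving-window integration, adaptive
#' thresholding with search-back, 200-ms refractory period), assigns each
#' inter-beat interval to the later beat, rejects IBIs outside 600-1200 ms
#' (50-100 bpm), linearly interpolates the accepted IBIs to a 10 Hz grid,
#' and band-pass filters the result with a 4th-order bidirectional
#' (zero-phase) Butterworth filter at 0.015-0.5 Hz.
#'
#' @param ecg A `continuous_signal` (channel `"ecg"`).
#' @param fs_out Output grid rate in Hz.
#' @return A `heart_period_series`: `time`, `period` (interpolated ms),
#'   `filtered` (band-passed), the per-beat IBI table, and accepted /
#'   rejected counts.
#' @export
ecg_to_heart_period <- function(ecg, fs_out = 10) {
  stopifnot(inherits(ecg, "continuous_signal"), ecg$channel == "ecg")
  fs <- ecg$sampling_rate
  beats <- detect_r_peaks(ecg$samples, fs)
  if (length(beats) < 2L) stop("fewer than 2 beats detected")
  ibi <- diff(beats) * 1000
  ibi_time <- beats[-1]              # assigned to the later beat
  accepted <- ibi >= 600 & ibi <= 1200
  if (sum(accepted) < 2L) stop("fewer than 2 accepted inter-beat intervals")
  tgrid <- seq(0, (length(ecg$samples) - 1) / fs, by = 1 / fs_out)
  period <- stats::approx(ibi_time[accepted], ibi[accepted], xout = tgrid,
                          rule = 2)$y
  filtered <- heart_period_bandpass(period, fs_out)
  structure(
    list(time = tgrid, period = period, filtered = filtered,
         ibi = data.frame(time = ibi_time, ibi = ibi, accepted = accepted),
         beats = beats,
         n_accepted = sum(accepted), n_rejected = sum(!accepted),
         sampling_rate = fs_out),
    class = "heart_period_series"
  )
}

#' @export
print.heart_period_series <- function(x, ...) {
  cat(sprintf("<heart_period_series> %d beats, %d IBIs accepted / %d rejected, %g Hz grid\n",
              length(x$beats), x$n_accepted, x$n_rejected, x$sampling_rate))
  invisible(x)
}

#' Respiration belt to interpolated cycle amplitude
#'
#' Detects inspiration onsets as positive-going zero crossings of the
#' band-limited (0.04-1 Hz) detrended signal, computes each cycle's
#' peak-to-trough amplitude, assigns it to the beginning of the next
#' cycle, and linearly interpolates to a 10 Hz grid. No further filtering.
#'
#' @param resp A `continuous_signal` (channel `"respiration"`).
#' @param fs_out Output grid rate in Hz.
#' @return A `respiration_amplitude_series`: `time`, `amplitude`, and the
#'   per-cycle table (`onset`, `amplitude`).
#' @export
respiration_to_amplitude <- function(resp, fs_out = 10) {
  stopifnot(inherits(resp, "continuous_signal"), resp$channel == "respiration")
  fs <- resp$sampling_rate
  x <- butter_apply(resp$samples, 2, c(0.04, 1), "pass", fs, zero_phase = TRUE)
  up <- which(x[-length(x)] <= 0 & x[-1] > 0)
  if (length(up) < 3L) stop("fewer than 2 full respiration cycles detected")
  onsets <- up / fs
  k <- length(up)
  amp <- vapply(seq_len(k - 1L), function(i) {
    seg <- x[up[i]:up[i + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
  # cycle i's amplitude belongs to the start of cycle i+1
  amp_time <- onsets[-1]
  tgrid <- seq(0, (length(resp$samples) - 1) / fs, by = 1 / fs_out)
  series <- stats::approx(amp_time, amp, xout = tgrid, rule = 2)$y
  structure(
    list(time = tgrid, amplitude = series,
         cycles = data.frame(onset = onsets[-1], amplitude = amp),
         sampling_rate = fs_out),
    class = "respiration_amplitude_series"
  )
}

#' @export
print.respiration_amplitude_series <- function(x, ...) {
  cat(sprintf("<respiration_amplitude_series> %d cycles, %g Hz grid\n",
              nrow(x$cycles), x$sampling_rate))
  invisible(x)
}

#' Coerce preprocessed series to a continuous signal
#'
#' Heart-period and respiration-amplitude series expose their 10 Hz values
#' as a `continuous_signal` so the GLM quantifier can consume them; the
#' heart-period method uses the band-passed values. A `pupil_series`
#' exposes its interpolated and smoothed diameter.
#'
#' @param x A series object.
#' @param ... Unused.
#' @export
as_continuous_signal <- function(x, ...) UseMethod("as_continuous_signal")

#' @export
as_continuous_signal.continuous_signal <- function(x, ...) x

#' @export
as_continuous_signal.heart_period_series <- function(x, ...) {
  continuous_signal(x$filtered, x$sampling_rate, "ecg", units = "ms")
}

#' @export
as_continuous_signal.respiration_amplitude_series <- function(x, ...) {
  continuous_signal(x$amplitude, x$sampling_rate, "respiration", units = "a.u.")
}

#' @export
as_continuous_signal.pupil_series <- function(x, fs_out = NULL,
                                              field = c("interpolated",
                                                        "smoothed"), ...) {
  field <- match.arg(field)
  v <- x[[field]]
  fs <- x$sampling_rate
  if (!is.null(fs_out) && fs_out < fs) {
    dec <- fs / fs_out
    if (abs(dec - round(dec)) > 1e-9)
      stop("fs_out must divide the pupil sampling rate")
    v <- butter_apply(v, 4, 0.8 * fs_out / 2, "low", fs, zero_phase = TRUE)
    v <- v[seq(1, length(v), by = as.integer(round(dec)))]
    fs <- fs_out
  }
  continuous_signal(v, fs, "pupil_l", units = "mm")
}
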