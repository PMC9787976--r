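new_estimates <- function(subject, session, trial_index, condition, modality,
                          method, component, amplitude,
                          latency = NA_real_, normalized = FALSE,
                          flagged = FALSE) {
  data.frame(subject = subject, session = session, trial_index = trial_index,
             condition = condition, modality = modality, method = method,
             component = component, amplitude = amplitude, latency = latency,
             normalized = normalized, flagged = flagged,
             stringsAsFactors = FALSE)
}

probe_onsets_of <- function(schedule) {
  if (inherits(schedule, "trial_schedule")) {
    po <- schedule$trials$probe_onset
    if (all(is.na(po))) stop("schedule has no probe onsets")
    po
  } else as.numeric(schedule)
}

#' Peak scoring of startle eyeblink responses
#'
#' Per startle probe, the response amplitude is the maximum of the
#' preprocessed EMG envelope in the closed window 20-100 ms after probe
#' onset (inclusive endpoints on the sample grid).
#'
#' @param env Envelope from [emg_preprocess_peak()].
#' @param schedule A recall `trial_schedule` (or a numeric vector of probe
#'   onsets in seconds).
#' @param window Scoring window relative to probe onset, seconds.
#' @param subject,session Labels attached to the estimates.
#' @return A trial-estimate data frame (method `"peak"`).
#' @export
sebr_peak_score <- function(env, schedule, window = c(0.020, 0.100),
                            subject = "S01", session = "recall") {
  stopifnot(inherits(env, "continuous_signal"))
  probes <- probe_onsets_of(schedule)
  fs <- env$sampling_rate
  n <- length(env$samples)
  amp <- vapply(probes, function(p0) {
    i0 <- ceiling((p0 + window[1]) * fs - 1e-9) + 1L
    i1 <- floor((p0 + window[2]) * fs + 1e-9) + 1L
    if (i0 < 1L || i1 > n) stop("scoring window exceeds the recording")
    max(env$samples[i0:i1])
  }, numeric(1))
  cond <- if (inherits(schedule, "trial_schedule")) schedule$trials$condition
          else rep(NA_character_, length(probes))
  new_estimates(subject, session, seq_along(probes), cond, "emg", "peak",
                "cs", amp)
}

#' GLM scoring of startle eyeblink responses with variable onset
#'
#' Per trial, the envelope segment after the probe is regressed onto the
#' canonical blink response function shifted over a grid of candidate
#' onsets (default 0-100 ms post-probe in 1-ms steps, plus an intercept);
#' the amplitude is the regression slope at the onset minimizing the
#' residual sum of squares.
#'
#' @param env Envelope from [emg_preprocess_glm()].
#' @inheritParams sebr_peak_score
#' @param rf Canonical blink response function ([sebr_canonical_rf()]).
#' @param onset_grid Candidate onsets after probe onset, seconds.
#' @return A trial-estimate data frame (method `"glm"`, `latency` = best
#'   onset).
#' @export
sebr_glm <- function(env, schedule, rf = NULL,
                     onset_grid = seq(0, 0.1, by = 0.001),
                     subject = "S01", session = "recall") {
  stopifnot(inherits(env, "continuous_signal"))
  probes <- probe_onsets_of(schedule)
  fs <- env$sampling_rate
  if (is.null(rf)) rf <- sebr_canonical_rf(fs = fs)
  rfv <- rf_resample(rf, fs)$values
  seg_len <- length(rfv) + round(max(onset_grid) * fs)
  n <- length(env$samples)
  res <- lapply(probes, function(p0) {
    i0 <- round(p0 * fs) + 1L
    if (i0 < 1L || i0 + seg_len - 1L > n) stop("segment exceeds the recording")
    y <- env$samples[i0:(i0 + seg_len - 1L)]
    best <- c(rss = Inf, amp = NA_real_, onset = NA_real_)
    for (on in onset_grid) {
      shift <- round(on * fs)
      reg <- c(rep(0, shift), rfv)[seq_len(seg_len)]
      reg[is.na(reg)] <- 0
      f <- stats::lm.fit(cbind(1, reg), y)
      rss <- sum(f$residuals^2)
      if (rss < best["rss"]) best <- c(rss = rss,
                                       amp = unname(f$coefficients[2]),
                                       onset = on)
    }
    best
  })
  cond <- if (inherits(schedule, "trial_schedule")) schedule$trials$condition
          else rep(NA_character_, length(probes))
  new_estimates(subject, session, seq_along(probes), cond, "emg", "glm", "cs",
                vapply(res, `[[`, numeric(1), "amp"),
                latency = vapply(res, `[[`, numeric(1), "onset"))
}

#' Three-burst trial model of the skin conductance response
#'
#' Burst structure and constraints for trial-wise inversion: CS- and
#' US-locked bursts at fixed latencies after the respective event, and one
#' trace-interval burst with free latency between 8 s after CS offset and
#' 1 s before (expected) US onset, all with fixed Gaussian dispersion and
#' non-negative amplitudes.
#'
#' @param kernel Conductance kernel ([scr_kernel_rf()]).
#' @param sigma Gaussian burst dispersion in seconds (fixed during
#'   fitting).
#' @param delta_cs,delta_us Fixed burst latencies after CS / US onset, s.
#' @param latency_lo Trace-window start after CS offset, s.
#' @param latency_hi Trace-window end before US onset, s.
#' @export
scr_trial_model <- function(kernel = scr_kernel_rf(), sigma = 0.3,
                            delta_cs = 1.0, delta_us = 1.0,
                            latency_lo = 8, latency_hi = 1) {
  list(kernel = kernel, sigma = sigma, delta_cs = delta_cs,
       delta_us = delta_us, latency_lo = latency_lo, latency_hi = latency_hi)
}

# non-negative least squares with a free intercept (profiled out by
# centering); returns amplitudes and residual sum of squares
nnls_with_intercept <- function(X, y) {
  ybar <- mean(y)
  Xbar <- colMeans(X)
  Xc <- sweep(X, 2, Xbar)
  fit <- pracma::lsqnonneg(Xc, y - ybar)
  a <- fit$x
  resid <- (y - ybar) - Xc %*% a
  list(a = a, rss = sum(resid^2), intercept = ybar - sum(Xbar * a))
}

#' Invert the three-burst SCR trial model
#'
#' Per trial, minimizes the squared error between the (preprocessed,
#' 10 Hz) skin conductance segment and the sum of the three burst
#' responses, subject to non-negative amplitudes and the trace-latency
#' bounds. The trace latency is profiled: amplitudes are solved by
#' non-negative least squares at each latency of a coarse grid, followed
#' by bounded local refinement around the best grid point. Masked samples
#' are excluded from the objective. A fit whose latency clamps to a
#' window bound (or that fails) is flagged, not dropped.
#'
#' @param scr10 10 Hz `continuous_signal` from [scr_preprocess()] (a raw
#'   10 Hz signal works for noiseless self-consistency checks).
#' @param schedule The session's `trial_schedule`.
#' @param model See [scr_trial_model()].
#' @param grid_step Coarse latency-grid step in seconds.
#' @param subject Label attached to the estimates.
#' @return Trial-estimate rows (method `"nls"`) with components `"cs"`,
#'   `"trace"` (with latency, seconds from CS onset), and `"us"`.
#' @export
fit_scr_trial_model <- function(scr10, schedule, model = scr_trial_model(),
                                grid_step = 0.5, subject = "S01") {
  stopifnot(inherits(scr10, "continuous_signal"))
  fs <- scr10$sampling_rate
  tr <- schedule$trials
  sp <- schedule$params
  tgrid <- signal_time(scr10)
  kern <- model$kernel
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    cs <- tr$cs_onset[i]
    us_nominal <- cs + sp$cs_duration + sp$trace_duration
    lat_lo <- sp$cs_duration + model$latency_lo
    lat_hi <- sp$cs_duration + sp$trace_duration - model$latency_hi
    seg_idx <- which(tgrid >= cs - 1e-9 &
                       tgrid <= us_nominal + 10 - 1e-9)
    ts_full <- tgrid[seg_idx]                 # uniform segment grid
    ok <- !scr10$missing_mask[seg_idx]
    y <- scr10$samples[seg_idx][ok]
    reg_cs <- scr_burst_response(ts_full, cs + model$delta_cs, model$sigma,
                                 kern, fs)[ok]
    reg_us <- scr_burst_response(ts_full, us_nominal + model$delta_us,
                                 model$sigma, kern, fs)[ok]
    obj <- function(lat) {
      reg_tr <- scr_burst_response(ts_full, cs + lat, model$sigma, kern, fs)[ok]
      nnls_with_intercept(cbind(reg_cs, reg_tr, reg_us), y)
    }
    fit <- tryCatch({
      grid <- seq(lat_lo, lat_hi, by = grid_step)
      rss <- vapply(grid, function(l) obj(l)$rss, numeric(1))
      best <- grid[which.min(rss)]
      opt <- stats::optimize(function(l) obj(l)$rss,
                             lower = max(lat_lo, best - grid_step),
                             upper = min(lat_hi, best + grid_step))
      lat <- opt$minimum
      # keep the better of grid point and refinement
      if (obj(best)$rss < opt$objective) lat <- best
      sol <- obj(lat)
      at_bound <- lat <= lat_lo + 1e-3 || lat >= lat_hi - 1e-3
      list(a = sol$a, lat = lat, flagged = at_bound, ok = TRUE)
    }, error = function(e) list(a = rep(NA_real_, 3), lat = NA_real_,
                                flagged = TRUE, ok = FALSE))
    out[[i]] <- new_estimates(
      subject, schedule$session, rep(tr$trial_index[i], 3),
      rep(tr$condition[i], 3), "scr", "nls", c("cs", "trace", "us"),
      as.numeric(fit$a),
      latency = c(NA_real_, fit$lat, NA_real_),
      flagged = fit$flagged)
  }
  do.call(rbind, out)
}

#' Area under the skin conductance curve
#'
#' Trapezoidal integral of the baseline-subtracted (value at CS onset)
#' signal from CS onset to the (expected) US timepoint; masked samples are
#' linearly interpolated first.
#'
#' @inheritParams fit_scr_trial_model
#' @param cs_onset,us_onset Window bounds in seconds.
#' @param trial_index,condition,subject Labels for the estimate row.
#' @return A single trial-estimate row (method `"auc"`).
#' @export
scr_auc <- function(scr10, cs_onset, us_onset, trial_index = 1L,
                    condition = NA_character_, subject = "S01") {
  stopifnot(inherits(scr10, "continuous_signal"), us_onset > cs_onset)
  tgrid <- signal_time(scr10)
  y <- scr10$samples
  if (any(scr10$missing_mask)) {
    ok <- !scr10$missing_mask
    y <- stats::approx(tgrid[ok], y[ok], xout = tgrid, rule = 2)$y
  }
  win <- tgrid >= cs_onset - 1e-9 & tgrid <= us_onset + 1e-9
  base <- stats::approx(tgrid, y, xout = cs_onset, rule = 2)$y
  auc <- trapz_int(tgrid[win], y[win] - base)
  new_estimates(subject, "acquisition", trial_index, condition, "scr", "auc",
                "whole_trial", auc)
}

#' Estimate a response function from trial-averaged time courses
#'
#' Builds an empirical RF from condition-average curves of a training
#' dataset: the grand-average CS+ curve minus its pre-CS baseline (or the
#' CS+ minus CS- difference), smoothed with a 1-s moving average,
#' truncated to 0-17 s after CS onset, and peak-normalized. The RF records
#' its source dataset so that evaluation on the same dataset can be
#' refused downstream. A warning is raised when the peak does not rise
#' above the curve's sample-to-sample noise level.
#'
#' @param curves Subjects x timepoints matrix of per-subject CS+ average
#'   curves (or, for `mode = "difference"`, CS+ minus CS- curves).
#' @param time Time grid of the columns, seconds relative to CS onset
#'   (points at or before 0 define the baseline; otherwise the first
#'   sample is used).
#' @param dataset_id Identifier of the source dataset (required).
#' @param kind RF label, e.g. `"pupil_fitted"` or `"hpr_fitted"`.
#' @param mode Curve combination: CS+ average (default) or difference.
#' @param snr_threshold Peak-to-noise ratio below which a warning is
#'   raised.
#' @return A `response_function` carrying `source_dataset`.
#' @export
estimate_rf_from_timecourse <- function(curves, time, dataset_id,
                                        kind = "pupil_fitted",
                                        mode = c("csplus", "difference"),
                                        snr_threshold = 3) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(curves), ncol(curves) == length(time),
            is.character(dataset_id), nzchar(dataset_id))
  avg <- colMeans(curves, na.rm = TRUE)
  base_idx <- which(time <= 0)
  base <- if (length(base_idx)) mean(avg[base_idx]) else avg[1]
  v <- avg - base
  dt <- stats::median(diff(time))
  v <- moving_average(v, max(1L, round(1 / dt)))
  keep <- time >= 0 & time <= 17
  v <- v[keep]
  grid <- time[keep]
  noise <- stats::sd(diff(avg)) / sqrt(2)
  if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
  if (max(abs(v)) / noise < snr_threshold) {
    warning("fitted response function peak is below the noise threshold")
  }
  response_function(kind, grid, v, params = list(mode = mode),
                    source_dataset = dataset_id)
}

anchor_times <- function(schedule, anchor) {
  tr <- schedule$trials
  sp <- schedule$params
  if (anchor == "cs") tr$cs_onset
  else ifelse(is.na(tr$us_onset),
              tr$cs_onset + sp$cs_duration + sp$trace_duration,
              tr$us_onset)
}

#' GLM quantification of slow-channel responses
#'
#' Ordinary least squares of a 10 Hz series on response-function
#' regressors shifted to each trial's anchor event (CS onset, or US onset
#' -- the would-be US time on unreinforced trials), plus an intercept and
#' a linear drift. One regressor per RF per trial (trial granularity) or
#' per condition (condition granularity). Masked samples are excluded.
#'
#' @param series A 10 Hz `continuous_signal` (or any object with an
#'   [as_continuous_signal()] method).
#' @param schedule The session's `trial_schedule`.
#' @param rfs A `response_function` or named list of them (e.g. early and
#'   late respiration RFs); names become estimate components.
#' @param anchor `"cs"` or `"us"`.
#' @param granularity `"trial"` or `"condition"`.
#' @param dataset_id Identifier of the evaluated dataset; if both this and
#'   an RF's `source_dataset` are set and equal, the fit is refused unless
#'   `allow_same_dataset = TRUE` (train/evaluate separation for fitted
#'   RFs).
#' @param allow_same_dataset Override the separation check.
#' @param exclude_trials Optional trial indices dropped from the design
#'   (e.g. pupil trials flagged excluded); their estimates are `NA`.
#' @param subject Label attached to the estimates.
#' @param modality Modality label of the estimates.
#' @return Trial- (or condition-) estimate rows, method `"glm"`.
#' @export
glm_quantify <- function(series, schedule, rfs, anchor = c("cs", "us"),
                         granularity = c("trial", "condition"),
                         dataset_id = NULL, allow_same_dataset = FALSE,
                         exclude_trials = integer(0), subject = "S01",
                         modality = NULL) {
  anchor <- match.arg(anchor)
  granularity <- match.arg(granularity)
  series <- as_continuous_signal(series)
  if (inherits(rfs, "response_function")) {
    rfs <- stats::setNames(list(rfs), default_component(rfs$kind, anchor))
  }
  if (is.null(names(rfs)) || any(!nzchar(names(rfs))))
    names(rfs) <- vapply(rfs, function(r) default_component(r$kind, anchor), "")
  for (rf in rfs) {
    if (!is.null(dataset_id) && !is.null(rf$source_dataset) &&
        identical(rf$source_dataset, dataset_id) && !allow_same_dataset) {
      stop("fitted RF was built on this dataset; evaluation refused ",
           "(set allow_same_dataset = TRUE to override)")
    }
  }
  if (is.null(modality)) {
    modality <- switch(series$channel, scr = "scr", ecg = "hpr",
                       respiration = "rar", "pupil")
  }
  fs <- series$sampling_rate
  tgrid <- signal_time(series)
  n <- length(tgrid)
  tr <- schedule$trials
  anchors <- anchor_times(schedule, anchor)
  keep_trial <- !(tr$trial_index %in% exclude_trials)
  conds <- sort(unique(tr$condition))
  cols <- list()
  labels <- list()
  for (rf_name in names(rfs)) {
    rfv <- rf_resample(rfs[[rf_name]], fs)$values
    make_col <- function(trials_in) {
      col <- numeric(n)
      for (i in trials_in) {
        i0 <- round(anchors[i] * fs)
        idx <- i0 + seq_along(rfv)
        ok <- idx >= 1 & idx <= n
        col[idx[ok]] <- col[idx[ok]] + rfv[ok]
      }
      col
    }
    if (granularity == "trial") {
      for (i in which(keep_trial)) {
        cols <- c(cols, list(make_col(i)))
        labels <- c(labels, list(c(rf_name, i)))
      }
    } else {
      for (cc in conds) {
        cols <- c(cols, list(make_col(which(keep_trial & tr$condition == cc))))
        labels <- c(labels, list(c(rf_name, cc)))
      }
    }
  }
  X <- cbind(do.call(cbind, cols), 1, seq_len(n) / n)
  ok <- !series$missing_mask
  fit <- stats::lm.fit(X[ok, , drop = FALSE], series$samples[ok])
  beta <- fit$coefficients[seq_along(cols)]
  if (granularity == "trial") {
    rows <- lapply(seq_along(cols), function(j) {
      i <- as.integer(labels[[j]][2])
      new_estimates(subject, schedule$session, tr$trial_index[i],
                    tr$condition[i], modality, "glm", labels[[j]][1], beta[j])
    })
    dropped <- which(!keep_trial)
    if (length(dropped)) {
      rows <- c(rows, lapply(dropped, function(i) {
        new_estimates(subject, schedule$session, tr$trial_index[i],
                      tr$condition[i], modality, "glm", names(rfs)[1],
                      NA_real_, flagged = TRUE)
      }))
    }
    out <- do.call(rbind, rows)
    out[order(out$trial_index, out$component), ]
  } else {
    do.call(rbind, lapply(seq_along(cols), function(j) {
      new_estimates(subject, schedule$session, NA_integer_, labels[[j]][2],
                    modality, "glm", labels[[j]][1], beta[j])
    }))
  }
}

default_component <- function(kind, anchor) {
  switch(kind,
         rar_early = "early", rar_late = "late",
         hpr_us_locked = "us", hpr_fitted = "us",
         if (anchor == "us") "us" else "cs")
}

#' Normalize trial estimates by the subject's CS- mean
#'
#' Divides every amplitude by the mean amplitude of the same subject's
#' CS- trials for that session, modality, method, and component,
#' correcting for between-subject scaling differences (electrode
#' impedance, anatomy). After normalization the CS- mean is exactly 1.
#' Subjects whose CS- mean does not exceed `eps` times the group
#' amplitude scale are flagged and their normalized values set to `NA`.
#'
#' @param estimates A trial-estimate data frame.
#' @param eps Relative tolerance for a usable CS- mean.
#' @return The estimates with normalized amplitudes (`normalized = TRUE`);
#'   excluded subjects are listed in attribute `"excluded_subjects"`.
#' @export
normalize_by_cs_minus <- function(estimates, eps = 1e-9) {
  est <- estimates
  key <- interaction(est$subject, est$session, est$modality, est$method,
                     est$component, drop = TRUE)
  scale_all <- mean(abs(est$amplitude), na.rm = TRUE)
  excluded <- character(0)
  for (k in levels(key)) {
    idx <- which(key == k)
    neg <- idx[est$condition[idx] == "CS-"]
    if (!length(neg)) stop("no CS- trials to normalize against in group ", k)
    m <- mean(est$amplitude[neg], na.rm = TRUE)
    if (!is.finite(m) || abs(m) <= eps * max(scale_all, .Machine$double.eps)) {
      est$amplitude[idx] <- NA_real_
      est$flagged[idx] <- TRUE
      excluded <- c(excluded, unique(est$subject[idx]))
    } else {
      est$amplitude[idx] <- est$amplitude[idx] / m
    }
  }
  est$normalized <- TRUE
  attr(est, "excluded_subjects") <- unique(excluded)
  est
}
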