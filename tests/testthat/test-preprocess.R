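test_that("every filter stage matches a direct-form reference on white noise", {
  set.seed(1)
  x <- rnorm(5000)
  fs <- 2000
  # each filter at the sampling rate it runs at in the pipeline
  specs <- list(
    list(fs = 2000, ord = 4, w = c(50, 470), type = "pass"),
    list(fs = 2000, ord = 4, w = 30, type = "high"),
    list(fs = 2000, ord = 4, w = 1 / (2 * pi * 0.003), type = "low"),
    list(fs = 100, ord = 1, w = c(0.0159, 5), type = "pass"),
    list(fs = 100, ord = 4, w = 4, type = "low"),
    list(fs = 250, ord = 3, w = c(5, 15), type = "pass"),
    list(fs = 10, ord = 2, w = 0.015, type = "high"),
    list(fs = 10, ord = 2, w = 0.5, type = "low"),
    list(fs = 50, ord = 2, w = c(0.04, 1), type = "pass")
  )
  for (sp in specs) {
    bt <- signal::butter(sp$ord, sp$w / (sp$fs / 2), type = sp$type)
    got <- tracefear:::butter_apply(x, sp$ord, sp$w, sp$type, sp$fs)
    expect_lt(max(abs(got - ref_iir(bt$b, bt$a, x))), 1e-9)
  }
  cf <- tracefear:::notch_coefficients(fs, 50, 35)
  got <- tracefear:::notch_apply(x, fs, 50, 35)
  expect_lt(max(abs(got - ref_iir(cf$b, cf$a, x))), 1e-9)
})

test_that("the notch removes a 50 Hz tone by at least 20 dB", {
  fs <- 2000
  t <- seq(0, 5, by = 1 / fs)
  tone50 <- continuous_signal(sin(2 * pi * 50 * t), fs, "emg")
  tone125 <- continuous_signal(sin(2 * pi * 125 * t), fs, "emg")
  env50 <- emg_preprocess_glm(tone50)
  env125 <- emg_preprocess_glm(tone125)
  # steady-state envelope after the filter transient
  s50 <- mean(env50$samples[(2 * fs):(4 * fs)])
  s125 <- mean(env125$samples[(2 * fs):(4 * fs)])
  expect_gt(20 * log10(s125 / s50), 20)
})

test_that("EMG preprocessing removes DC, preserves length, rejects low rates", {
  fs <- 1000
  const <- continuous_signal(rep(2, 3000), fs, "emg")
  env <- emg_preprocess_peak(const)
  expect_equal(length(env), 3000L)
  # after the notch ring-down the DC offset is fully rejected
  expect_lt(max(abs(env$samples[2000:3000])), 1e-4)
  expect_equal(sum(emg_preprocess_glm(
    continuous_signal(rep(0, 2000), fs, "emg"))$samples), 0)
  slow <- continuous_signal(rnorm(1000), 500, "emg")
  expect_error(emg_preprocess_glm(slow), "940")
})

test_that("the peak-scoring moving average has a 20-ms window", {
  fs <- 1000
  x <- c(rep(0, 100), 1, rep(0, 100))
  sm <- tracefear:::moving_average(x, round(0.020 * fs))
  expect_equal(sum(sm > 0), round(0.020 * fs))
  expect_equal(sum(sm), 1)
})

test_that("scaling raw EMG by k scales both envelopes by exactly k", {
  set.seed(2)
  fs <- 1000
  x <- rnorm(4000)
  a <- continuous_signal(x, fs, "emg")
  b <- continuous_signal(3.7 * x, fs, "emg")
  for (f in list(emg_preprocess_peak, emg_preprocess_glm)) {
    ya <- f(a)$samples
    yb <- f(b)$samples
    expect_lt(max(abs(yb - 3.7 * ya)) / max(abs(ya)), 1e-12)
  }
})

test_that("SCR preprocessing masks the US artifact window on the 10 Hz grid", {
  sched <- quick_schedule("acquisition", seed = 1, n = 2)
  fs <- 50
  n <- ceiling(tracefear:::session_duration(sched) * fs)
  scr <- continuous_signal(rnorm(n, 2, 0.01), fs, "scr")
  out <- scr_preprocess(scr, sched)
  expect_equal(out$sampling_rate, 10)
  us <- sched$trials$us_onset[!is.na(sched$trials$us_onset)]
  t10 <- signal_time(out)
  for (u in us) {
    in_window <- t10 >= u - 0.2 - 1e-9 & t10 < u + 1.6 - 1e-9
    expect_equal(sum(out$missing_mask & in_window), 18L)
  }
  expect_equal(sum(out$missing_mask), 18L * length(us))
  # a schedule without US leaves the mask empty
  rec <- quick_schedule("recall", seed = 2, n = 2)
  n2 <- ceiling(tracefear:::session_duration(rec) * fs)
  out2 <- scr_preprocess(continuous_signal(rnorm(n2, 2, 0.01), fs, "scr"), rec)
  expect_false(any(out2$missing_mask))
})

test_that("US mask arithmetic: one US at t = 100 s covers 18 decimated samples", {
  sched <- quick_schedule("acquisition", seed = 1, n = 1)
  sched$trials$us_onset[sched$trials$condition == "CS+"] <- 100
  fs <- 50
  scr <- continuous_signal(rnorm(120 * fs, 2, 0.01), fs, "scr")
  out <- scr_preprocess(scr, sched)
  t10 <- signal_time(out)
  expect_equal(sum(out$missing_mask), 18L)
  expect_true(all(t10[out$missing_mask] >= 99.8 - 1e-9))
  expect_true(all(t10[out$missing_mask] < 101.6))
})

test_that("the causal SCR band-pass rejects DC (step input decays back to 0)", {
  fs <- 50
  x <- c(rep(0, 10 * fs), rep(1, 600 * fs))
  sched <- quick_schedule("recall", seed = 3, n = 1)
  out <- scr_preprocess(continuous_signal(x, fs, "scr"), sched)
  expect_lt(abs(mean(tail(out$samples, 100))), 0.01)
})

test_that("clean equal eyes pass through pupil preprocessing unchanged", {
  fs <- 50
  t <- seq(0, 60, by = 1 / fs)
  x <- 4 + 0.3 * sin(2 * pi * t / 20)
  sched <- quick_schedule("acquisition", seed = 4, n = 1)
  mk <- function(ch) continuous_signal(x, fs, ch, units = "mm")
  gz <- continuous_signal(rep(0, length(t)), fs, "gaze_x", units = "deg")
  ps <- pupil_preprocess(mk("pupil_l"), mk("pupil_r"), gz,
                         continuous_signal(rep(0, length(t)), fs, "gaze_y",
                                           units = "deg"), sched)
  ok <- !ps$missing_mask
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(ps$diameter[ok] - x[ok])), 1e-12)
})

test_that("gaze outside the 5-degree window marks samples missing", {
  fs <- 50
  n <- 60 * fs
  sched <- quick_schedule("acquisition", seed = 4, n = 1)
  x <- rep(4, n)
  gx <- rep(0, n)
  gx[1000:1049] <- 6                      # 1 s excursion at 6 degrees
  ps <- pupil_preprocess(continuous_signal(x, fs, "pupil_l", units = "mm"),
                         continuous_signal(x, fs, "pupil_r", units = "mm"),
                         continuous_signal(gx, fs, "gaze_x", units = "deg"),
                         continuous_signal(rep(0, n), fs, "gaze_y",
                                           units = "deg"), sched)
  expect_true(all(ps$missing_mask[1000:1049]))
  expect_false(any(ps$missing_mask[1:900]))
})

test_that("the 50% missing-data exclusion boundary is strict", {
  sched <- quick_schedule("acquisition", seed = 5, n = 1)
  fs <- 50
  dur <- tracefear:::session_duration(sched)
  n <- ceiling(dur * fs)
  tg <- (seq_len(n) - 1) / fs
  base <- rep(4, n)
  win1 <- tg >= sched$trials$cs_onset[1] & tg <= sched$trials$cs_onset[1] + 17
  win2 <- tg >= sched$trials$cs_onset[2] & tg <= sched$trials$cs_onset[2] + 17
  x <- base
  x[which(win1)[seq_len(ceiling(0.51 * sum(win1)))]] <- NA   # 51% missing
  x[which(win2)[seq_len(floor(0.49 * sum(win2)))]] <- NA     # 49% missing
  ps <- pupil_preprocess(continuous_signal(x, fs, "pupil_l", units = "mm"),
                         continuous_signal(x, fs, "pupil_r", units = "mm"),
                         continuous_signal(rep(0, n), fs, "gaze_x",
                                           units = "deg"),
                         continuous_signal(rep(0, n), fs, "gaze_y",
                                           units = "deg"), sched)
  expect_true(ps$trials$excluded[1])
  expect_false(ps$trials$excluded[2])
})

test_that("pupil exclusion is monotone in injected artifact duration", {
  sched <- quick_schedule("acquisition", seed = 6, n = 1)
  fs <- 50
  n <- ceiling(tracefear:::session_duration(sched) * fs)
  tg <- (seq_len(n) - 1) / fs
  cs1 <- sched$trials$cs_onset[1]
  fracs <- vapply(c(2, 5, 9, 13), function(len) {
    gx <- rep(0, n)
    gx[tg >= cs1 & tg <= cs1 + len] <- 7
    ps <- pupil_preprocess(
      continuous_signal(rep(4, n), fs, "pupil_l", units = "mm"),
      continuous_signal(rep(4, n), fs, "pupil_r", units = "mm"),
      continuous_signal(gx, fs, "gaze_x", units = "deg"),
      continuous_signal(rep(0, n), fs, "gaze_y", units = "deg"), sched)
    ps$trials$missing_fraction[1]
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("QRS detection on a jittered synthetic ECG is accurate to 10 ms", {
  sched <- quick_schedule("acquisition", seed = 7, n = 3)
  truth <- ground_truth(sched, seed = 8)
  ecg <- synth_ecg(sched, truth, seed = 9, fs = 250)
  hp <- ecg_to_heart_period(ecg)
  bt <- attr(ecg, "beat_times")
  err <- vapply(hp$beats, function(b) min(abs(b - bt)), numeric(1))
  expect_gte(mean(err <= 0.010), 0.99)
  expect_lt(abs(length(hp$beats) - length(bt)), 0.01 * length(bt))
})

test_that("heart-period pipeline conserves time and errors on flat input", {
  sched <- quick_schedule("acquisition", seed = 7, n = 2)
  truth <- ground_truth(sched, seed = 8)
  ecg <- synth_ecg(sched, truth, seed = 9, fs = 250, hrv = FALSE)
  hp <- ecg_to_heart_period(ecg)
  span <- diff(range(hp$beats))
  expect_equal(sum(hp$ibi$ibi) / 1000, span, tolerance = 1 / 250)
  expect_error(ecg_to_heart_period(
    continuous_signal(rep(0, 5000), 250, "ecg")), "beats")
})

test_that("respiration cycle amplitude assignment lags one cycle", {
  fs <- 50
  per <- 4
  amps <- rep(c(1, 1, 0.5, 0.5), 10)       # paired big / small cycles
  x <- unlist(lapply(amps, function(a) {
    a * sin(2 * pi * seq_len(per * fs) / (per * fs))
  }))
  ra <- respiration_to_amplitude(continuous_signal(x, fs, "respiration"))
  cyc <- ra$cycles
  # the row at the start of cycle 11 (t = 40 s) carries cycle 10's
  # amplitude (big, peak-to-trough 2); the row at t = 44 s carries the
  # small cycle 11 (peak-to-trough 1)
  amp_at <- function(t0) cyc$amplitude[which.min(abs(cyc$onset - t0))]
  expect_equal(amp_at(40), 2, tolerance = 0.3)
  expect_equal(amp_at(44), 1, tolerance = 0.3)
  # sine of half-amplitude a has peak-to-trough 2a
  pure <- continuous_signal(0.7 * sin(2 * pi * seq_len(120 * fs) / (per * fs)),
                            fs, "respiration")
  rp <- respiration_to_amplitude(pure)
  expect_equal(median(rp$cycles$amplitude), 1.4, tolerance = 0.05)
})

test_that("noisy synthetic breathing amplitudes are recovered within 5%", {
  sched <- quick_schedule("acquisition", seed = 10, n = 2)
  truth <- ground_truth(sched, list(rar = list(amp = 0)), seed = 11)
  truth$trials$rar$amplitude[] <- 0
  rsp <- synth_respiration(sched, truth, seed = 12, fs = 50,
                           period_jitter = 0.1)
  ra <- respiration_to_amplitude(rsp)
  expect_lt(abs(median(ra$cycles$amplitude) - 1) , 0.05)
})
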