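test_that("peak scoring equals an exhaustive window scan", {
  set.seed(1)
  fs <- 1000
  env <- continuous_signal(abs(rnorm(60 * fs)), fs, "emg")
  probes <- c(5.3, 12.71, 20.004, 41.5)
  est <- sebr_peak_score(env, probes)
  tg <- signal_time(env)
  oracle <- vapply(probes, function(p0) {
    max(env$samples[tg >= p0 + 0.020 - 1e-9 & tg <= p0 + 0.100 + 1e-9])
  }, numeric(1))
  expect_identical(est$amplitude, oracle)
})

test_that("peak scoring obeys its window: constant level and late bursts", {
  fs <- 1000
  env <- continuous_signal(rep(0.5, 10 * fs), fs, "emg")
  expect_equal(sebr_peak_score(env, 2)$amplitude, 0.5)
  # a burst peaking 150 ms post-probe lies outside the 20-100 ms window
  x <- rep(0.1, 10 * fs)
  x[round(2.150 * fs) + (-5:5)] <- 5
  env2 <- continuous_signal(x, fs, "emg")
  expect_equal(sebr_peak_score(env2, 2)$amplitude, 0.1)
  expect_error(sebr_peak_score(env, 9.95), "window")
})

test_that("GLM scoring recovers amplitude and onset from a noiseless envelope", {
  fs <- 1000
  rf <- sebr_canonical_rf(fs = fs)
  rfv <- tracefear:::rf_resample(rf, fs)$values
  x <- numeric(5 * fs)
  onset <- 0.030
  i0 <- round((2 + onset) * fs) + 1L
  x[i0:(i0 + length(rfv) - 1L)] <- 2 * rfv
  env <- continuous_signal(x, fs, "emg")
  est <- sebr_glm(env, 2, rf = rf)
  expect_equal(est$amplitude, 2, tolerance = 1e-6)
  expect_equal(est$latency, onset, tolerance = 1e-9)
})

test_that("GLM scoring on pure noise is centered near zero", {
  set.seed(7)
  fs <- 1000
  env <- continuous_signal(abs(rnorm(200 * fs, 0, 0.1)), fs, "emg")
  probes <- seq(5, 195, by = 10)
  est <- sebr_glm(env, probes)
  expect_lt(abs(mean(est$amplitude)), 0.05)
})

test_that("three-burst inversion returns zeros for a zero segment", {
  sched <- quick_schedule("acquisition", seed = 1, n = 1)
  n10 <- ceiling(tracefear:::session_duration(sched) * 10)
  scr10 <- continuous_signal(rep(0, n10), 10, "scr")
  est <- fit_scr_trial_model(scr10, sched)
  expect_true(all(est$amplitude == 0))
})

test_that("three-burst inversion recovers noiseless parameters to 1% / 0.1 s", {
  sched <- quick_schedule("acquisition", seed = 3, n = 3)
  truth <- ground_truth(sched, seed = 4)
  scr <- synth_scr(sched, truth, seed = 5, fs = 10, noise = FALSE)
  est <- fit_scr_trial_model(scr, sched)
  g <- truth$trials$scr
  for (comp in c("cs", "trace", "us")) {
    e <- est[est$component == comp, ]
    tru <- switch(comp, cs = g$amp_cs, trace = g$amp_trace, us = g$amp_us)
    keep <- tru > 0
    expect_equal(e$amplitude[keep], tru[keep], tolerance = 0.01)
  }
  tr <- est[est$component == "trace", ]
  expect_lt(max(abs(tr$latency - g$latency)), 0.1)
})

test_that("a trace burst at the window edge clamps to the bound and is flagged", {
  sched <- quick_schedule("acquisition", seed = 6, n = 1)
  truth <- ground_truth(sched, seed = 7)
  truth$trials$scr$amp_cs[] <- 0
  truth$trials$scr$amp_us[] <- 0
  truth$trials$scr$amp_trace[] <- 0
  truth$trials$scr$amp_trace[1] <- 1
  truth$trials$scr$latency[1] <- 2 + 8          # exactly at the lower bound
  scr <- synth_scr(sched, truth, seed = 8, fs = 10, noise = FALSE)
  est <- fit_scr_trial_model(scr, sched)
  tr <- est[est$component == "trace" & est$trial_index == 1, ]
  expect_equal(tr$latency, 10, tolerance = 0.05)
  expect_true(tr$flagged)
})

test_that("masked samples are excluded from the inversion objective", {
  sched <- quick_schedule("acquisition", seed = 3, n = 2)
  truth <- ground_truth(sched, seed = 4)
  scr <- synth_scr(sched, truth, seed = 5, fs = 10, noise = FALSE)
  # corrupt the US artifact window, then mask it
  mask <- rep(FALSE, length(scr$samples))
  tg <- signal_time(scr)
  for (u in sched$trials$us_onset[!is.na(sched$trials$us_onset)]) {
    bad <- tg >= u - 0.2 & tg < u + 1.6
    scr$samples[bad] <- scr$samples[bad] + 50
    mask[bad] <- TRUE
  }
  masked <- continuous_signal(scr$samples, 10, "scr", missing_mask = mask)
  est <- fit_scr_trial_model(masked, sched)
  g <- truth$trials$scr
  tr <- est[est$component == "trace", ]
  expect_equal(tr$amplitude, g$amp_trace, tolerance = 0.02)
})

test_that("SCR area under the curve matches closed forms", {
  fs <- 10
  zero <- continuous_signal(rep(0, 300), fs, "scr")
  expect_equal(scr_auc(zero, 5, 22)$amplitude, 0)
  const <- continuous_signal(rep(3, 300), fs, "scr")
  expect_equal(scr_auc(const, 5, 22)$amplitude, 0)
  # ramp rising at rate r from CS onset: integral = r (b-a)^2 / 2
  tg <- (seq_len(300) - 1) / fs
  ramp <- continuous_signal(pmax(0, 0.2 * (tg - 5)), fs, "scr")
  expect_equal(scr_auc(ramp, 5, 22)$amplitude, 0.2 * 17^2 / 2,
               tolerance = 1e-6)
})

test_that("fitted response functions recover a shifted unit kernel", {
  time <- seq(-1, 20, by = 0.1)
  kern <- tracefear:::gamma_kernel(pmax(time - 0, 0), 2.5, 1.8)
  kern <- kern / max(kern)
  curves <- rbind(kern, kern, kern)
  rf <- suppressWarnings(
    estimate_rf_from_timecourse(curves, time, dataset_id = "train"))
  expect_equal(max(abs(rf$values)), 1)
  expect_equal(rf$grid[which.max(rf$values)], time[which.max(kern)],
               tolerance = 0.6)   # 1-s smoothing can shift the peak slightly
  expect_identical(rf$source_dataset, "train")
})

test_that("a pure-noise time course triggers the low-SNR warning", {
  set.seed(9)
  time <- seq(0, 17, by = 0.1)
  curves <- matrix(rnorm(5 * length(time), 0, 1), nrow = 5)
  expect_warning(estimate_rf_from_timecourse(curves, time, "train"),
                 "noise")
})

test_that("train/evaluate dataset separation is enforced for fitted RFs", {
  time <- seq(0, 17, by = 0.1)
  kern <- tracefear:::gamma_kernel(time, 2.5, 1.8)
  rf <- suppressWarnings(
    estimate_rf_from_timecourse(rbind(kern, kern), time, dataset_id = "A"))
  sched <- quick_schedule("acquisition", seed = 2, n = 1)
  n10 <- ceiling(tracefear:::session_duration(sched) * 10)
  series <- continuous_signal(rnorm(n10), 10, "scr")
  expect_error(glm_quantify(series, sched, rf, dataset_id = "A"),
               "refused")
  expect_silent(glm_quantify(series, sched, rf, dataset_id = "A",
                             allow_same_dataset = TRUE))
  expect_silent(glm_quantify(series, sched, rf, dataset_id = "B"))
})

test_that("GLM quantification is an OLS identity on noiseless designs", {
  sched <- quick_schedule("acquisition", seed = 5, n = 2)
  rf <- pupil_canonical_rf()
  fs <- 10
  n <- ceiling(tracefear:::session_duration(sched) * fs)
  rfv <- tracefear:::rf_resample(rf, fs)$values
  x <- numeric(n)
  for (cs in sched$trials$cs_onset) {
    i0 <- round(cs * fs)
    x[i0 + seq_along(rfv)] <- x[i0 + seq_along(rfv)] + 3 * rfv
  }
  est <- glm_quantify(continuous_signal(x, fs, "scr"), sched, rf,
                      anchor = "cs")
  expect_equal(est$amplitude, rep(3, 4), tolerance = 1e-8)
  # two response functions, amplitudes (1, 2)
  e1 <- tracefear:::rf_resample(rar_early_rf(), fs)$values
  e2 <- tracefear:::rf_resample(rar_late_rf(), fs)$values
  y <- numeric(n)
  anchors <- tracefear:::anchor_times(sched, "us")
  for (a0 in anchors) {
    i0 <- round(a0 * fs)
    y[i0 + seq_along(e1)] <- y[i0 + seq_along(e1)] + 1 * e1
    y[i0 + seq_along(e2)] <- y[i0 + seq_along(e2)] + 2 * e2
  }
  est2 <- glm_quantify(continuous_signal(y, fs, "respiration"), sched,
                       list(early = rar_early_rf(), late = rar_late_rf()),
                       anchor = "us", granularity = "condition")
  expect_equal(est2$amplitude[est2$component == "early"], c(1, 1),
               tolerance = 1e-6)
  expect_equal(est2$amplitude[est2$component == "late"], c(2, 2),
               tolerance = 1e-6)
})

test_that("GLM estimates match an independent normal-equations oracle", {
  set.seed(11)
  sched <- quick_schedule("acquisition", seed = 6, n = 2)
  rf <- pupil_canonical_rf()
  fs <- 10
  n <- ceiling(tracefear:::session_duration(sched) * fs)
  y <- rnorm(n)
  est <- glm_quantify(continuous_signal(y, fs, "scr"), sched, rf,
                      anchor = "cs")
  # oracle: build the same design and solve the normal equations directly
  rfv <- tracefear:::rf_resample(rf, fs)$values
  X <- matrix(0, n, 4)
  for (i in 1:4) {
    i0 <- round(sched$trials$cs_onset[i] * fs)
    X[i0 + seq_along(rfv), i] <- rfv
  }
  X <- cbind(X, 1, seq_len(n) / n)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(est$amplitude[order(est$trial_index)], as.numeric(beta[1:4]),
               tolerance = 1e-8)
})

test_that("CS- normalization has the stated exact identities", {
  est <- rbind(
    data.frame(subject = "S1", session = "recall", trial_index = 1:4,
               condition = c("CS-", "CS-", "CS-", "CS+"), modality = "emg",
               method = "peak", component = "cs",
               amplitude = c(2, 2, 2, 3), latency = NA_real_,
               normalized = FALSE, flagged = FALSE))
  out <- normalize_by_cs_minus(est)
  expect_equal(out$amplitude[out$condition == "CS+"], 1.5)
  expect_equal(mean(out$amplitude[out$condition == "CS-"]), 1)
  # gain invariance: scaling all raw amplitudes leaves normalized values
  est2 <- est
  est2$amplitude <- est2$amplitude * 17.3
  expect_equal(normalize_by_cs_minus(est2)$amplitude, out$amplitude)
})

test_that("a vanishing CS- mean flags the subject instead of dividing", {
  est <- data.frame(subject = rep(c("S1", "S2"), each = 4),
                    session = "recall", trial_index = rep(1:4, 2),
                    condition = rep(c("CS-", "CS-", "CS+", "CS+"), 2),
                    modality = "emg", method = "peak", component = "cs",
                    amplitude = c(0, 0, 5, 6, 2, 2, 3, 4),
                    latency = NA_real_, normalized = FALSE, flagged = FALSE)
  out <- normalize_by_cs_minus(est)
  expect_identical(attr(out, "excluded_subjects"), "S1")
  expect_true(all(is.na(out$amplitude[out$subject == "S1"])))
  expect_true(all(is.finite(out$amplitude[out$subject == "S2"])))
})
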