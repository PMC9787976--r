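# shared numerical helpers

# centered moving average with partial windows at the edges (length preserved)
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  half_l <- (n - 1L) %/% 2L
  half_r <- n - 1L - half_l
  cs <- cumsum(c(0, x))
  N <- length(x)
  lo <- pmax(seq_len(N) - half_l, 1L)
  hi <- pmin(seq_len(N) + half_r, N)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# causal Butterworth filtering via the signal package; zero_phase uses
# forward-backward filtering (filtfilt)
butter_apply <- function(x, order, cutoff_hz, type, fs, zero_phase = FALSE) {
  W <- cutoff_hz / (fs / 2)
  if (any(W <= 0) || any(W >= 1)) {
    stop(sprintf("cutoff %s Hz invalid at sampling rate %g Hz",
                 paste(cutoff_hz, collapse = "-"), fs))
  }
  bt <- signal::butter(order, W, type = type)
  if (zero_phase) as.numeric(signal::filtfilt(bt, x))
  else as.numeric(signal::filter(bt, x))
}

# second-order IIR notch (constrained biquad, quality factor Q)
notch_coefficients <- function(fs, f0 = 50, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

notch_apply <- function(x, fs, f0 = 50, Q = 35) {
  cf <- notch_coefficients(fs, f0, Q)
  as.numeric(signal::filter(cf$b, cf$a, x))
}

# stationary AR(1) noise with unit marginal variance
ar1_noise <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  e <- stats::rnorm(n) * sqrt(1 - phi^2)
  e[1] <- stats::rnorm(1)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# trapezoidal integral on a uniform or arbitrary grid
trapz_int <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# derive a bounded child seed from a base seed and a stream label
# (double arithmetic: products stay below 2^53, results below 2^31)
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483629)
}
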