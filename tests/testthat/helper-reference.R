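# independent oracles shared across test files

# textbook direct-form II transposed IIR filter, plain R loop
ref_iir <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  nord <- max(nb, na) - 1L
  b <- c(b, rep(0, nord + 1L - nb))
  a <- c(a, rep(0, nord + 1L - na))
  z <- rep(0, nord)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (k in seq_len(nord)) {
      znext <- if (k < nord) z[k + 1L] else 0
      z[k] <- b[k + 1L] * x[i] + znext - a[k + 1L] * y[i]
    }
  }
  y
}

# short schedules keep signal synthesis fast in unit tests
mini_params <- function(n = 3L) list(n_plus = n, n_minus = n)

# a session dataset with only the channels a test needs
quick_schedule <- function(session = "acquisition", seed = 1, n = 3L) {
  generate_schedule(session, seed = seed, params = mini_params(n))
}
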