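#' Response function objects
#'
#' A response function (RF) is a fixed-shape kernel describing the
#' stereotyped physiological response to a unit neural input; it serves as
#' the regression basis of the GLM quantifiers and as the conductance
#' kernel of the sudomotor burst model. Values are peak-normalized to unit
#' maximum absolute value and causal (zero before lag 0) unless a fitted RF
#' dictates otherwise.
#'
#' @param kind One of `"sebr_canonical"`, `"scr_kernel"`,
#'   `"pupil_canonical"`, `"pupil_fitted"`, `"hpr_us_locked"`,
#'   `"hpr_fitted"`, `"rar_early"`, `"rar_late"`.
#' @param grid Time grid in seconds (uniform, starting at 0 for causal RFs).
#' @param values Kernel values on `grid`; rescaled internally to unit peak.
#' @param params Optional parametric description.
#' @param source_dataset Optional dataset identifier for fitted RFs, used to
#'   enforce train/evaluate separation.
#' @return A `response_function`.
#' @export
response_function <- function(kind, grid, values, params = list(),
                              source_dataset = NULL) {
  kinds <- c("sebr_canonical", "scr_kernel", "pupil_canonical",
             "pupil_fitted", "hpr_us_locked", "hpr_fitted",
             "rar_early", "rar_late")
  kind <- match.arg(kind, kinds)
  stopifnot(length(grid) == length(values), all(is.finite(values)),
            all(diff(grid) > 0))
  m <- max(abs(values))
  if (m == 0) stop("response function must be non-zero")
  structure(
    list(kind = kind, grid = as.numeric(grid), values = values / m,
         params = params, source_dataset = source_dataset),
    class = "response_function"
  )
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function> %s on [%.3g, %.3g] s (%d points)%s\n",
              x$kind, min(x$grid), max(x$grid), length(x$grid),
              if (is.null(x$source_dataset)) "" else
                paste0(", fitted on '", x$source_dataset, "'")))
  invisible(x)
}

# gamma-density kernel parameterized by its mode and standard deviation
gamma_kernel <- function(t, mode, sd) {
  theta <- (-mode + sqrt(mode^2 + 4 * sd^2)) / 2
  shape <- mode / theta + 1
  stats::dgamma(t, shape = shape, scale = theta)
}

#' Canonical startle eyeblink response function
#'
#' Gamma-density kernel peaking ~45 ms after blink onset with ~25 ms width,
#' used as the regression basis for GLM scoring of the orbicularis oculi
#' EMG envelope.
#'
#' @param fs Sampling rate of the grid in Hz.
#' @param duration Kernel support in seconds.
#' @export
sebr_canonical_rf <- function(fs = 1000, duration = 0.35) {
  grid <- seq(0, duration, by = 1 / fs)
  response_function("sebr_canonical", grid, gamma_kernel(grid, 0.045, 0.025),
                    params = list(mode = 0.045, sd = 0.025))
}

#' Canonical skin conductance response kernel
#'
#' Bateman-type difference of exponentials (rise 0.75 s, decay 2.5 s,
#' 1 s onset delay) mapping sudomotor input to skin conductance.
#'
#' @param fs Grid sampling rate in Hz.
#' @param duration Kernel support in seconds.
#' @param rise,decay,delay Time constants and onset delay in seconds.
#' @export
scr_kernel_rf <- function(fs = 10, duration = 30, rise = 0.75, decay = 2.5,
                          delay = 1.0) {
  grid <- seq(0, duration, by = 1 / fs)
  tt <- pmax(grid - delay, 0)
  v <- exp(-tt / decay) - exp(-tt / rise)
  v[grid < delay] <- 0
  response_function("scr_kernel", grid, v,
                    params = list(rise = rise, decay = decay, delay = delay))
}

#' Canonical pupil size response function
#'
#' Gamma-family kernel peaking ~2.5 s after event onset, the standard basis
#' for anticipatory pupil dilation responses.
#'
#' @inheritParams sebr_canonical_rf
#' @export
pupil_canonical_rf <- function(fs = 10, duration = 17) {
  grid <- seq(0, duration, by = 1 / fs)
  response_function("pupil_canonical", grid, gamma_kernel(grid, 2.5, 1.8),
                    params = list(mode = 2.5, sd = 1.8))
}

#' Canonical US-locked heart period response function
#'
#' Biphasic kernel (bradycardic peak ~4 s followed by a shallow rebound)
#' for US-anchored heart-period responses.
#'
#' @inheritParams sebr_canonical_rf
#' @export
hpr_canonical_rf <- function(fs = 10, duration = 25) {
  grid <- seq(0, duration, by = 1 / fs)
  v <- gamma_kernel(grid, 4, 2) / max(gamma_kernel(grid, 4, 2)) -
    0.45 * gamma_kernel(grid, 9, 3.5) / max(gamma_kernel(grid, 9, 3.5))
  response_function("hpr_us_locked", grid, v,
                    params = list(peak = 4, rebound = 9))
}

#' Early and late respiration amplitude response functions
#'
#' Two-basis set for condition-wise respiration amplitude GLMs.
#'
#' @inheritParams sebr_canonical_rf
#' @export
rar_early_rf <- function(fs = 10, duration = 20) {
  grid <- seq(0, duration, by = 1 / fs)
  response_function("rar_early", grid, gamma_kernel(grid, 2, 1.2),
                    params = list(mode = 2, sd = 1.2))
}

#' @rdname rar_early_rf
#' @export
rar_late_rf <- function(fs = 10, duration = 20) {
  grid <- seq(0, duration, by = 1 / fs)
  response_function("rar_late", grid, gamma_kernel(grid, 7, 3),
                    params = list(mode = 7, sd = 3))
}

# resample an RF onto a target rate; zero outside its support
rf_resample <- function(rf, fs) {
  grid <- seq(min(rf$grid), max(rf$grid), by = 1 / fs)
  vals <- stats::approx(rf$grid, rf$values, xout = grid, rule = 2)$y
  list(grid = grid, values = vals)
}

#' Serialize / read a response function as two-column text
#'
#' Writes `(time, value)` as tab-separated text with a JSON sidecar holding
#' the kind and parameters.
#'
#' @param rf A `response_function`.
#' @param path Output path (`.tsv`); the sidecar is `paste0(path, ".json")`.
#' @export
write_rf <- function(rf, path) {
  utils::write.table(
    data.frame(time = rf$grid, value = rf$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(kind = rf$kind, params = rf$params,
               source_dataset = rf$source_dataset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  response_function(meta$kind, tab$time, tab$value,
                    params = as.list(meta$params),
                    source_dataset = meta$source_dataset)
}
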