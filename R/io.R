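write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Write / read a session schedule as an events table
#'
#' Events are serialized as a tab-delimited table (UTF-8, "." decimals)
#' with columns `onset`, `duration`, `trial_type`, `condition`,
#' `trial_index` -- one row per CS, US, probe, and incidental-task event --
#' plus a JSON sidecar (`<path>.json`) holding the session label, timing
#' parameters, and seed. `read_events()` reconstructs the schedule; the
#' round trip is the identity at full float precision.
#'
#' @param schedule A `trial_schedule`.
#' @param path Output path for the `.tsv` table.
#' @return Invisibly, the path.
#' @export
write_events <- function(schedule, path) {
  tr <- schedule$trials
  p <- schedule$params
  rows <- list(
    data.frame(onset = tr$cs_onset, duration = p$cs_duration,
               trial_type = "cs", condition = tr$condition,
               trial_index = tr$trial_index),
    data.frame(onset = tr$iti_task_onset, duration = 13,
               trial_type = "iti_task", condition = tr$condition,
               trial_index = tr$trial_index)
  )
  if (any(!is.na(tr$us_onset))) {
    keep <- !is.na(tr$us_onset)
    rows <- c(rows, list(
      data.frame(onset = tr$us_onset[keep], duration = p$us_duration,
                 trial_type = "us", condition = tr$condition[keep],
                 trial_index = tr$trial_index[keep])))
  }
  if (any(!is.na(tr$probe_onset))) {
    keep <- !is.na(tr$probe_onset)
    rows <- c(rows, list(
      data.frame(onset = tr$probe_onset[keep], duration = 0.02,
                 trial_type = "probe", condition = tr$condition[keep],
                 trial_index = tr$trial_index[keep])))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset), ]
  ev$onset <- sprintf("%.17g", ev$onset)
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  write_json_sidecar(
    list(session = schedule$session, rng_seed = schedule$rng_seed,
         params = schedule$params,
         iti_duration = schedule$trials$iti_duration),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = c(
                            onset = "character"))
  ev$onset <- as.numeric(ev$onset)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cs <- ev[ev$trial_type == "cs", ]
  cs <- cs[order(cs$trial_index), ]
  pick <- function(type) {
    sub <- ev[ev$trial_type == type, ]
    out <- rep(NA_real_, nrow(cs))
    out[match(sub$trial_index, cs$trial_index)] <- sub$onset
    out
  }
  trials <- data.frame(
    trial_index = cs$trial_index, condition = cs$condition,
    cs_onset = cs$onset, us_onset = pick("us"), probe_onset = pick("probe"),
    iti_task_onset = pick("iti_task"),
    iti_duration = as.numeric(meta$iti_duration),
    stringsAsFactors = FALSE)
  params <- meta$params
  params$n_plus <- as.integer(params$n_plus)
  params$n_minus <- as.integer(params$n_minus)
  params$max_run <- as.integer(params$max_run)
  sched <- structure(
    list(session = meta$session, trials = trials, params = params,
         rng_seed = as.integer(meta$rng_seed)),
    class = "trial_schedule")
  validate_schedule(sched)
  sched
}

#' Write / read a continuous signal as delimited text
#'
#' One file per channel: a tab-separated table with columns `sample` and
#' `missing` (0/1) and a JSON sidecar (`<path>.json`) with the channel
#' name, sampling rate, and units.
#'
#' @param sig A `continuous_signal`.
#' @param path Output path for the `.tsv` table.
#' @param digits Significant digits written (default 17: lossless round
#'   trip for doubles).
#' @return Invisibly, the path.
#' @export
write_signal <- function(sig, path, digits = 17) {
  stopifnot(inherits(sig, "continuous_signal"))
  tab <- data.frame(
    sample = ifelse(is.na(sig$samples), "NA",
                    sprintf(paste0("%.", digits, "g"), sig$samples)),
    missing = as.integer(sig$missing_mask))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  write_json_sidecar(list(channel = sig$channel,
                          sampling_rate = sig$sampling_rate,
                          units = sig$units),
                     paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(sample = "character"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  continuous_signal(as.numeric(tab$sample), meta$sampling_rate, meta$channel,
                    units = meta$units,
                    missing_mask = as.logical(tab$missing))
}

#' Default pipeline configuration
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; every stochastic step derives its own stream
#'   from it.
#' @param modalities Subset of `c("emg", "scr")`: the recall startle
#'   (peak-scored) and acquisition skin-conductance (three-burst model)
#'   paths.
#' @param dataset_id Dataset identifier (train/evaluate bookkeeping).
#' @param out_dir Output directory; `NULL` disables file output.
#' @param n_calibration_max Largest trial average in the calibration.
#' @param fs Per-channel sampling-rate overrides for synthesis.
#' @param truth Truth-parameter overrides for synthesis.
#' @export
pipeline_config <- function(n_subjects = 8, seed = 1,
                            modalities = c("emg", "scr"),
                            dataset_id = "synthetic-1", out_dir = NULL,
                            n_calibration_max = 15, fs = list(),
                            truth = list()) {
  list(n_subjects = n_subjects, seed = seed, modalities = modalities,
       dataset_id = dataset_id, out_dir = out_dir,
       n_calibration_max = n_calibration_max, fs = fs, truth = truth)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; unknown keys are rejected.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(pipeline_config())
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(pipeline_config(), raw)
}

#' Run the synthetic end-to-end pipeline
#'
#' For each subject, generates schedules and signals, runs the per-modality
#' preprocessing and quantification (recall EMG: peak scoring of the
#' rectified envelope; acquisition SCR: band-pass, decimation, and
#' three-burst model inversion), normalizes by the CS- mean, and runs the
#' trial-averaging calibration on the recall startle estimates. Fully
#' deterministic given the config. With `out_dir` set, writes tidy
#' estimate tables, the calibration table, and a provenance JSON (config,
#' seed, config hash, package version). A modality whose synthesis or
#' quantification fails is skipped with a warning, not a global failure.
#'
#' @param config See [pipeline_config()] / [read_config()].
#' @return A list: `estimates` (normalized trial estimates),
#'   `calibration` (or `NULL` without EMG), `config`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  est_all <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    sseed <- child_seed(config$seed, s)
    subj_scale <- withr_seed(child_seed(sseed, 999L),
                             stats::rlnorm(1, 0, 0.4))
    truth_ovr <- utils::modifyList(
      list(sebr = list(amp = subj_scale),
           scr = list(amp_cs = 0.3 * subj_scale,
                      amp_trace = 0.4 * subj_scale,
                      amp_us = 0.8 * subj_scale)),
      config$truth)
    for (mod in config$modalities) {
      res <- tryCatch({
        if (mod == "emg") {
          sched <- generate_schedule("recall", seed = child_seed(sseed, 11L))
          truth <- ground_truth(sched, truth_ovr, seed = child_seed(sseed, 12L))
          fs <- if (!is.null(config$fs$emg)) config$fs$emg else 2000
          raw <- synth_emg(sched, truth, seed = child_seed(sseed, 13L), fs = fs)
          env <- emg_preprocess_peak(raw)
          sebr_peak_score(env, sched, subject = sid)
        } else if (mod == "scr") {
          sched <- generate_schedule("acquisition", seed = child_seed(sseed, 21L))
          truth <- ground_truth(sched, truth_ovr, seed = child_seed(sseed, 22L))
          fs <- if (!is.null(config$fs$scr)) config$fs$scr else 100
          raw <- synth_scr(sched, truth, seed = child_seed(sseed, 23L), fs = fs)
          scr10 <- scr_preprocess(raw, sched)
          fit_scr_trial_model(scr10, sched, subject = sid)
        } else {
          warning("modality not handled by run_pipeline: ", mod)
          NULL
        }
      }, error = function(e) {
        warning(sprintf("modality %s skipped for %s: %s", mod, sid,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) est_all <- c(est_all, list(res))
    }
  }
  if (!length(est_all)) stop("no modality produced estimates")
  estimates <- normalize_by_cs_minus(do.call(rbind, est_all))
  calibration <- NULL
  emg_est <- estimates[estimates$modality == "emg" &
                         is.finite(estimates$amplitude), ]
  if (nrow(emg_est) && length(unique(emg_est$subject)) >= 2) {
    calibration <- calibrate_trial_average(emg_est,
                                           n_max = config$n_calibration_max)
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("tracefear")),
    seed = config$seed, config = config[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(estimates, file.path(config$out_dir, "estimates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(calibration)) {
      utils::write.table(calibration$table,
                         file.path(config$out_dir, "calibration.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_json_sidecar(provenance,
                       file.path(config$out_dir, "provenance.json"))
  }
  list(estimates = estimates, calibration = calibration, config = config,
       provenance = provenance)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
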