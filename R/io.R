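# Plain-text serialization: CSV for data/event/rating tables, JSON for
# configs and fits.

#' Write an epoched trial set to a directory of plain-text files
#'
#' Layout: `data.csv` (long format: trial, channel, sample, value),
#' `trials.csv`, `channels.csv`, and `meta.json` (time axis, fs, subject,
#' kept mask).
#'
#' @param tset an `hp_trialset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trialset <- function(tset, dir) {
  stopifnot(inherits(tset, "hp_trialset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(tset$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(tset$channels$name, each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(tset$data))
  utils::write.csv(long, file.path(dir, "data.csv"), row.names = FALSE)
  utils::write.csv(tset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(tset$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(time = tset$time, fs = tset$fs,
                            subject_id = tset$subject_id, kept = tset$kept),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' Read a trial set written by [write_trialset()]
#' @param dir directory path.
#' @return an `hp_trialset`.
#' @export
read_trialset <- function(dir) {
  long <- utils::read.csv(file.path(dir, "data.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  channels <- utils::read.csv(file.path(dir, "channels.csv"),
                              stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- c(max(long$trial), nrow(channels), max(long$sample))
  data <- array(long$value, dim = d,
                dimnames = list(NULL, channels$name, NULL))
  structure(list(data = data, time = meta$time, fs = meta$fs,
                 channels = channels, trials = trials,
                 kept = as.logical(meta$kept), subject_id = meta$subject_id),
            class = "hp_trialset")
}

#' Serialize a simulation config to JSON
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read a simulation config from JSON
#' @param path JSON file written by [write_sim_config()].
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  relist_spec <- function(x, ctor) do.call(ctor, lapply(x, function(v)
    if (is.list(v)) unlist(v) else v))
  sim_config(
    seed = cfg$seed, fs_raw = cfg$fs_raw, fs_out = cfg$fs_out,
    n_subjects = cfg$n_subjects,
    n_trials_per_condition = cfg$n_trials_per_condition,
    trial_window = unlist(cfg$trial_window),
    aperiodic_offset = cfg$aperiodic_offset,
    aperiodic_exponent = cfg$aperiodic_exponent,
    peak_specs = lapply(cfg$peak_specs, function(p)
      list(cf = p$cf, amp = p$amp, bw = p$bw)),
    sensor_peak_specs = lapply(cfg$sensor_peak_specs, function(p)
      list(cf = p$cf, amp = p$amp, bw = p$bw)),
    effect_specs = lapply(cfg$effect_specs, relist_spec,
                          ctor = condition_effect),
    coupling_specs = lapply(cfg$coupling_specs, function(x) {
      x$condition <- x$condition %||% NULL
      relist_spec(x, coupling_spec)
    }),
    n_meg_sensors = cfg$n_meg_sensors, n_lfp_contacts = cfg$n_lfp_contacts,
    erp_amplitude = cfg$erp_amplitude, erp_latency = cfg$erp_latency,
    subject_sd = cfg$subject_sd,
    coupling_theta_link = cfg$coupling_theta_link,
    rating_means = lapply(cfg$rating_means, function(m) {
      v <- unlist(m)
      if (is.null(names(v)) || !all(c("valence", "arousal") %in% names(v)))
        names(v) <- c("valence", "arousal")
      v
    }),
    rating_sd = cfg$rating_sd)
}
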