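# Synthetic study generator: resting and task recordings, ratings, lead fields.

#' Condition-gated oscillatory effect specification
#'
#' Describes a band-limited, non-phase-locked power modulation tied to one
#' stimulus condition: within `window`, the in-band signal amplitude on the
#' target channels is multiplied by `amplitude_gain` relative to baseline.
#'
#' @param condition one of `"neutral"`, `"positive"`, `"negative"`.
#' @param band numeric length-2, frequency interval in Hz.
#' @param window numeric length-2, time interval in seconds after onset.
#' @param amplitude_gain multiplicative amplitude factor (>= 0); 1 = no effect.
#' @param target_channels character vector of channel names, or one of the
#'   selectors `"lfp"`, `"frontal"`, `"occipital"`, `"all"`.
#' @return a `condition_effect` list.
#' @export
condition_effect <- function(condition, band, window, amplitude_gain,
                             target_channels = "lfp") {
  condition <- match.arg(condition, c("neutral", "positive", "negative"))
  stopifnot(length(band) == 2, band[1] < band[2],
            length(window) == 2, window[1] < window[2])
  if (amplitude_gain < 0) stop("amplitude_gain must be >= 0")
  structure(list(condition = condition, band = as.numeric(band),
                 window = as.numeric(window),
                 amplitude_gain = amplitude_gain,
                 target_channels = target_channels),
            class = "condition_effect")
}

#' Cross-region coupling specification
#'
#' Within `window`, the in-band activity of the target channels shares a
#' common narrowband component with the source channel (optionally lagged)
#' such that the cross-trial coherence approaches `coupling_strength`.
#'
#' @param source_channel channel name providing the shared component.
#' @param target_channels channel names or a selector (see
#'   [condition_effect()]).
#' @param band,window frequency (Hz) and time (s) intervals.
#' @param coupling_strength target coherence in `[0, 1]`.
#' @param lag seconds by which the target lags the source.
#' @param condition optional condition restriction (`NULL` = all conditions).
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(source_channel, target_channels, band, window,
                          coupling_strength, lag = 0, condition = NULL) {
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must be in [0, 1]")
  if (abs(lag) > diff(window))
    stop("lag larger than the coupling window length")
  structure(list(source_channel = source_channel,
                 target_channels = target_channels,
                 band = as.numeric(band), window = as.numeric(window),
                 coupling_strength = coupling_strength, lag = lag,
                 condition = condition),
            class = "coupling_spec")
}

#' Quasi-uniform 2-D sensor layout on the unit disk
#'
#' Sensors are placed by the golden-angle (sunflower) rule, which gives a
#' deterministic, roughly uniform planar layout. Sensors with y above 0.25
#' are labelled `"frontal"`, below -0.25 `"occipital"`, otherwise
#' `"central"`; x > 0 is the right hemisphere in layout coordinates.
#'
#' @param n_sensors number of sensors (>= 8).
#' @return data.frame with columns `name, x, y, group`.
#' @export
sensor_layout <- function(n_sensors) {
  stopifnot(n_sensors >= 8)
  i <- seq_len(n_sensors)
  r <- sqrt((i - 0.5) / n_sensors)
  th <- i * pi * (3 - sqrt(5))
  x <- r * cos(th); y <- r * sin(th)
  grp <- ifelse(y > 0.25, "frontal", ifelse(y < -0.25, "occipital", "central"))
  data.frame(name = sprintf("S%02d", i), x = x, y = y, group = grp,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the paradigm constants (trial timing, trial counts, sampling
#' rates), the spectral model of the background activity (aperiodic offset
#' and exponent plus Gaussian oscillatory peaks), the condition-dependent
#' effects and cross-region couplings to inject, and the rating-distribution
#' parameters for the three stimulus valence categories.
#'
#' Defaults emulate an emotional picture-viewing paradigm: 1 s fixation,
#' 2 s picture, 3-4 s blank; epochs of -2.5 to 4.5 s around picture onset;
#' 27 trials per valence condition and 9 subjects; raw sampling at 1000 Hz
#' down-sampled to 250 Hz. The default injected effects are an early
#' 5-10 Hz amplitude increase (100-500 ms, habenular LFP and frontal
#' sensors), a late 4-7 Hz increase (2700-3300 ms, LFP only), and an
#' 800-1300 ms 5-10 Hz LFP-frontal coupling increase, all strongest for
#' negative stimuli.
#'
#' @param seed integer seed governing all randomness derived from this
#'   config.
#' @param fs_raw,fs_out raw and analysis sampling rates in Hz (`fs_out`
#'   must divide `fs_raw`).
#' @param n_subjects number of simulated subjects.
#' @param n_trials_per_condition trials per valence condition (>= 2).
#' @param trial_window epoch limits in seconds relative to stimulus onset.
#' @param aperiodic_offset log10 power density at 1 Hz.
#' @param aperiodic_exponent 1/f exponent (chi).
#' @param peak_specs list of `list(cf, amp, bw)` Gaussian oscillatory peaks
#'   applied to LFP channels (amp in log10 power above the aperiodic fit,
#'   bw = two standard deviations, in Hz).
#' @param sensor_peak_specs peaks applied to the MEG-like sensors.
#' @param effect_specs list of [condition_effect()].
#' @param coupling_specs list of [coupling_spec()].
#' @param n_meg_sensors number of planar sensors.
#' @param n_lfp_contacts monopolar DBS contacts per hemisphere.
#' @param erp_amplitude amplitude of the phase-locked evoked transient
#'   (same for all conditions; 0 disables it).
#' @param erp_latency evoked-peak latency in seconds.
#' @param subject_sd log10-amplitude SD of per-subject oscillation gain.
#' @param coupling_theta_link strength of the latent per-subject-condition
#'   factor that jointly raises the 800-1300 ms coupling and the late theta
#'   gain (0 disables the link).
#' @param rating_means list of per-condition `c(valence, arousal)` means on
#'   the 1-9 rating scale; defaults preserve the orderings negative <
#'   neutral < positive on valence and neutral < both on arousal.
#' @param rating_sd SD of the truncated-normal rating distributions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       fs_raw = 1000, fs_out = 250,
                       n_subjects = 9,
                       n_trials_per_condition = 27,
                       trial_window = c(-2.5, 4.5),
                       aperiodic_offset = 1.0,
                       aperiodic_exponent = 1.0,
                       peak_specs = list(list(cf = 8.2, amp = 0.5, bw = 2.4)),
                       sensor_peak_specs = list(list(cf = 9.5, amp = 0.3, bw = 3.0)),
                       effect_specs = default_effect_specs(),
                       coupling_specs = default_coupling_specs(),
                       n_meg_sensors = 32,
                       n_lfp_contacts = 4,
                       erp_amplitude = 0,
                       erp_latency = 0.3,
                       subject_sd = 0.05,
                       coupling_theta_link = 0.15,
                       rating_means = list(neutral  = c(valence = 5.0, arousal = 3.3),
                                           positive = c(valence = 7.1, arousal = 6.3),
                                           negative = c(valence = 2.3, arousal = 6.0)),
                       rating_sd = 0.4) {
  if (fs_raw %% fs_out != 0) stop("fs_out must divide fs_raw")
  if (n_trials_per_condition < 2)
    stop("n_trials_per_condition must be >= 2 (coherence undefined otherwise)")
  if (trial_window[1] > -2.5 || trial_window[2] < 4.5)
    stop("trial_window must span at least [-2.5, 4.5] s")
  for (p in c(peak_specs, sensor_peak_specs)) {
    if (p$bw <= 0) stop("peak bandwidths must be > 0")
    if (p$amp < 0) stop("peak amplitudes must be >= 0")
  }
  for (e in effect_specs) {
    if (e$window[1] < trial_window[1] || e$window[2] > trial_window[2])
      stop("effect window outside trial_window")
  }
  structure(list(seed = as.integer(seed), fs_raw = fs_raw, fs_out = fs_out,
                 n_subjects = n_subjects,
                 n_trials_per_condition = n_trials_per_condition,
                 trial_window = trial_window,
                 aperiodic_offset = aperiodic_offset,
                 aperiodic_exponent = aperiodic_exponent,
                 peak_specs = peak_specs,
                 sensor_peak_specs = sensor_peak_specs,
                 effect_specs = effect_specs,
                 coupling_specs = coupling_specs,
                 n_meg_sensors = n_meg_sensors,
                 n_lfp_contacts = n_lfp_contacts,
                 erp_amplitude = erp_amplitude, erp_latency = erp_latency,
                 subject_sd = subject_sd,
                 coupling_theta_link = coupling_theta_link,
                 rating_means = rating_means, rating_sd = rating_sd),
            class = "sim_config")
}

#' Default condition effects
#'
#' Early 5-10 Hz modulation at 100-500 ms on the LFP channels and frontal
#' sensors, and a late 4-7 Hz modulation at 2700-3300 ms on the LFP only.
#' Amplitude gains (negative 1.2, neutral 1.1, positive 1.0) were chosen so
#' that the negative-vs-positive percent-change contrast lands in the tens
#' of percent, the magnitude typical of event-related synchronization in
#' depth recordings.
#' @return list of [condition_effect()].
#' @export
default_effect_specs <- function() {
  gains <- c(negative = 1.2, neutral = 1.1, positive = 1.0)
  specs <- list()
  for (cond in names(gains)) {
    specs[[length(specs) + 1L]] <-
      condition_effect(cond, c(5, 10), c(0.1, 0.5), gains[[cond]], "lfp")
    specs[[length(specs) + 1L]] <-
      condition_effect(cond, c(5, 10), c(0.1, 0.5), gains[[cond]], "frontal")
    specs[[length(specs) + 1L]] <-
      condition_effect(cond, c(4, 7), c(2.7, 3.3), gains[[cond]], "lfp")
  }
  specs
}

#' Default cross-region couplings
#'
#' 5-10 Hz coupling between each habenular LFP channel and the frontal
#' sensors in the 800-1300 ms window, strongest for negative stimuli.
#' Both hemispheres act as sources (the emulated design analyses every
#' habenula-sensor combination), so the sensor in-band activity carries a
#' shared component from each habenula.
#' @return list of [coupling_spec()].
#' @export
default_coupling_specs <- function() {
  strength <- c(negative = 0.45, neutral = 0.35, positive = 0.25)
  specs <- list()
  for (cond in names(strength)) for (src in c("HabL", "HabR"))
    specs[[length(specs) + 1L]] <-
      coupling_spec(src, "frontal", c(5, 10), c(0.8, 1.3),
                    strength[[cond]], lag = 0.02, condition = cond)
  specs
}

# ---- internal channel bookkeeping -------------------------------------------

task_channels <- function(config) {
  lay <- sensor_layout(config$n_meg_sensors)
  data.frame(
    name = c("HabL", "HabR", lay$name),
    kind = c("lfp_bipolar", "lfp_bipolar", rep("meg_like", nrow(lay))),
    hemisphere = c("left", "right", ifelse(lay$x >= 0, "right", "left")),
    x = c(NA, NA, lay$x), y = c(NA, NA, lay$y),
    group = c("lfp", "lfp", lay$group),
    stringsAsFactors = FALSE)
}

resolve_channels <- function(selector, channels) {
  if (length(selector) == 1 && selector %in% c("lfp", "frontal", "occipital",
                                               "central", "all")) {
    if (selector == "all") return(channels$name)
    return(channels$name[channels$group == selector])
  }
  bad <- setdiff(selector, channels$name)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  selector
}

# In-band power of the baseline spectrum (numerical band integral).
band_power_of <- function(offset, exponent, peaks, band) {
  f <- seq(band[1], band[2], length.out = 200)
  mean(target_psd(f, offset, exponent, peaks)) * diff(band)
}

# Unit-power narrowband process, flat in `band` with 0.5 Hz cosine edges.
band_noise_unit <- function(n, fs, band, edge = 0.5) {
  shaped_noise(n, fs, function(f) band_shape(f, band, edge) / diff(band))
}

erp_kernel <- function(time, amplitude, latency, f0 = 7, width = 0.12) {
  amplitude * exp(-(time - latency)^2 / (2 * width^2)) *
    cos(2 * pi * f0 * (time - latency))
}

# ---- operations -------------------------------------------------------------

#' Simulate a resting multichannel recording
#'
#' Produces monopolar DBS-contact LFP channels (per hemisphere) at the raw
#' sampling rate. Each contact carries an independent realization of the
#' configured 1/f background plus Gaussian oscillatory peaks, and all
#' contacts of a hemisphere share a common-mode component (50 Hz line
#' interference and slow drift) that bipolar referencing and filtering
#' remove.
#'
#' @param config a [sim_config()].
#' @param duration recording length in seconds (>= 60 for stable spectra).
#' @param common_mode logical; include the shared line-noise/drift component.
#' @return an `hp_recording`: list with `data` (samples x channels matrix),
#'   `fs`, `channels` (metadata data.frame), `events` (empty data.frame).
#' @export
simulate_rest <- function(config, duration = 180, common_mode = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (duration < 60) stop("duration must be >= 60 s for stable spectra")
  set.seed(stage_seed(config$seed, 1L))
  fs <- config$fs_raw
  n <- round(duration * fs)
  hemis <- c("left", "right")
  n_c <- config$n_lfp_contacts
  chans <- expand.grid(contact = seq_len(n_c) - 1L, hemisphere = hemis,
                       stringsAsFactors = FALSE)
  chans$name <- sprintf("%s%d", ifelse(chans$hemisphere == "left", "L", "R"),
                        chans$contact)
  chans$kind <- "lfp_monopolar"
  data <- matrix(0, n, nrow(chans))
  psd_fun <- function(f) target_psd(f, config$aperiodic_offset,
                                    config$aperiodic_exponent,
                                    config$peak_specs)
  t_ax <- (seq_len(n) - 1) / fs
  for (h in hemis) {
    cm <- if (common_mode) {
      5 * sin(2 * pi * 50 * t_ax + stats::runif(1, 0, 2 * pi)) +
        shaped_noise(n, fs, function(f) 50 * aperiodic_psd(f, 0, 2, 0.05) *
                       (f < 0.3))
    } else 0
    for (j in which(chans$hemisphere == h))
      data[, j] <- shaped_noise(n, fs, psd_fun) + cm
  }
  colnames(data) <- chans$name
  structure(list(data = data, fs = fs,
                 channels = chans[, c("name", "kind", "hemisphere", "contact")],
                 events = data.frame(onset_s = numeric(0), label = character(0),
                                     picture_id = integer(0))),
            class = "hp_recording")
}

# Core per-subject trial synthesis shared by simulate_task().
simulate_subject_trials <- function(config, subject_id, ratings) {
  fs <- config$fs_out
  tw <- config$trial_window
  time <- seq(tw[1], tw[2] - 1 / fs, by = 1 / fs)
  n <- length(time)
  chans <- task_channels(config)
  conds <- c("neutral", "positive", "negative")
  n_tr <- config$n_trials_per_condition
  subj_gain <- 10^stats::rnorm(1, 0, config$subject_sd)
  latent <- stats::setNames(stats::rnorm(3), conds)   # coupling/theta link

  # per-channel baseline spectra
  ch_peaks <- function(j) {
    if (chans$kind[j] == "lfp_bipolar") config$peak_specs else config$sensor_peak_specs
  }
  off <- config$aperiodic_offset; chi <- config$aperiodic_exponent

  # spatial mixing of sensor background noise
  sens_idx <- which(chans$kind == "meg_like")
  ns <- length(sens_idx)
  d2 <- as.matrix(stats::dist(chans[sens_idx, c("x", "y")]))^2
  K <- exp(-d2 / (2 * 0.4^2))
  M <- K / sqrt(rowSums(K^2))

  trial_meta <- do.call(rbind, lapply(conds, function(cond) {
    rc <- ratings[ratings$condition == cond, , drop = FALSE]
    pick <- rc[sample.int(nrow(rc), n_tr, replace = n_tr > nrow(rc)), ]
    data.frame(condition = cond, picture_id = pick$picture_id,
               valence = pick$valence, arousal = pick$arousal,
               stringsAsFactors = FALSE)
  }))
  # nominal paradigm timeline: 1 s cross + 2 s picture + 3.5 s blank
  trial_meta$onset_s <- 3.5 + (seq_len(nrow(trial_meta)) - 1) * 9.5
  n_trials <- nrow(trial_meta)
  data <- array(0, dim = c(n_trials, nrow(chans), n),
                dimnames = list(NULL, chans$name, NULL))

  erp <- erp_kernel(time, config$erp_amplitude, config$erp_latency)

  # channels acting as coupling sources get their coupling band synthesized
  # explicitly (power-neutral shared-component construction)
  cs_sources <- unique(vapply(config$coupling_specs, `[[`, "", "source_channel"))

  for (tr in seq_len(n_trials)) {
    cond <- trial_meta$condition[tr]
    active_cs <- Filter(function(cs) is.null(cs$condition) ||
                          cs$condition == cond, config$coupling_specs)
    sig <- matrix(0, n, nrow(chans))
    # backgrounds: LFP independent, sensors spatially mixed
    for (j in setdiff(seq_len(nrow(chans)), sens_idx)) {
      nm <- chans$name[j]
      notch <- Filter(function(cs) cs$source_channel == nm, active_cs)
      sig[, j] <- shaped_noise(n, fs, function(f) {
        s <- target_psd(f, off, chi, ch_peaks(j))
        for (cs in notch) s <- s * (1 - band_shape(f, cs$band))
        s
      }) * subj_gain
    }
    iid <- vapply(seq_len(ns), function(i)
      shaped_noise(n, fs, function(f) aperiodic_psd(f, off, chi)), numeric(n))
    sig[, sens_idx] <- iid %*% t(M)
    for (j in sens_idx) {
      for (p in ch_peaks(j))
        sig[, j] <- sig[, j] +
          narrowband_noise(n, fs, off, chi, p$cf, p$amp, p$bw) * subj_gain
    }
    # condition effects: gated band-limited bursts, random phase per trial
    for (e in config$effect_specs) {
      if (e$condition != cond) next
      g <- e$amplitude_gain
      targ <- resolve_channels(e$target_channels, chans)
      if (all(e$band == c(4, 7)) && config$coupling_theta_link > 0)
        g <- max(0, g + config$coupling_theta_link * 0.05 * latent[[cond]])
      if (g == 1) next
      w <- smooth_window(time, e$window[1], e$window[2])
      for (nm in targ) {
        j <- match(nm, chans$name)
        pb <- band_power_of(off, chi, ch_peaks(j), e$band) * subj_gain^2
        burst <- band_noise_unit(n, fs, e$band) * sqrt(pb * max(g^2 - 1, 0))
        sig[, j] <- sig[, j] + w * burst
      }
    }
    # cross-region coupling via a shared gated narrowband component;
    # on the (notched) source the in-band activity is rebuilt as
    # sqrt(1-m)*own + sqrt(m)*shared so that band power stays constant
    for (cs in active_cs) {
      cstr <- cs$coupling_strength
      if (config$coupling_theta_link > 0)
        cstr <- min(0.98, max(0, cstr + config$coupling_theta_link * 0.1 *
                                latent[[cond]]))
      targ <- resolve_channels(cs$target_channels, chans)
      js <- match(cs$source_channel, chans$name)
      if (is.na(js)) stop("unknown coupling source channel: ", cs$source_channel)
      w <- smooth_window(time, cs$window[1], cs$window[2])
      m <- cstr * w
      z <- band_noise_unit(n, fs, cs$band)
      own <- band_noise_unit(n, fs, cs$band)
      lag_n <- round(cs$lag * fs)
      z_lag <- c(rep(0, lag_n), z)[seq_len(n)]
      pb_src <- band_power_of(off, chi, ch_peaks(js), cs$band) * subj_gain^2
      sig[, js] <- sig[, js] +
        sqrt(pb_src) * (sqrt(1 - m) * own + sqrt(m) * z)
      if (cstr <= 0) next
      for (nm in targ) {
        j <- match(nm, chans$name)
        pb <- band_power_of(off, chi, ch_peaks(j), cs$band) * subj_gain^2
        sig[, j] <- sig[, j] + w * z_lag *
          sqrt(cstr / (1 - min(cstr, 0.98)) * pb)
      }
    }
    if (config$erp_amplitude != 0)
      sig <- sig + outer(erp, rep(1, nrow(chans)))
    data[tr, , ] <- t(sig)
  }

  structure(list(data = data, time = time, fs = fs, channels = chans,
                 trials = cbind(subject_id = subject_id, trial_meta),
                 kept = rep(TRUE, n_trials), subject_id = subject_id),
            class = "hp_trialset")
}

#' Simulate picture ratings for the three valence conditions
#'
#' Draws per-picture valence and arousal scores from truncated normal
#' distributions on the 1-9 rating scale. The default condition means give
#' the orderings negative < neutral < positive on valence and neutral <
#' {negative, positive} on arousal, i.e. arousal is non-monotone in valence,
#' which is what lets the mixed models dissociate the two.
#'
#' @param config a [sim_config()].
#' @param n_pictures pictures per condition.
#' @return data.frame `picture_id, condition, valence, arousal`.
#' @export
simulate_ratings <- function(config, n_pictures = 30) {
  conds <- c("neutral", "positive", "negative")
  out <- do.call(rbind, lapply(seq_along(conds), function(k) {
    cond <- conds[k]
    m <- config$rating_means[[cond]]
    data.frame(
      picture_id = (k - 1L) * n_pictures + seq_len(n_pictures),
      condition = cond,
      valence = rtruncnorm(n_pictures, m[["valence"]], config$rating_sd, 1, 9),
      arousal = rtruncnorm(n_pictures, m[["arousal"]], config$rating_sd, 1, 9),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate the full task dataset
#'
#' Generates, for every subject, an epoched trial set (habenular LFP
#' channels plus a planar sensor array) containing a 1/f-plus-peaks
#' background, condition-gated non-phase-locked band-limited bursts, the
#' configured cross-region couplings, and an optional phase-locked evoked
#' transient, together with the picture rating table.
#'
#' @param config a [sim_config()].
#' @return list with `subjects` (list of `hp_trialset`, one per subject)
#'   and `ratings` (picture rating data.frame).
#' @export
simulate_task <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_trials_per_condition < 2)
    stop("n_trials_per_condition must be >= 2")
  set.seed(stage_seed(config$seed, 2L))
  ratings <- simulate_ratings(config)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(stage_seed(config$seed, 100L + s))
    simulate_subject_trials(config, sprintf("sub%02d", s), ratings)
  })
  list(subjects = subjects, ratings = ratings)
}

#' Simulate a coupled two-channel trial set
#'
#' Builds trials for a single channel pair in which, inside the coupling
#' window, both channels share a narrowband component scaled so that the
#' expected cross-trial coherence equals `spec$coupling_strength`; outside
#' the window the channels are independent. `noise_scale = 0` removes the
#' independent in-band noise so that unit coupling yields coherence 1.
#'
#' @param spec a [coupling_spec()].
#' @param config a [sim_config()] (supplies fs, trial window, trial count,
#'   aperiodic background).
#' @param n_trials number of trials (default from config).
#' @param noise_scale multiplier on the independent background noise.
#' @return an `hp_trialset` with channels `"x"` (source) and `"y"` (target).
#' @export
simulate_coupled_pair <- function(spec, config, n_trials = NULL,
                                  noise_scale = 1) {
  stopifnot(inherits(spec, "coupling_spec"), inherits(config, "sim_config"))
  n_trials <- n_trials %||% (config$n_trials_per_condition)
  if (n_trials < 2) stop("need >= 2 trials")
  set.seed(stage_seed(config$seed, 3L))
  fs <- config$fs_out
  tw <- config$trial_window
  time <- seq(tw[1], tw[2] - 1 / fs, by = 1 / fs)
  n <- length(time)
  c0 <- spec$coupling_strength
  w <- smooth_window(time, spec$window[1], spec$window[2])
  lag_n <- round(spec$lag * fs)
  off <- config$aperiodic_offset; chi <- config$aperiodic_exponent
  pb <- band_power_of(off, chi, list(), spec$band)
  # out-of-band aperiodic background; the coupling band is synthesized
  # explicitly so that the realized in-band coherence profile is c0 * w(t)
  # with band power held constant at the baseline level
  bg_psd <- function(f) aperiodic_psd(f, off, chi) * (1 - band_shape(f, spec$band))
  data <- array(0, dim = c(n_trials, 2, n),
                dimnames = list(NULL, c("x", "y"), NULL))
  for (tr in seq_len(n_trials)) {
    z <- band_noise_unit(n, fs, spec$band)
    n1 <- band_noise_unit(n, fs, spec$band)
    n2 <- band_noise_unit(n, fs, spec$band)
    z_lag <- c(rep(0, lag_n), z)[seq_len(n)]
    m <- c0 * w                      # time-resolved target coherence profile
    x <- sqrt(pb) * (sqrt(m) * z + sqrt(1 - m) * n1) +
      noise_scale * shaped_noise(n, fs, bg_psd)
    y <- sqrt(pb) * (sqrt(m) * z_lag + sqrt(1 - m) * n2) +
      noise_scale * shaped_noise(n, fs, bg_psd)
    data[tr, 1, ] <- x
    data[tr, 2, ] <- y
  }
  chans <- data.frame(name = c("x", "y"), kind = c("lfp_bipolar", "meg_like"),
                      hemisphere = c("right", "right"), x = c(NA, 0.1),
                      y = c(NA, 0.5), group = c("lfp", "frontal"),
                      stringsAsFactors = FALSE)
  structure(list(data = data, time = time, fs = fs, channels = chans,
                 trials = data.frame(subject_id = "sub01",
                                     condition = rep("neutral", n_trials),
                                     picture_id = seq_len(n_trials),
                                     valence = 5, arousal = 3.3),
                 kept = rep(TRUE, n_trials), subject_id = "sub01"),
            class = "hp_trialset")
}

#' Generate a synthetic lead field on a regular source grid
#'
#' Sensors are placed at random positions on an upper spherical cap outside
#' the grid; the gain from node j to sensor i follows a smooth distance
#' decay 1 / (eps + d^2) with eps = grid_spacing^2. The columns are distinct
#' for distinct nodes and full rank for the sizes used here.
#'
#' @param n_sensors number of sensors (>= 8).
#' @param grid_dims integer length-3, nodes per axis (total >= 27).
#' @param grid_spacing node spacing in mm.
#' @param seed integer seed for the sensor geometry.
#' @param normalize normalize gain columns to unit norm (default TRUE);
#'   without normalization the unit-gain beamformer's depth bias inflates
#'   power at weakly seen nodes.
#' @return an `hp_leadfield`: list with `gain` (sensor x node), and
#'   `node_positions` (node x 3, mm), `grid_dims`, `grid_spacing`,
#'   `sensor_positions`.
#' @export
make_leadfield <- function(n_sensors, grid_dims = c(4, 4, 4),
                           grid_spacing = 5, seed = 1L, normalize = TRUE) {
  if (n_sensors < 8) stop("n_sensors must be >= 8")
  if (prod(grid_dims) < 27) stop("need >= 27 grid nodes")
  set.seed(stage_seed(seed, 4L))
  ax <- lapply(grid_dims, function(k) (seq_len(k) - (k + 1) / 2) * grid_spacing)
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  if (anyDuplicated(nodes)) stop("degenerate geometry: duplicate node positions")
  r <- max(sqrt(rowSums(nodes^2))) + 2 * grid_spacing
  # sensors on an upper cap, jittered for genericity
  u <- stats::runif(n_sensors, 0.3, 1)        # cos(theta)
  phi <- stats::runif(n_sensors, 0, 2 * pi)
  sens <- cbind(r * sqrt(1 - u^2) * cos(phi),
                r * sqrt(1 - u^2) * sin(phi),
                r * u)
  eps <- grid_spacing^2
  gain <- matrix(0, n_sensors, nrow(nodes))
  for (j in seq_len(nrow(nodes))) {
    d2 <- rowSums((sens - matrix(nodes[j, ], n_sensors, 3, byrow = TRUE))^2)
    gain[, j] <- 1 / (eps + d2)
  }
  if (any(colSums(abs(gain)) == 0)) stop("all-zero lead-field column")
  if (normalize) gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
  structure(list(gain = gain, node_positions = nodes,
                 grid_dims = grid_dims, grid_spacing = grid_spacing,
                 sensor_positions = sens),
            class = "hp_leadfield")
}

#' @export
print.hp_trialset <- function(x, ...) {
  cat(sprintf("<hp_trialset> %d trials x %d channels x %d samples @ %g Hz, t in [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$time), max(x$time)))
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$trials$condition)),
                                     table(x$trials$condition)), collapse = " "),
      sprintf(" kept=%d/%d\n", sum(x$kept), length(x$kept)))
  invisible(x)
}

#' @export
print.hp_recording <- function(x, ...) {
  cat(sprintf("<hp_recording> %d samples x %d channels @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}
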