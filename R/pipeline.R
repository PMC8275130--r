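# End-to-end orchestration of the synthetic study.

#' Analysis constants for the full study
#'
#' Couples a [sim_config()] with the analysis constants used across the
#' pipeline: frequency bands (theta/alpha 5-10 Hz, theta 4-7 Hz, beta
#' 12-30 Hz), the analysis windows (early 100-500 ms, coupling
#' 800-1300 ms, late 2700-3300 ms, baseline -2000 to -200 ms), the
#' permutation count, pre-cluster threshold and beamformer regularization.
#'
#' @param sim a [sim_config()].
#' @param n_perm permutations for all cluster tests (default 1000).
#' @param pre_cluster_alpha per-bin threshold (default 0.05).
#' @param lambda_frac beamformer regularization (default 0.01).
#' @param tf_freqs frequency grid for the LFP/sensor TF maps.
#' @param coh_freqs frequency grid for coherence (theta/alpha band).
#' @param decim TFR time decimation factor.
#' @param rest_duration seconds of resting data.
#' @param grid_dims source grid dimensions for the beamformer stage.
#' @param quick reduced sizes for fast runs (fewer trials, sensors and
#'   permutations); the analysis logic is unchanged.
#' @return a `study_config` list.
#' @export
study_config <- function(sim = sim_config(), n_perm = 1000,
                         pre_cluster_alpha = 0.05, lambda_frac = 0.01,
                         tf_freqs = 2:30, coh_freqs = 5:10, decim = 4L,
                         rest_duration = 120, grid_dims = c(4, 4, 4),
                         quick = FALSE) {
  if (quick) {
    # only nuisance sizes are reduced; trial and subject counts stay at
    # the design level because cross-trial coherence bias/variance scales
    # with 1/n_trials and the group tests' power with the sample counts —
    # cutting them would change what is being estimated.
    sim$n_meg_sensors <- min(sim$n_meg_sensors, 24L)
    n_perm <- min(n_perm, 200L)
    rest_duration <- min(rest_duration, 60)
    grid_dims <- c(3, 3, 3)
  }
  structure(list(
    sim = sim,
    bands = list(theta_alpha = c(5, 10), theta = c(4, 7), beta = c(12, 30)),
    windows = list(early = c(0.1, 0.5), coupling = c(0.8, 1.3),
                   late = c(2.7, 3.3), baseline = c(-2, -0.2)),
    control_windows = list(`-200-300ms` = c(-0.2, 0.3),
                           `300-800ms` = c(0.3, 0.8),
                           `1300-1800ms` = c(1.3, 1.8),
                           `1800-2300ms` = c(1.8, 2.3)),
    n_perm = n_perm, pre_cluster_alpha = pre_cluster_alpha,
    lambda_frac = lambda_frac, tf_freqs = tf_freqs, coh_freqs = coh_freqs,
    decim = as.integer(decim), rest_duration = rest_duration,
    grid_dims = grid_dims, quick = quick), class = "study_config")
}

# FNV-1a hash of a serialized R object, as provenance fingerprint.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[habpipe] ", fmt), ...))
}

#' Run the full synthetic study end-to-end
#'
#' Sequences generation, preprocessing, resting spectral parameterization,
#' task time-frequency analysis, cortico-LFP coherence, cluster-based
#' permutation statistics, source localization and mixed-effects modeling,
#' returning a structured report. Fully deterministic given the config
#' seed.
#'
#' @param cfg a [study_config()].
#' @param verbose log stage boundaries.
#' @return a `study_report` list; see the elements `spectra`, `tf_cluster`,
#'   `sensor_cluster`, `coherence`, `source`, `lme`, `flags`, `provenance`.
#' @export
run_study <- function(cfg = study_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  t0 <- Sys.time()
  sim <- cfg$sim
  ba <- cfg$bands; wi <- cfg$windows

  # --- generation ------------------------------------------------------
  log_stage(verbose, "simulate: rest %gs + task (%d subjects x %d trials/cond)",
            cfg$rest_duration, sim$n_subjects, sim$n_trials_per_condition)
  rest <- simulate_rest(sim, duration = cfg$rest_duration)
  task <- simulate_task(sim)
  layout <- sensor_layout(sim$n_meg_sensors)

  # --- preprocessing + resting spectra ---------------------------------
  log_stage(verbose, "preprocess rest: bipolar + filter chain %g -> %g Hz",
            sim$fs_raw, sim$fs_out)
  rest_bp <- filter_chain(bipolar_reference(rest), fs_out = sim$fs_out)
  psd <- welch_psd(rest_bp)
  fits <- lapply(seq_len(ncol(psd$power)), function(j)
    fit_spectral_model(psd, channel = j))
  names(fits) <- colnames(psd$power)
  spec_table <- specfit_table(fits)

  # --- per-subject task analysis ---------------------------------------
  conds <- c("neutral", "positive", "negative")
  lfp_names <- c("HabL", "HabR")
  frontal <- layout$name[layout$group == "frontal"]
  rfrontal <- layout$name[layout$group == "frontal" & layout$x >= 0]
  occipital <- layout$name[layout$group == "occipital"]

  lfp_maps <- list(); sens_vals <- list(); coh_tc <- list()
  coh_win <- list(); coh_ctrl <- list(); meas_rows <- list()
  hab_rows <- list()
  src_pow <- list(); csd_ref_neg <- NULL
  lf <- make_leadfield(sim$n_meg_sensors, cfg$grid_dims, grid_spacing = 5,
                       seed = sim$seed)

  for (s in seq_along(task$subjects)) {
    ts <- task$subjects[[s]]
    sid <- ts$subject_id
    log_stage(verbose, "analyze %s (%d/%d)", sid, s, length(task$subjects))

    # LFP time-frequency maps, percent change per condition
    tfr_lfp <- morlet_tfr(ts, freqs = cfg$tf_freqs, channels = lfp_names,
                          decim = cfg$decim)
    avg <- tfr_condition_average(tfr_lfp)
    norm <- lapply(avg, baseline_normalize, baseline = wi$baseline)
    for (cond in conds) for (ch in lfp_names) {
      key <- paste(sid, ch, sep = "_")
      lfp_maps[[cond]][[key]] <- norm[[cond]]$power[ch, , ]
    }

    # sensor + LFP complex TFR in the coherence band
    tfr_coh <- morlet_tfr(ts, freqs = cfg$coh_freqs,
                          channels = c(lfp_names, layout$name),
                          decim = cfg$decim, keep_complex = TRUE)
    # sensor band/window power values per condition (for topography test)
    savg <- tfr_condition_average(tfr_coh)
    snorm <- lapply(savg, baseline_normalize, baseline = wi$baseline)
    for (cond in conds)
      sens_vals[[cond]] <- rbind(sens_vals[[cond]],
        band_window_average(snorm[[cond]], ba$theta_alpha, wi$early)[layout$name])

    # cross-trial coherence per condition and habenula (the emulated
    # design analyses every habenula-sensor combination), with trial
    # counts equalized across conditions
    tse <- equalize_trial_counts(ts, seed = sim$seed + s)
    for (cond in conds) {
      idx <- which(tfr_coh$trials$condition == cond & tse$kept)
      sub <- tfr_coh
      sub$fourier <- tfr_coh$fourier[idx, , , , drop = FALSE]
      sub$power <- tfr_coh$power[idx, , , , drop = FALSE]
      sub$trials <- NULL
      for (ref in lfp_names) {
        panel <- cross_trial_coherence(sub, ref = ref,
                                       targets = layout$name)
        pct <- coherence_baseline_change(panel, baseline = wi$baseline)
        allavg <- coherence_group_average(pct, layout$name)
        tsel <- pct$time >= wi$coupling[1] & pct$time <= wi$coupling[2]
        coh_tc[[cond]] <- rbind(coh_tc[[cond]], colMeans(allavg))
        coh_win[[cond]] <- rbind(coh_win[[cond]], c(
          all = mean(allavg[, tsel]),
          frontal = mean(coherence_group_average(pct, frontal)[, tsel]),
          rfrontal = mean(coherence_group_average(pct, rfrontal)[, tsel]),
          occipital = if (length(occipital))
            mean(coherence_group_average(pct, occipital)[, tsel]) else NA_real_))
        for (nm in names(cfg$control_windows)) {
          cw <- cfg$control_windows[[nm]]
          csel <- pct$time >= cw[1] & pct$time <= cw[2]
          coh_ctrl[[nm]][[cond]] <- c(coh_ctrl[[nm]][[cond]],
            mean(coherence_group_average(pct, rfrontal)[, csel]))
        }
      }

      # beamformer power maps in the early window
      csd <- band_csd(tfr_coh_subset(sub), ba$theta_alpha, wi$early,
                      sensors = layout$name)
      W <- dics_filters(lf, csd, cfg$lambda_frac)
      src_pow[[cond]] <- rbind(src_pow[[cond]],
                               Re(diag(W %*% csd$csd %*% Conj(t(W)))))
      if (cond == "negative" && is.null(csd_ref_neg))
        csd_ref_neg <- band_csd(tfr_coh_subset(sub), ba$theta_alpha,
                                wi$coupling, sensors = layout$name,
                                ref = "HabR")
    }

    # per subject x condition measures for the mixed models (habenula
    # measures averaged over hemispheres; per-habenula values kept for
    # the coherence-power analysis)
    for (cond in conds) {
      trl <- ts$trials[ts$trials$condition == cond, ]
      hab1_ch <- vapply(lfp_names, function(ch)
        band_window_average_mat(norm[[cond]]$power[ch, , ], cfg$tf_freqs,
                                norm[[cond]]$time, ba$theta_alpha, wi$early),
        0)
      hab2_ch <- vapply(lfp_names, function(ch)
        band_window_average_mat(norm[[cond]]$power[ch, , ], cfg$tf_freqs,
                                norm[[cond]]$time, ba$theta, wi$late), 0)
      pfc <- mean(band_window_average(snorm[[cond]], ba$theta_alpha,
                                      wi$early)[frontal])
      rows <- nrow(coh_win[[cond]]) - c(1L, 0L)   # HabL, HabR of this subject
      coh_ch <- coh_win[[cond]][rows, "rfrontal"]
      meas_rows[[length(meas_rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond,
        HabTheta1 = mean(hab1_ch), HabTheta2 = mean(hab2_ch),
        PFC_Theta = pfc, rPFC_Hab_Coh = mean(coh_ch),
        valence = mean(trl$valence), arousal = mean(trl$arousal))
      hab_rows[[length(hab_rows) + 1L]] <- data.frame(
        subject_id = sid, hemisphere = c("left", "right"), condition = cond,
        HabTheta2 = unname(hab2_ch), rPFC_Hab_Coh = unname(coh_ch))
    }
  }

  # --- group statistics -------------------------------------------------
  log_stage(verbose, "cluster statistics (%d permutations)", cfg$n_perm)
  tfr_time <- tfr_time_axis(task$subjects[[1]], cfg$decim)
  to_array <- function(lst) {
    arr <- array(0, dim = c(length(lst), dim(lst[[1]])))
    for (i in seq_along(lst)) arr[i, , ] <- lst[[i]]
    arr
  }
  keys <- names(lfp_maps$negative)
  tf_cluster <- tf_cluster_permutation(
    to_array(lfp_maps$negative[keys]), to_array(lfp_maps$positive[keys]),
    n_perm = cfg$n_perm, pre_cluster_alpha = cfg$pre_cluster_alpha,
    seed = sim$seed, freqs = cfg$tf_freqs, time = tfr_time)

  adj <- sensor_adjacency(layout)
  sensor_cluster <- sensor_cluster_permutation(
    sens_vals$negative, sens_vals$positive, adj, n_perm = cfg$n_perm,
    pre_cluster_alpha = cfg$pre_cluster_alpha, seed = sim$seed)

  coh_test <- permutation_ttest_paired(coh_win$negative[, "all"],
                                       coh_win$positive[, "all"],
                                       n_perm = cfg$n_perm, seed = sim$seed)

  source_contrast <- source_power_contrast(src_pow$negative,
                                           src_pow$positive, lf,
                                           n_perm = cfg$n_perm,
                                           tail = "pos", seed = sim$seed)
  coh_map <- dics_coherence_map(lf, csd_ref_neg, cfg$lambda_frac)

  # --- mixed models -----------------------------------------------------
  log_stage(verbose, "mixed-effects models")
  meas <- do.call(rbind, meas_rows)
  lme_fits <- lapply(c("HabTheta1", "HabTheta2", "PFC_Theta", "rPFC_Hab_Coh"),
                     function(m) fit_random_intercept_lme(meas, m))
  names(lme_fits) <- c("HabTheta1", "HabTheta2", "PFC_Theta", "rPFC_Hab_Coh")

  # coherence-power link at the habenula level (one observation per
  # habenula x condition, subject as random effect)
  hab <- do.call(rbind, hab_rows)
  cp <- coherence_power_regression(
    data.frame(subject_id = hab$subject_id,
               coherence = hab$rPFC_Hab_Coh, power = hab$HabTheta2),
    n_perm = cfg$n_perm, seed = sim$seed)
  # control-window coherence values are stored condition-major with
  # habenula order preserved inside each condition; pair the power
  # measure identically
  pw_cond_major <- unlist(lapply(conds, function(cond)
    hab$HabTheta2[hab$condition == cond]), use.names = FALSE)
  ctrl <- control_window_specificity(
    lapply(coh_ctrl, function(byc) unlist(byc[conds], use.names = FALSE)),
    pw_cond_major, n_perm = cfg$n_perm, seed = sim$seed)

  # --- flags against the expected synthetic effects ---------------------
  tile_overlap <- function(res, band, window) {
    any(vapply(significant_clusters(res), function(cl) {
      f <- res$freqs[cl$members_fi]; t <- res$time[cl$members_ti]
      any(f >= band[1] & f <= band[2] & t >= window[1] & t <= window[2])
    }, TRUE))
  }
  frontal_idx <- which(layout$group == "frontal")
  flags <- list(
    early_lfp_cluster = length(significant_clusters(tf_cluster)) > 0 &&
      tile_overlap(tf_cluster, ba$theta_alpha, wi$early),
    late_lfp_cluster = tile_overlap(tf_cluster, ba$theta, wi$late),
    frontal_sensor_cluster = any(vapply(significant_clusters(sensor_cluster),
                                        function(cl) any(cl$members %in% frontal_idx),
                                        TRUE)),
    coherence_contrast = coh_test$p <= 0.05 && coh_test$t > 0,
    lme_valence_negative = all(vapply(lme_fits, function(f)
      f$fixed$estimate[f$fixed$term == "valence"] < 0, TRUE)),
    lme_valence_significant = vapply(lme_fits, function(f)
      f$fixed$p[f$fixed$term == "valence"] <= 0.05, TRUE),
    lme_arousal_ns = vapply(lme_fits, function(f)
      f$fixed$p[f$fixed$term == "arousal"] > 0.05, TRUE),
    coherence_power_link = cp$slope_p <= 0.05 && cp$slope > 0)

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_stage(verbose, "done in %.1f s", elapsed)
  structure(list(
    spectra = spec_table, spectral_fits = fits,
    tf_cluster = tf_cluster, sensor_cluster = sensor_cluster,
    coherence_timecourse = coh_tc, coherence_window = coh_win,
    coherence_test = coh_test,
    source = source_contrast, coherence_map = coh_map,
    measures = meas, habenula_measures = hab,
    lme = lme_fits, coherence_power = cp,
    window_specificity = ctrl, ratings = task$ratings,
    flags = flags, layout = layout,
    provenance = list(config_hash = config_hash(cfg), seed = sim$seed,
                      elapsed_s = elapsed,
                      version = as.character(utils::packageVersion("habpipe")))),
    class = "study_report")
}

# helper: trialset's decimated, buffered TFR time axis without recomputing
tfr_time_axis <- function(tset, decim) {
  time <- tset$time
  keep <- which(time >= time[1] + 0.5 - 1e-9 &
                  time <= time[length(time)] - 0.5 + 1e-9)
  time[keep[seq(1, length(keep), by = decim)]]
}

# helper: band/window average on a freq x time matrix
band_window_average_mat <- function(m, freqs, time, band, window) {
  fsel <- freqs >= band[1] & freqs <= band[2]
  tsel <- time >= window[1] & time <= window[2]
  mean(m[fsel, tsel])
}

# helper: an hp_tfr whose fourier array was subset to one condition
tfr_coh_subset <- function(sub) {
  if (is.null(sub$trials))
    sub$trials <- data.frame(condition = rep("x", dim(sub$fourier)[1]))
  sub
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  resting peaks:\n")
  print(x$spectra[, c("channel", "cf", "band")])
  cat(sprintf("  TF clusters (neg vs pos): %d significant\n",
              length(significant_clusters(x$tf_cluster))))
  cat(sprintf("  sensor clusters: %d significant\n",
              length(significant_clusters(x$sensor_cluster))))
  cat(sprintf("  coherence contrast 800-1300 ms: t=%.2f p=%.4f\n",
              x$coherence_test$t, x$coherence_test$p))
  cat(sprintf("  coherence-power link: slope=%.3f p=%.4f\n",
              x$coherence_power$slope, x$coherence_power$slope_p))
  cat("  flags:\n")
  for (nm in names(x$flags))
    cat(sprintf("    %-26s %s\n", nm,
                paste(x$flags[[nm]], collapse = " ")))
  invisible(x)
}

#' Write the study report summary as JSON
#'
#' Persists the numeric summaries (spectral table, cluster masses and
#' p-values with their null distributions, coherence contrasts, LME
#' coefficients, flags, provenance) to a JSON file.
#'
#' @param report a `study_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  cl_json <- function(res) list(
    n_perm = res$n_perm,
    clusters = lapply(res$clusters, function(cl)
      list(mass = cl$mass, size = length(cl$members), p = cl$p,
           members = cl$members)),
    null_distribution = res$null_distribution)
  out <- list(
    spectra = report$spectra,
    tf_cluster = cl_json(report$tf_cluster),
    sensor_cluster = cl_json(report$sensor_cluster),
    coherence_test = report$coherence_test[c("t", "p", "ci", "mean_diff")],
    lme = lapply(report$lme, function(f)
      list(formula = f$formula, fixed = f$fixed,
           r2_marginal = f$r2_marginal)),
    coherence_power = list(slope = report$coherence_power$slope,
                           ci = report$coherence_power$slope_ci,
                           p = report$coherence_power$slope_p,
                           r = report$coherence_power$correlation$r),
    window_specificity = report$window_specificity,
    flags = report$flags,
    provenance = report$provenance)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
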