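# Re-referencing, filtering, down-sampling, epoching, artifact exclusion.

#' Bipolar re-referencing of monopolar DBS contacts
#'
#' Constructs bipolar channels by subtracting monopolar recordings from
#' neighboring contacts on each electrode (contact i minus contact i+1,
#' with contact 0 the deepest), removing the shared reference and
#' common-mode interference. Four contacts per hemisphere yield three
#' bipolar channels.
#'
#' @param rec an `hp_recording` whose channels carry `hemisphere` and
#'   `contact` metadata (kind `"lfp_monopolar"`).
#' @return an `hp_recording` with bipolar channels named e.g. `"L01"`
#'   (left, contacts 0-1).
#' @export
bipolar_reference <- function(rec) {
  stopifnot(inherits(rec, "hp_recording"))
  ch <- rec$channels
  mono <- which(ch$kind == "lfp_monopolar")
  if (!length(mono)) stop("no monopolar LFP channels present")
  out_cols <- list(); out_meta <- list()
  for (h in unique(ch$hemisphere[mono])) {
    idx <- mono[ch$hemisphere[mono] == h]
    idx <- idx[order(ch$contact[idx])]
    if (length(idx) < 2)
      stop("hemisphere '", h, "' has a single contact; cannot re-reference")
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      out_cols[[length(out_cols) + 1L]] <- rec$data[, a] - rec$data[, b]
      out_meta[[length(out_meta) + 1L]] <- data.frame(
        name = sprintf("%s%d%d", toupper(substr(h, 1, 1)),
                       ch$contact[a], ch$contact[b]),
        kind = "lfp_bipolar", hemisphere = h,
        contact = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  data <- do.call(cbind, out_cols)
  meta <- do.call(rbind, out_meta)
  colnames(data) <- meta$name
  structure(list(data = data, fs = rec$fs, channels = meta,
                 events = rec$events), class = "hp_recording")
}

#' Standard filtering and down-sampling chain
#'
#' Applies, in order: zero-phase 4th-order Butterworth high-pass at
#' `hp_hz`, zero-phase IIR band-stop notches (2 Hz wide) at `notch_hz` and
#' its harmonics below the low-pass edge, a zero-phase 4th-order
#' Butterworth low-pass at `lp_hz` (which also serves as the anti-alias
#' filter), and decimation to `fs_out`. All filters are applied
#' forward-backward (`signal::filtfilt`), so the chain has zero phase and
#' preserves latencies.
#'
#' @param rec an `hp_recording`.
#' @param fs_out output sampling rate in Hz.
#' @param hp_hz,lp_hz high-/low-pass corner frequencies in Hz.
#' @param notch_hz line frequency in Hz (`NULL` disables notching).
#' @return the filtered, down-sampled `hp_recording`.
#' @export
filter_chain <- function(rec, fs_out = 250, hp_hz = 0.3, lp_hz = 100,
                         notch_hz = 50) {
  stopifnot(inherits(rec, "hp_recording"))
  fs <- rec$fs
  if (fs <= 2 * lp_hz) stop("input sampling rate must exceed twice the low-pass edge")
  x <- rec$data
  nyq <- fs / 2
  bh <- signal::butter(4, hp_hz / nyq, type = "high")
  bl <- signal::butter(4, lp_hz / nyq, type = "low")
  notches <- if (is.null(notch_hz)) numeric(0) else {
    h <- seq(notch_hz, lp_hz - 1e-9, by = notch_hz)
    h[h < lp_hz]
  }
  for (j in seq_len(ncol(x))) {
    v <- signal::filtfilt(bh, x[, j])
    for (f0 in notches) {
      bs <- signal::butter(2, c(f0 - 1, f0 + 1) / nyq, type = "stop")
      v <- signal::filtfilt(bs, v)
    }
    x[, j] <- signal::filtfilt(bl, v)
  }
  dec <- fs / fs_out
  if (abs(dec - round(dec)) < 1e-9) {
    keep <- seq(1, nrow(x), by = round(dec))
    x <- x[keep, , drop = FALSE]
  } else {
    warning("fs_in is not an integer multiple of fs_out; resampling")
    n_out <- round(nrow(x) * fs_out / fs)
    x <- apply(x, 2, function(v)
      stats::approx(seq_along(v), v, xout = seq(1, length(v),
                                                length.out = n_out))$y)
  }
  ev <- rec$events
  structure(list(data = x, fs = fs_out, channels = rec$channels, events = ev),
            class = "hp_recording")
}

#' Epoch a continuous recording around events
#'
#' Cuts fixed-length windows around each event onset and joins the event
#' metadata onto the trials. Events whose window would exceed the recording
#' bounds are dropped with a message.
#'
#' @param rec an `hp_recording` with an `events` table (`onset_s`, `label`,
#'   optionally `picture_id`, `valence`, `arousal`).
#' @param window numeric length-2, epoch limits in seconds relative to
#'   onset (default `c(-2.5, 4.5)`).
#' @param subject_id subject identifier stored on the trial set.
#' @return an `hp_trialset`.
#' @export
epoch_trials <- function(rec, window = c(-2.5, 4.5), subject_id = "sub01") {
  stopifnot(inherits(rec, "hp_recording"))
  ev <- rec$events
  if (!nrow(ev)) stop("recording has no events to epoch around")
  fs <- rec$fs
  n_per <- round(diff(window) * fs)
  rel <- seq_len(n_per) - 1 + round(window[1] * fs)
  n_samp <- nrow(rec$data)
  onset_idx <- round(ev$onset_s * fs) + 1L
  ok <- (onset_idx + rel[1]) >= 1 & (onset_idx + rel[n_per]) <= n_samp
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: window exceeds recording bounds")
  ev <- ev[ok, , drop = FALSE]; onset_idx <- onset_idx[ok]
  if (!nrow(ev)) stop("no events with complete windows")
  data <- array(0, dim = c(nrow(ev), ncol(rec$data), n_per),
                dimnames = list(NULL, colnames(rec$data), NULL))
  for (tr in seq_len(nrow(ev)))
    data[tr, , ] <- t(rec$data[onset_idx[tr] + rel, , drop = FALSE])
  trials <- data.frame(subject_id = subject_id,
                       condition = ev$label,
                       onset_s = ev$onset_s,
                       picture_id = ev$picture_id %||% seq_len(nrow(ev)),
                       valence = ev$valence %||% NA_real_,
                       arousal = ev$arousal %||% NA_real_,
                       stringsAsFactors = FALSE)
  structure(list(data = data, time = rel / fs, fs = fs,
                 channels = rec$channels, trials = trials,
                 kept = rep(TRUE, nrow(ev)), subject_id = subject_id),
            class = "hp_trialset")
}

#' Exclude trials overlapping marked artifact windows
#'
#' Marks trials whose epoch overlaps any supplied artifact interval as not
#' kept. Intervals are in absolute recording time (seconds); each trial
#' occupies `onset_s + range(time)` on that axis (the `onset_s` column of
#' the trial table). Optionally auto-marks trials containing samples with
#' |z| above `z_thresh` on any channel — a reproducible stand-in for visual
#' inspection. Errors if fewer than two trials per condition would remain,
#' since cross-trial coherence is undefined below that.
#'
#' @param tset an `hp_trialset`.
#' @param marked_windows list of numeric length-2 intervals in absolute
#'   recording time (seconds).
#' @param z_thresh optional amplitude threshold for automatic marking
#'   (standard deviations per channel; `NULL` disables).
#' @return the `hp_trialset` with an updated `kept` mask.
#' @export
reject_artifacts <- function(tset, marked_windows = list(), z_thresh = NULL) {
  stopifnot(inherits(tset, "hp_trialset"))
  kept <- tset$kept
  if (length(marked_windows)) {
    on <- tset$trials$onset_s
    if (is.null(on)) stop("trial table has no 'onset_s' column")
    lo <- on + tset$time[1]
    hi <- on + tset$time[length(tset$time)]
    for (w in marked_windows) kept[hi >= w[1] & lo <= w[2]] <- FALSE
  }
  if (!is.null(z_thresh)) {
    for (j in seq_len(dim(tset$data)[2])) {
      ch <- tset$data[, j, , drop = TRUE]
      if (is.null(dim(ch))) ch <- matrix(ch, nrow = dim(tset$data)[1])
      z <- abs(ch - mean(ch)) / stats::sd(ch)
      kept[apply(z > z_thresh, 1, any)] <- FALSE
    }
  }
  tab <- table(tset$trials$condition[kept])
  if (length(tab) && any(tab < 2))
    stop("artifact rejection would leave fewer than 2 trials in condition(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  tset$kept <- kept
  tset
}

#' Subset a trial set to its kept trials
#' @param tset an `hp_trialset`.
#' @return the trial set with rejected trials removed.
#' @export
kept_trials <- function(tset) {
  stopifnot(inherits(tset, "hp_trialset"))
  k <- tset$kept
  tset$data <- tset$data[k, , , drop = FALSE]
  tset$trials <- tset$trials[k, , drop = FALSE]
  tset$kept <- rep(TRUE, sum(k))
  tset
}
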