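# Morlet wavelet time-frequency decomposition and derived quantities.

# Complex Morlet kernel at frequency f: analytic carrier with Gaussian
# envelope of SD sigma_t = n_cycles / (2 pi f), clipped at +/- 4 sigma_t.
# Normalized so a unit-amplitude real sinusoid at f yields magnitude 1.
morlet_kernel <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * f * t)
  w * (2 / sum(g))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (`n_cycles` cycles, temporal SD `n_cycles / (2 pi f)`), via FFT-based
#' convolution. Power is the squared magnitude. A `buffer` at each epoch
#' edge is computed from the full data and then trimmed, so no retained
#' sample's wavelet support leans on zero padding (edge safety holds for
#' frequencies with 4 sigma_t <= buffer; the lowest frequencies are
#' attenuated at the very edges of the retained axis rather than
#' contaminated by padding).
#'
#' @param tset an `hp_trialset` (kept trials are used).
#' @param freqs frequency grid in Hz (default 2-40 in 1 Hz steps).
#' @param n_cycles wavelet cycles (default 6).
#' @param channels channel names or indices to decompose (default all).
#' @param buffer seconds trimmed from each epoch edge (default 0.5).
#' @param decim keep every `decim`-th output time sample (default 1).
#' @param keep_complex retain the complex spectra (needed for coherence
#'   and cross-spectral densities).
#' @return an `hp_tfr`: `power` array (trial x channel x freq x time),
#'   optional `fourier` complex array, `freqs`, `time`, `fs`, `n_cycles`,
#'   `channels`, `trials`, `normalized = FALSE`.
#' @export
morlet_tfr <- function(tset, freqs = 2:40, n_cycles = 6, channels = NULL,
                       buffer = 0.5, decim = 1L, keep_complex = FALSE) {
  stopifnot(inherits(tset, "hp_trialset"))
  tset <- kept_trials(tset)
  fs <- tset$fs
  time <- tset$time
  n <- length(time)
  if (any(freqs < 1 / (n / fs)))
    stop("frequency below 1/trial-length cannot be resolved")
  if (min(freqs) > 0 && n_cycles / min(freqs) > n / fs)
    stop("lowest frequency needs n_cycles/f <= trial length")
  ch_idx <- if (is.null(channels)) seq_len(dim(tset$data)[2]) else {
    if (is.character(channels)) match(channels, tset$channels$name) else channels
  }
  if (anyNA(ch_idx)) stop("unknown channel selection")
  keep_t <- which(time >= time[1] + buffer - 1e-9 &
                    time <= time[n] - buffer + 1e-9)
  keep_t <- keep_t[seq(1, length(keep_t), by = decim)]
  out_time <- time[keep_t]
  n_tr <- dim(tset$data)[1]

  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles)
  max_nk <- max(vapply(kernels, length, 1L))
  nfft <- stats::nextn(n + max_nk - 1L, 2)

  pow <- array(NA_real_, dim = c(n_tr, length(ch_idx), length(freqs),
                                 length(keep_t)))
  four <- if (keep_complex)
    array(NA_complex_, dim = dim(pow)) else NULL

  for (jj in seq_along(ch_idx)) {
    X <- matrix(tset$data[, ch_idx[jj], ], nrow = n_tr)
    Xp <- rbind(t(X), matrix(0, nfft - n, n_tr))
    FX <- stats::mvfft(Xp)
    for (kk in seq_along(freqs)) {
      ker <- kernels[[kk]]
      nk <- length(ker)
      ic <- (nk + 1L) %/% 2L
      FK <- stats::fft(c(Conj(rev(ker)), complex(real = rep(0, nfft - nk))))
      conv <- stats::mvfft(FX * FK, inverse = TRUE) / nfft
      # index t of full convolution output aligned so sample s of the input
      # corresponds to row s + nk - ic of the linear convolution
      rows <- keep_t + (nk - ic)
      seg <- conv[rows, , drop = FALSE]
      pow[, jj, kk, ] <- t(abs(seg)^2)
      if (keep_complex) four[, jj, kk, ] <- t(seg)
    }
  }
  dimnames(pow)[[2]] <- tset$channels$name[ch_idx]
  if (keep_complex) dimnames(four)[[2]] <- tset$channels$name[ch_idx]
  structure(list(power = pow, fourier = four, freqs = as.numeric(freqs),
                 time = out_time, fs = fs, n_cycles = n_cycles,
                 channels = tset$channels[ch_idx, , drop = FALSE],
                 trials = tset$trials, normalized = FALSE,
                 baseline_window = NULL),
            class = "hp_tfr")
}

#' Average a trial-resolved TFR within conditions
#'
#' @param tfr an `hp_tfr` with a trial dimension.
#' @param conditions conditions to include (default: all present).
#' @return named list of `hp_tfr`, each with `power` (channel x freq x
#'   time) averaged over that condition's trials.
#' @export
tfr_condition_average <- function(tfr, conditions = NULL) {
  stopifnot(inherits(tfr, "hp_tfr"), length(dim(tfr$power)) == 4)
  conds <- conditions %||% unique(tfr$trials$condition)
  out <- lapply(conds, function(cond) {
    sel <- which(tfr$trials$condition == cond)
    if (!length(sel)) stop("condition absent: ", cond)
    avg <- apply(tfr$power[sel, , , , drop = FALSE], c(2, 3, 4), mean)
    structure(list(power = avg, fourier = NULL, freqs = tfr$freqs,
                   time = tfr$time, fs = tfr$fs, n_cycles = tfr$n_cycles,
                   channels = tfr$channels, trials = NULL,
                   n_trials = length(sel), normalized = FALSE,
                   baseline_window = NULL),
              class = "hp_tfr")
  })
  names(out) <- conds
  out
}

#' Baseline percent-change normalization
#'
#' Converts power to percentage change relative to the mean pre-stimulus
#' power, per channel and frequency:
#' `100 * (P(t, f) - Pbase(f)) / Pbase(f)`. Following standard practice
#' the normalization is applied to trial-averaged power: a trial-resolved
#' TFR is averaged first (use [tfr_condition_average()] for per-condition
#' maps) unless `per_trial = TRUE`.
#'
#' @param tfr an `hp_tfr`.
#' @param baseline numeric length-2 baseline window in seconds (default
#'   `c(-2, -0.2)`).
#' @param per_trial normalize each trial by its own baseline instead.
#' @return the normalized `hp_tfr` (values in percent, >= -100).
#' @export
baseline_normalize <- function(tfr, baseline = c(-2, -0.2),
                               per_trial = FALSE) {
  stopifnot(inherits(tfr, "hp_tfr"))
  if (isTRUE(tfr$normalized)) stop("TFR is already baseline-normalized")
  bsel <- tfr$time >= baseline[1] & tfr$time <= baseline[2]
  if (!any(bsel)) stop("baseline window outside the time axis")
  nd <- length(dim(tfr$power))
  if (nd == 4 && !per_trial)
    tfr$power <- apply(tfr$power, c(2, 3, 4), mean)
  nd <- length(dim(tfr$power))
  if (nd == 3) {
    base <- apply(tfr$power[, , bsel, drop = FALSE], c(1, 2), mean)
    if (any(base <= 0)) {
      bad <- which(base <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf("zero baseline power at channel %s, %.1f Hz",
                   dimnames(tfr$power)[[1]][bad[1]] %||% bad[1],
                   tfr$freqs[bad[2]]))
    }
    tfr$power <- 100 * sweep(sweep(tfr$power, c(1, 2), base, "-"),
                             c(1, 2), base, "/")
  } else {
    base <- apply(tfr$power[, , , bsel, drop = FALSE], c(1, 2, 3), mean)
    if (any(base <= 0)) stop("zero baseline power in a trial")
    tfr$power <- 100 * sweep(sweep(tfr$power, c(1, 2, 3), base, "-"),
                             c(1, 2, 3), base, "/")
  }
  tfr$normalized <- TRUE
  tfr$baseline_window <- baseline
  tfr
}

#' Event-related potential of one condition
#'
#' Band-passes every kept trial (0.3-30 Hz, zero phase), averages across
#' trials, and extracts the largest-magnitude deflection in the 0-800 ms
#' post-onset window.
#'
#' @param tset an `hp_trialset`.
#' @param condition condition label (`NULL` = all kept trials).
#' @param band band-pass corners in Hz.
#' @param peak_window seconds interval searched for the peak.
#' @return an `hp_erp`: `waveform` (channel x time), `time`,
#'   `peak_latency` and `peak_amplitude` per channel, `n_trials`.
#' @export
compute_erp <- function(tset, condition = NULL, band = c(0.3, 30),
                        peak_window = c(0, 0.8)) {
  stopifnot(inherits(tset, "hp_trialset"))
  tset <- kept_trials(tset)
  sel <- if (is.null(condition)) seq_len(dim(tset$data)[1]) else
    which(tset$trials$condition == condition)
  if (length(sel) < 2) stop("need >= 2 kept trials in condition")
  nyq <- tset$fs / 2
  bp <- signal::butter(4, band / nyq, type = "pass")
  n_ch <- dim(tset$data)[2]
  wav <- matrix(0, n_ch, length(tset$time))
  for (j in seq_len(n_ch)) {
    avg <- colMeans(matrix(tset$data[sel, j, ], nrow = length(sel)))
    wav[j, ] <- signal::filtfilt(bp, avg)
  }
  rownames(wav) <- tset$channels$name
  psel <- tset$time >= peak_window[1] & tset$time <= peak_window[2]
  pk_i <- apply(abs(wav[, psel, drop = FALSE]), 1, which.max)
  structure(list(waveform = wav, time = tset$time,
                 peak_latency = tset$time[psel][pk_i],
                 peak_amplitude = wav[cbind(seq_len(n_ch),
                                            which(psel)[pk_i])],
                 n_trials = length(sel)),
            class = "hp_erp")
}

#' Remove the phase-locked (evoked) component from every trial
#'
#' Subtracts each condition's trial-average waveform from its trials, so
#' that subsequent time-frequency decomposition reflects non-phase-locked
#' (induced-only) activity.
#'
#' @param tset an `hp_trialset`.
#' @return the `hp_trialset` with evoked components removed.
#' @export
induced_only <- function(tset) {
  stopifnot(inherits(tset, "hp_trialset"))
  tset <- kept_trials(tset)
  for (cond in unique(tset$trials$condition)) {
    sel <- which(tset$trials$condition == cond)
    for (j in seq_len(dim(tset$data)[2])) {
      m <- matrix(tset$data[sel, j, ], nrow = length(sel))
      tset$data[sel, j, ] <- sweep(m, 2, colMeans(m), "-")
    }
  }
  tset
}

#' Mean power over a frequency-band x time-window rectangle
#'
#' Inclusive on both axes. For a trial-averaged (channel x freq x time)
#' TFR returns one value per channel; for a trial-resolved TFR one value
#' per trial x channel.
#'
#' @param tfr an `hp_tfr` (typically baseline-normalized).
#' @param band Hz interval.
#' @param window seconds interval.
#' @return named numeric vector (channels), or matrix (trial x channel).
#' @export
band_window_average <- function(tfr, band, window) {
  stopifnot(inherits(tfr, "hp_tfr"))
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  tsel <- tfr$time >= window[1] & tfr$time <= window[2]
  if (!any(fsel) || !any(tsel)) stop("empty band/window selection")
  nd <- length(dim(tfr$power))
  if (nd == 3) {
    out <- apply(tfr$power[, fsel, tsel, drop = FALSE], 1, mean)
    names(out) <- dimnames(tfr$power)[[1]] %||% tfr$channels$name
    out
  } else {
    apply(tfr$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
  }
}

#' @export
print.hp_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<hp_tfr> %s, %d freqs (%.0f-%.0f Hz), %d times (%.2f..%.2f s)%s\n",
              paste(d, collapse = " x "), length(x$freqs), min(x$freqs),
              max(x$freqs), length(x$time), min(x$time), max(x$time),
              if (isTRUE(x$normalized)) ", % change" else ""))
  invisible(x)
}
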