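# Shared fixture builders: all synthetic, generated at test time.

# Minimal trial set holding externally supplied per-trial waveforms.
# waves: list of (channel x sample) matrices, or a single matrix recycled.
make_trialset <- function(waves, fs = 250, t0 = -2.5,
                          conditions = NULL, channels = NULL) {
  if (is.matrix(waves)) waves <- list(waves)
  n_tr <- length(waves)
  n_ch <- nrow(waves[[1]])
  n <- ncol(waves[[1]])
  data <- array(0, dim = c(n_tr, n_ch, n))
  for (tr in seq_len(n_tr)) data[tr, , ] <- waves[[tr]]
  ch_names <- channels %||% sprintf("c%d", seq_len(n_ch))
  dimnames(data)[[2]] <- ch_names
  conditions <- conditions %||% rep("neutral", n_tr)
  structure(list(
    data = data,
    time = t0 + (seq_len(n) - 1) / fs,
    fs = fs,
    channels = data.frame(name = ch_names, kind = "lfp_bipolar",
                          hemisphere = "left", group = "lfp",
                          stringsAsFactors = FALSE),
    trials = data.frame(subject_id = "sub01", condition = conditions,
                        onset_s = (seq_len(n_tr) - 1) * 10 + 3,
                        picture_id = seq_len(n_tr), valence = 5, arousal = 5,
                        stringsAsFactors = FALSE),
    kept = rep(TRUE, n_tr), subject_id = "sub01"), class = "hp_trialset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Continuous monopolar recording fixture with explicit per-contact signals.
make_recording <- function(signals, fs = 1000, hemisphere = "left",
                           events = NULL) {
  n_ch <- ncol(signals)
  ch <- data.frame(name = sprintf("%s%d", toupper(substr(hemisphere, 1, 1)),
                                  seq_len(n_ch) - 1),
                   kind = "lfp_monopolar", hemisphere = hemisphere,
                   contact = seq_len(n_ch) - 1L, stringsAsFactors = FALSE)
  colnames(signals) <- ch$name
  structure(list(data = signals, fs = fs, channels = ch,
                 events = events %||% data.frame(onset_s = numeric(0),
                                                 label = character(0),
                                                 picture_id = integer(0))),
            class = "hp_recording")
}

# Synthetic power spectrum from an analytic log10-power curve (plus
# optional Gaussian noise in log10 units), as an hp_spectrum.
make_spectrum <- function(freqs, offset, exponent, peaks = list(),
                          noise_sd = 0) {
  lg <- offset - exponent * log10(freqs)
  for (p in peaks)
    lg <- lg + p$amp * exp(-(freqs - p$cf)^2 / (2 * (p$bw / 2)^2))
  if (noise_sd > 0) lg <- lg + stats::rnorm(length(freqs), 0, noise_sd)
  structure(list(freqs = freqs, power = matrix(10^lg, ncol = 1),
                 fs = NA, segment_s = NA, overlap = NA, n_segments = NA),
            class = "hp_spectrum")
}
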