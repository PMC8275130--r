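# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed, split per stage
#' with a counter so that stages can be re-run independently and still
#' reproduce. Seeds stay below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed.
#' @export
stage_seed <- function(root, counter) {
  as.integer((as.numeric(root) * 48271 + as.numeric(counter) * 10007) %% 2147483587L)
}

# One-sided aperiodic power spectral density 10^(offset - chi*log10(f)),
# clamped below f_floor to avoid unbounded low-frequency power.
aperiodic_psd <- function(f, offset, exponent, f_floor = 0.3) {
  fc <- pmax(f, f_floor)
  out <- 10^(offset - exponent * log10(fc))
  out[f <= 0] <- 0
  out
}

# Gaussian peak contribution in log10-power units. Bandwidth is two standard
# deviations of the Gaussian, so sd = bw / 2.
peak_log10_gain <- function(f, cf, amp, bw) {
  amp * exp(-(f - cf)^2 / (2 * (bw / 2)^2))
}

# Target one-sided PSD: aperiodic plus multiplicative Gaussian peaks
# (peaks specified in log10 power above the aperiodic fit).
target_psd <- function(f, offset, exponent, peaks = list()) {
  lg <- rep(0, length(f))
  for (p in peaks) lg <- lg + peak_log10_gain(f, p$cf, p$amp, p$bw)
  aperiodic_psd(f, offset, exponent) * 10^lg
}

# Synthesize n samples of Gaussian noise whose one-sided PSD (power/Hz)
# follows psd_fun(f), by spectrally shaping white noise. Phase is inherited
# from the white noise, i.e. random; the realization is deterministic under
# the session RNG state.
shaped_noise <- function(n, fs, psd_fun) {
  w <- stats::rnorm(n)
  fr <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(fr, fs - fr)            # two-sided frequency magnitude
  s2 <- psd_fun(f_fold) / 2              # two-sided density
  h <- sqrt(pmax(s2, 0) * fs)
  h[1] <- 0                              # zero-mean output
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
}

# Narrowband Gaussian process whose PSD is the Gaussian-peak excess
# S_ap(f) * (10^G(f) - 1); independent phases => non-phase-locked.
narrowband_noise <- function(n, fs, offset, exponent, cf, amp, bw) {
  shaped_noise(n, fs, function(f) {
    aperiodic_psd(f, offset, exponent) *
      (10^peak_log10_gain(f, cf, amp, bw) - 1)
  })
}

# Truncated normal sampler on [lo, hi] by inverse-CDF; vectorized in n.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Smooth 0..1 band indicator with cosine edges (Hz).
band_shape <- function(f, band, edge = 0.5) {
  w <- numeric(length(f))
  w[f >= band[1] & f <= band[2]] <- 1
  up <- f > band[1] - edge & f < band[1]
  w[up] <- 0.5 * (1 + cos(pi * (band[1] - f[up]) / edge))
  dn <- f > band[2] & f < band[2] + edge
  w[dn] <- 0.5 * (1 + cos(pi * (f[dn] - band[2]) / edge))
  w
}

# Smooth 0..1 window indicator with cosine ramps (seconds), evaluated on a
# time axis. Used to gate oscillatory bursts without spectral splatter.
smooth_window <- function(time, lo, hi, ramp = 0.05) {
  w <- numeric(length(time))
  core <- time >= lo & time <= hi
  w[core] <- 1
  up <- time > (lo - ramp) & time < lo
  w[up] <- 0.5 * (1 + cos(pi * (time[up] - lo) / ramp))
  dn <- time > hi & time < (hi + ramp)
  w[dn] <- 0.5 * (1 + cos(pi * (time[dn] - hi) / ramp))
  w
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
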