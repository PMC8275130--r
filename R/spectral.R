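# Power-spectrum estimation and 1/f + Gaussian-peak parameterization.

#' Frequency band definitions
#'
#' Default bands: theta/alpha 5-10 Hz, theta 4-7 Hz (used only for
#' time-frequency windows, not peak classification), beta 12-30 Hz.
#' Bands used for peak classification must be disjoint.
#'
#' @param bands named list of `c(low, high)` Hz intervals.
#' @return the validated list.
#' @export
band_definitions <- function(bands = list(theta_alpha = c(5, 10),
                                          beta = c(12, 30))) {
  for (b in bands) if (b[1] >= b[2]) stop("band low must be < high")
  nm <- names(bands)
  for (i in seq_along(bands)) for (j in seq_len(i - 1)) {
    if (bands[[i]][1] < bands[[j]][2] && bands[[j]][1] < bands[[i]][2])
      stop("overlapping band definitions: ", nm[i], ", ", nm[j])
  }
  bands
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann-tapered, overlapping segments.
#' The estimate is one-sided power density (signal units squared per Hz):
#' for white noise of variance s^2 sampled at `fs`, the integral over
#' frequency returns approximately s^2 (Parseval).
#'
#' @param x numeric vector, matrix (samples x channels) or `hp_recording`.
#' @param fs sampling rate in Hz (taken from the recording if supplied).
#' @param segment_s segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution).
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @return an `hp_spectrum`: list with `freqs`, `power` (freq x channel
#'   matrix), `fs`, `segment_s`, `overlap`, `n_segments`.
#' @export
welch_psd <- function(x, fs = NULL, segment_s = 2, overlap = 0.5) {
  if (inherits(x, "hp_recording")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop("fs required")
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  nseg <- round(segment_s * fs)
  if (nseg > nrow(x)) stop("segment longer than the recording")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, nrow(x) - nseg + 1L, by = step)
  if (length(starts) < 2) stop("recording must cover at least 2 segments")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))  # Hann
  u <- sum(w^2)
  n_keep <- floor(nseg / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * fs / nseg
  pow <- matrix(0, n_keep, ncol(x))
  for (j in seq_len(ncol(x))) {
    acc <- numeric(n_keep)
    for (s in starts) {
      seg <- x[s:(s + nseg - 1L), j] * w
      sp <- abs(stats::fft(seg))^2
      acc <- acc + sp[seq_len(n_keep)]
    }
    # one-sided density: double all bins except DC and Nyquist
    acc <- acc / (length(starts) * u * fs)
    dbl <- rep(2, n_keep); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[n_keep] <- 1
    pow[, j] <- acc * dbl
  }
  colnames(pow) <- colnames(x)
  structure(list(freqs = freqs, power = pow, fs = fs, segment_s = segment_s,
                 overlap = overlap, n_segments = length(starts)),
            class = "hp_spectrum")
}

gaussian_sum <- function(f, pars) {
  # pars: matrix with columns cf, amp, sd
  y <- numeric(length(f))
  if (!is.null(pars) && nrow(pars))
    for (i in seq_len(nrow(pars)))
      y <- y + pars[i, 2] * exp(-(f - pars[i, 1])^2 / (2 * pars[i, 3]^2))
  y
}

# Robust aperiodic fit of log10 power = b - chi * log10(f): an initial OLS
# fit, then refit on the points whose residual lies below the `quant`
# quantile of positive residuals, which down-weights oscillatory peaks.
fit_aperiodic <- function(logf, logp, quant = 0.025) {
  co <- stats::coef(stats::lm(logp ~ logf))
  res <- logp - (co[1] + co[2] * logf)
  thr <- stats::quantile(res[res >= 0], quant, names = FALSE)
  keep <- res <= thr
  if (sum(keep) >= 5) co <- stats::coef(stats::lm(logp[keep] ~ logf[keep]))
  c(offset = unname(co[1]), exponent = unname(-co[2]))
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Models log10 power over `fit_range` as an aperiodic component
#' `b - chi * log10(f)` plus Gaussian oscillatory peaks, in the spirit of
#' spectral parameterization ("FOOOF-style") algorithms. The procedure:
#' (1) robust aperiodic fit down-weighting points above the fit; (2)
#' iterative peak extraction on the flattened spectrum — the largest
#' residual maximum is retained only while its height exceeds
#' `peak_threshold` times the SD of the flattened residual, then a Gaussian
#' is fitted and subtracted, up to `max_n_peaks` times; (3) joint nonlinear
#' refinement of all Gaussians; (4) aperiodic refit on the peak-removed
#' spectrum. Peaks whose centers are closer than half the smaller bandwidth
#' are merged. Reported peak bandwidth is two standard deviations of the
#' fitted Gaussian; amplitude is the height above the aperiodic fit in
#' log10-power units.
#'
#' @param psd an `hp_spectrum` (single channel, or use `channel`).
#' @param channel column index/name when the spectrum holds several.
#' @param fit_range Hz interval to fit (default `c(2, 40)`).
#' @param max_n_peaks maximum number of retained peaks (default 4).
#' @param peak_width_limits allowed bandwidth range in Hz (default
#'   `c(1, 15)`).
#' @param peak_threshold detection threshold in SD of the flattened
#'   residual (default 2).
#' @return an `hp_specfit`: list with `aperiodic` (offset, exponent),
#'   `peaks` (data.frame `cf, amp, bw`), `r_squared`, `fit_range`,
#'   `settings`, `converged`.
#' @export
fit_spectral_model <- function(psd, channel = 1, fit_range = c(2, 40),
                               max_n_peaks = 4, peak_width_limits = c(1, 15),
                               peak_threshold = 2) {
  stopifnot(inherits(psd, "hp_spectrum"))
  pw <- psd$power[, channel]
  sel <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2]
  if (sum(sel) < 20) stop("fit_range must be covered by >= 20 frequency points")
  f <- psd$freqs[sel]; p <- pw[sel]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("power spectrum must be finite and positive over the fit range")
  logf <- log10(f); logp <- log10(p)
  sd_lim <- peak_width_limits / 2

  ap <- fit_aperiodic(logf, logp)
  flat <- logp - (ap["offset"] - ap["exponent"] * logf)

  # iterative peak extraction
  pars <- NULL
  resid <- flat
  for (k in seq_len(max_n_peaks)) {
    i0 <- which.max(resid)
    h <- resid[i0]
    if (!is.finite(h) || h <= peak_threshold * stats::sd(resid)) break
    # half-height width estimate for the sd seed
    half <- h / 2
    li <- i0; while (li > 1 && resid[li] > half) li <- li - 1
    ri <- i0; while (ri < length(f) && resid[ri] > half) ri <- ri + 1
    fwhm <- max(f[ri] - f[li], diff(f[1:2]))
    sd0 <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    pars <- rbind(pars, c(f[i0], h, sd0))
    resid <- resid - gaussian_sum(f, pars[nrow(pars), , drop = FALSE])
  }

  converged <- TRUE
  if (!is.null(pars)) {
    # joint Gaussian refinement on the flattened spectrum
    start <- as.numeric(t(pars))
    lower <- rep(c(fit_range[1], 0, sd_lim[1]), nrow(pars))
    upper <- rep(c(fit_range[2], Inf, sd_lim[2]), nrow(pars))
    model_fun <- function(par) {
      m <- matrix(par, ncol = 3, byrow = TRUE)
      gaussian_sum(f, m)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(par) flat - model_fun(par),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      converged <- FALSE
      pars <- NULL
    } else {
      pars <- matrix(fit$par, ncol = 3, byrow = TRUE)
      # drop peaks that fell below threshold or hit zero amplitude
      keep <- pars[, 2] > 0 & pars[, 1] >= fit_range[1] & pars[, 1] <= fit_range[2]
      pars <- pars[keep, , drop = FALSE]
      if (!nrow(pars)) pars <- NULL
    }
  }

  # merge near-duplicate peaks (centers closer than half the smaller bw)
  if (!is.null(pars) && nrow(pars) > 1) {
    ord <- order(-pars[, 2])
    pars <- pars[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pars))
    for (i in seq_len(nrow(pars))) for (j in seq_len(i - 1)) {
      if (keep[i] && keep[j] &&
          abs(pars[i, 1] - pars[j, 1]) < min(pars[i, 3], pars[j, 3]))
        keep[i] <- FALSE
    }
    pars <- pars[keep, , drop = FALSE]
  }

  # aperiodic refit on the peak-removed spectrum
  peak_part <- gaussian_sum(f, pars)
  co <- stats::coef(stats::lm(I(logp - peak_part) ~ logf))
  ap <- c(offset = unname(co[1]), exponent = unname(-co[2]))

  model <- ap["offset"] - ap["exponent"] * logf + peak_part
  r2 <- 1 - sum((logp - model)^2) / sum((logp - mean(logp))^2)

  peaks <- if (is.null(pars) || !nrow(pars)) {
    data.frame(cf = numeric(0), amp = numeric(0), bw = numeric(0))
  } else {
    ord <- order(pars[, 1])
    data.frame(cf = pars[ord, 1], amp = pars[ord, 2], bw = 2 * pars[ord, 3])
  }
  structure(list(aperiodic = ap, peaks = peaks,
                 r_squared = max(0, min(1, r2)), fit_range = fit_range,
                 settings = list(max_n_peaks = max_n_peaks,
                                 peak_width_limits = peak_width_limits,
                                 peak_threshold = peak_threshold),
                 converged = converged),
            class = "hp_specfit")
}

#' Assign fitted peaks to frequency bands
#'
#' A peak belongs to a band iff its center frequency lies inside the band
#' (inclusive); peaks falling in no band are reported as `"unclassified"`.
#' Band definitions must be disjoint.
#'
#' @param fit an `hp_specfit`.
#' @param bands a [band_definitions()] list.
#' @return the peak data.frame with an added `band` column.
#' @export
classify_peaks <- function(fit, bands = band_definitions()) {
  stopifnot(inherits(fit, "hp_specfit"))
  bands <- band_definitions(bands)
  pk <- fit$peaks
  pk$band <- "unclassified"
  for (nm in names(bands)) {
    b <- bands[[nm]]
    pk$band[pk$cf >= b[1] & pk$cf <= b[2]] <- nm
  }
  pk
}

#' @export
print.hp_specfit <- function(x, ...) {
  cat(sprintf("<hp_specfit> offset=%.3f exponent=%.3f R2=%.3f, %d peak(s)\n",
              x$aperiodic["offset"], x$aperiodic["exponent"], x$r_squared,
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(round(x$peaks, 2))
  invisible(x)
}

#' Serialize spectral fits to a per-peak table
#'
#' One row per channel-peak, mirroring a "resting oscillation peaks"
#' summary table; channels with no retained peak get a single row with NA
#' peak fields.
#'
#' @param fits named list of `hp_specfit` (names = channels).
#' @return data.frame `channel, cf, amp, bw, band, offset, exponent,
#'   r_squared`.
#' @export
specfit_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    pk <- classify_peaks(ft)
    if (!nrow(pk))
      pk <- data.frame(cf = NA_real_, amp = NA_real_, bw = NA_real_,
                       band = "none")
    cbind(data.frame(channel = nm), pk,
          data.frame(offset = ft$aperiodic[["offset"]],
                     exponent = ft$aperiodic[["exponent"]],
                     r_squared = ft$r_squared))
  }))
}
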