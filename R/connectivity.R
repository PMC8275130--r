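# Cross-trial time-resolved coherence between an LFP reference and sensors.

#' Cross-trial time-resolved coherence
#'
#' For each (frequency, time) point, coherence across the trial ensemble
#' between a reference channel and one or more target channels:
#' `coh(f, t) = |sum_k X_k conj(Y_k)| / sqrt(sum_k |X_k|^2 sum_k |Y_k|^2)`.
#' The magnitude (not its square) is returned, in `[0, 1]`. Both inputs
#' must come from the same trials, time axis and frequency grid; pass the
#' same `hp_tfr` (computed with `keep_complex = TRUE`) holding both
#' channels, or two TFRs from the same trial set.
#'
#' @param tfr an `hp_tfr` with complex spectra (`keep_complex = TRUE`).
#' @param ref reference channel name.
#' @param targets target channel names (default: all others).
#' @param squared return squared coherence instead of magnitude.
#' @return an `hp_coh`: `coherence` array (pair x freq x time) in `[0,1]`,
#'   `pairs` data.frame, `freqs`, `time`, `n_trials`, `normalized = FALSE`.
#' @export
cross_trial_coherence <- function(tfr, ref, targets = NULL, squared = FALSE) {
  stopifnot(inherits(tfr, "hp_tfr"))
  if (is.null(tfr$fourier)) stop("TFR lacks complex spectra; use keep_complex = TRUE")
  chn <- tfr$channels$name
  if (!(ref %in% chn)) stop("unknown reference channel: ", ref)
  targets <- targets %||% setdiff(chn, ref)
  bad <- setdiff(targets, chn)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  n_tr <- dim(tfr$fourier)[1]
  if (n_tr < 2) stop("coherence needs >= 2 trials")
  ir <- match(ref, chn)
  X <- tfr$fourier[, ir, , , drop = FALSE]
  dim(X) <- dim(tfr$fourier)[c(1, 3, 4)]
  ax <- apply(abs(X)^2, c(2, 3), sum)
  coh <- array(NA_real_, dim = c(length(targets), dim(X)[2], dim(X)[3]),
               dimnames = list(targets, NULL, NULL))
  for (k in seq_along(targets)) {
    Y <- tfr$fourier[, match(targets[k], chn), , , drop = FALSE]
    dim(Y) <- dim(X)
    cross <- apply(X * Conj(Y), c(2, 3), sum)
    ay <- apply(abs(Y)^2, c(2, 3), sum)
    cval <- Mod(cross) / sqrt(ax * ay)
    coh[k, , ] <- if (squared) cval^2 else cval
  }
  stopifnot(all(coh >= 0 - 1e-12), all(coh <= 1 + 1e-9))
  coh <- pmin(pmax(coh, 0), 1)
  dim(coh) <- c(length(targets), dim(X)[2], dim(X)[3])
  dimnames(coh)[[1]] <- targets
  structure(list(coherence = coh,
                 pairs = data.frame(ref = ref, target = targets),
                 freqs = tfr$freqs, time = tfr$time, n_trials = n_tr,
                 squared = squared, normalized = FALSE),
            class = "hp_coh")
}

#' Coherence as percent change from the pre-stimulus baseline
#'
#' `100 * (coh(f, t) - cbase(f)) / cbase(f)` per pair and frequency, with
#' `cbase(f)` the mean coherence over the baseline window.
#'
#' @param panel an `hp_coh`.
#' @param baseline numeric length-2 window in seconds (default
#'   `c(-2, -0.2)`).
#' @return the normalized `hp_coh` (percent change).
#' @export
coherence_baseline_change <- function(panel, baseline = c(-2, -0.2)) {
  stopifnot(inherits(panel, "hp_coh"))
  if (isTRUE(panel$normalized)) stop("panel is already baseline-normalized")
  bsel <- panel$time >= baseline[1] & panel$time <= baseline[2]
  if (!any(bsel)) stop("baseline window outside the time axis")
  base <- apply(panel$coherence[, , bsel, drop = FALSE], c(1, 2), mean)
  if (any(base <= 0)) stop("zero baseline coherence for some pair/frequency")
  panel$coherence <- 100 * sweep(sweep(panel$coherence, c(1, 2), base, "-"),
                                 c(1, 2), base, "/")
  panel$normalized <- TRUE
  panel$baseline_window <- baseline
  panel
}

#' Average a coherence panel over a sensor group
#'
#' @param panel an `hp_coh`.
#' @param sensors character vector of target-sensor names to average.
#' @return matrix (freq x time), the arithmetic mean over the selected
#'   pairs.
#' @export
coherence_group_average <- function(panel, sensors) {
  stopifnot(inherits(panel, "hp_coh"))
  if (!length(sensors)) stop("empty sensor selector")
  bad <- setdiff(sensors, panel$pairs$target)
  if (length(bad)) stop("unknown sensor names: ", paste(bad, collapse = ", "))
  sel <- match(sensors, panel$pairs$target)
  unname(apply(panel$coherence[sel, , , drop = FALSE], c(2, 3), mean))
}

#' Equalize trial counts across conditions by random subsampling
#'
#' Coherence bias depends on the number of trials, so conditions compared
#' on coherence are subsampled to their common minimum with a fixed seed.
#'
#' @param tset an `hp_trialset`.
#' @param seed integer seed for the subsample.
#' @return the `hp_trialset` with per-condition trial counts equalized
#'   (via the kept mask).
#' @export
equalize_trial_counts <- function(tset, seed = 1L) {
  stopifnot(inherits(tset, "hp_trialset"))
  kept <- tset$kept
  tab <- table(tset$trials$condition[kept])
  n_min <- min(tab)
  set.seed(stage_seed(seed, 7L))
  for (cond in names(tab)) {
    idx <- which(kept & tset$trials$condition == cond)
    if (length(idx) > n_min)
      kept[sample(idx, length(idx) - n_min)] <- FALSE
  }
  tset$kept <- kept
  tset
}

#' @export
print.hp_coh <- function(x, ...) {
  cat(sprintf("<hp_coh> %d pair(s) x %d freqs x %d times, n_trials=%d%s\n",
              nrow(x$pairs), length(x$freqs), length(x$time), x$n_trials,
              if (isTRUE(x$normalized)) ", % change" else ""))
  invisible(x)
}
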