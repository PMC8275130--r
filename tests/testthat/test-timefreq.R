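test_that("Morlet TFR matches the direct-convolution oracle on a tone", {
  fs <- 250
  time <- seq(-2.5, 4.5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * time)
  ts <- make_trialset(matrix(x, 1), conditions = "neutral")
  tfr <- morlet_tfr(ts, freqs = c(6, 10, 20), n_cycles = 6)

  interior <- which(tfr$time > -1 & tfr$time < 3)
  probe <- interior[seq(1, length(interior), length.out = 25)]
  full_idx <- match(round(tfr$time[probe] * fs), round(time * fs))
  for (k in 1:3) {
    ora <- oracle_wavelet_power(x, fs, c(6, 10, 20)[k], 6, full_idx)
    expect_equal(tfr$power[1, 1, k, probe], ora, tolerance = 1e-6)
  }

  # ridge at the 10 Hz row, near-constant over the trial interior
  ridge <- apply(tfr$power[1, 1, , interior], 1, mean)
  expect_equal(which.max(ridge), 2L)
  p10 <- tfr$power[1, 1, 2, interior]
  expect_lt(diff(range(p10)) / mean(p10), 0.01)
  expect_equal(mean(p10), 1, tolerance = 0.01)
})

test_that("wavelet temporal SD follows n_cycles / (2 pi f)", {
  for (f in c(4, 6, 10)) {
    ker <- habpipe:::morlet_kernel(f, 1000, 6)
    tt <- (seq_along(ker) - (length(ker) + 1) / 2) / 1000
    g <- Mod(ker)
    sd_emp <- sqrt(sum(tt^2 * g) / sum(g))
    expect_equal(sd_emp, 6 / (2 * pi * f), tolerance = 0.01)
  }
  expect_equal(6 / (2 * pi * 6), 0.159, tolerance = 0.01)
})

test_that("zero input produces zero power and frequencies are validated", {
  ts <- make_trialset(matrix(0, 1, 1750))
  tfr <- morlet_tfr(ts, freqs = c(5, 10))
  expect_true(all(tfr$power == 0))
  expect_error(morlet_tfr(ts, freqs = c(0.05, 10)), "trial-length")
})

test_that("baseline normalization is exact percent change", {
  # constant power everywhere -> 0%; doubled power in a window -> +100%
  fs <- 250
  time <- seq(-2.5, 4.5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * time)
  x[time >= 1 & time < 2] <- sqrt(2) * x[time >= 1 & time < 2]
  ts <- make_trialset(list(matrix(x, 1), matrix(x, 1)))
  tfr <- morlet_tfr(ts, freqs = 10)
  nrm <- baseline_normalize(tfr, baseline = c(-2, -0.2))
  expect_true(nrm$normalized)
  expect_true(all(nrm$power >= -100))
  inside <- nrm$time > 1.2 & nrm$time < 1.8
  outside <- nrm$time > -1.5 & nrm$time < -0.5
  expect_equal(mean(nrm$power[1, 1, inside]), 100, tolerance = 1)
  expect_equal(mean(nrm$power[1, 1, outside]), 0, tolerance = 1)
  # self-consistency: baseline-window mean of the normalized map is ~0
  bsel <- nrm$time >= -2 & nrm$time <= -0.2
  expect_lt(abs(mean(nrm$power[1, 1, bsel])), 1e-8)

  expect_error(baseline_normalize(nrm), "already")
  expect_error(baseline_normalize(tfr, baseline = c(-10, -9)), "outside")
})

test_that("ERP extraction recovers deterministic waveforms and latencies", {
  fs <- 250
  time <- seq(-2.5, 4.5 - 1 / fs, by = 1 / fs)
  kern <- 2 * exp(-(time - 0.3)^2 / (2 * 0.05^2)) * cos(2 * pi * 8 * (time - 0.3))

  # identical trials: ERP equals the (band-passed) waveform, peak at 300 ms
  ts <- make_trialset(replicate(6, matrix(kern, 1), simplify = FALSE))
  erp <- compute_erp(ts, "neutral")
  expect_equal(erp$n_trials, 6)
  expect_equal(erp$peak_latency[1], 0.3, tolerance = 0.008)
  expect_gt(erp$peak_amplitude[1], 1.5)

  # random-phase sinusoids cancel: ERP RMS below 3x the SEM
  set.seed(17)
  waves <- lapply(1:200, function(i)
    matrix(sin(2 * pi * 8 * time + runif(1, 0, 2 * pi)), 1))
  tsr <- make_trialset(waves)
  erpr <- compute_erp(tsr, "neutral")
  sem <- sqrt(0.5 / 200)
  expect_lt(sqrt(mean(erpr$waveform^2)), 3 * sem)

  expect_error(compute_erp(ts, "positive"), ">= 2")
})

test_that("induced-only removes evoked and spares non-phase-locked power", {
  fs <- 250
  time <- seq(-2.5, 4.5 - 1 / fs, by = 1 / fs)

  # purely evoked data: identical trials -> induced TFR ~ 0
  kern <- exp(-(time - 0.3)^2 / (2 * 0.05^2)) * cos(2 * pi * 8 * time)
  tse <- make_trialset(replicate(5, matrix(kern, 1), simplify = FALSE))
  ind <- induced_only(tse)
  expect_lt(max(abs(ind$data)), 1e-12)

  # purely induced: random-phase trials change by < 5% in mean power
  set.seed(18)
  waves <- lapply(1:60, function(i)
    matrix(sin(2 * pi * 8 * time + runif(1, 0, 2 * pi)), 1))
  tsi <- make_trialset(waves)
  tfr_before <- morlet_tfr(tsi, freqs = 8)
  tfr_after <- morlet_tfr(induced_only(tsi), freqs = 8)
  expect_equal(mean(tfr_after$power), mean(tfr_before$power),
               tolerance = 0.05)

  # mixed data: induced power no larger than total power on average
  waves_m <- lapply(1:40, function(i)
    matrix(kern + sin(2 * pi * 12 * time + runif(1, 0, 2 * pi)), 1))
  tsm <- make_trialset(waves_m)
  p_tot <- mean(morlet_tfr(tsm, freqs = c(8, 12))$power)
  p_ind <- mean(morlet_tfr(induced_only(tsm), freqs = c(8, 12))$power)
  expect_lte(p_ind, p_tot * 1.001)
})

test_that("band/window averaging is plain arithmetic over the rectangle", {
  tfr <- structure(list(
    power = array(0, dim = c(1, 3, 10),
                  dimnames = list("c1", NULL, NULL)),
    freqs = c(5, 7, 9), time = seq(0, 0.9, by = 0.1),
    channels = data.frame(name = "c1"), normalized = TRUE),
    class = "hp_tfr")
  tfr$power[1, , 1:5] <- 100
  expect_equal(unname(band_window_average(tfr, c(5, 9), c(0, 0.4))["c1"]), 100)
  expect_equal(unname(band_window_average(tfr, c(5, 9), c(0, 0.9))), 50)
  expect_error(band_window_average(tfr, c(20, 30), c(0, 0.4)), "empty")
})

test_that("time-averaged wavelet power tracks the Welch spectrum", {
  set.seed(19)
  fs <- 250
  x <- habpipe:::shaped_noise(fs * 30, fs,
                              function(f) habpipe:::aperiodic_psd(f, 1, 1))
  ts <- make_trialset(matrix(x[1:(7 * fs)], 1))
  tfr <- morlet_tfr(ts, freqs = 2:40)
  wav <- apply(tfr$power[1, 1, , ], 1, mean)
  ps <- welch_psd(x, fs)
  welch_at <- approx(ps$freqs, ps$power[, 1], xout = 2:40)$y
  # the tone-normalized wavelet's equivalent noise bandwidth grows
  # linearly with frequency, so power density is wav / f up to a constant
  expect_gt(cor(log10(wav / 2:40), log10(welch_at)), 0.95)
})
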