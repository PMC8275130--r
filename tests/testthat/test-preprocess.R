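test_that("bipolar referencing removes common-mode and differences neighbors", {
  n <- 1000
  t_ax <- (seq_len(n) - 1) / 1000
  common <- sin(2 * pi * 50 * t_ax) + 3

  # identical signal on all contacts -> exactly zero bipolar channels
  rec <- make_recording(matrix(common, n, 4))
  bp <- bipolar_reference(rec)
  expect_equal(ncol(bp$data), 3)
  expect_true(all(bp$data == 0))
  expect_equal(bp$channels$kind, rep("lfp_bipolar", 3))

  # sinusoid on contact 0 only: bipolar(0-1) carries it, bipolar(1-2) silent
  s <- sin(2 * pi * 10 * t_ax)
  rec2 <- make_recording(cbind(s, 0, 0, 0))
  bp2 <- bipolar_reference(rec2)
  expect_equal(bp2$data[, 1], s)
  expect_true(all(bp2$data[, 2] == 0))

  # independent white-noise contacts: bipolar variance ~ 2 sigma^2
  set.seed(11)
  sigma <- 1.5
  rec3 <- make_recording(matrix(rnorm(4 * 50000, sd = sigma), ncol = 4))
  bp3 <- bipolar_reference(rec3)
  expect_equal(mean(apply(bp3$data, 2, var)), 2 * sigma^2, tolerance = 0.05)

  expect_error(bipolar_reference(make_recording(matrix(rnorm(100), ncol = 1))),
               "single contact")
})

test_that("filter chain hits its design targets", {
  fs <- 1000
  n <- fs * 10
  t_ax <- (seq_len(n) - 1) / fs
  interior <- seq(2 * 250, 8 * 250)   # away from filtfilt edge transients

  # 50 Hz attenuated by >= 40 dB
  rec50 <- make_recording(matrix(sin(2 * pi * 50 * t_ax), ncol = 1))
  out50 <- filter_chain(rec50)
  expect_equal(out50$fs, 250)
  rms_in <- sqrt(mean(sin(2 * pi * 50 * t_ax)^2))
  rms_out <- sqrt(mean(out50$data[interior, 1]^2))
  expect_gt(20 * log10(rms_in / rms_out), 40)

  # 10 Hz passes within 5% amplitude and with zero phase shift
  rec10 <- make_recording(matrix(sin(2 * pi * 10 * t_ax), ncol = 1))
  out10 <- filter_chain(rec10)
  dec_t <- t_ax[seq(1, n, by = 4)]
  ref <- sin(2 * pi * 10 * dec_t)
  amp <- max(abs(out10$data[interior, 1]))
  expect_equal(amp, 1, tolerance = 0.05)
  # zero-lag cross-correlation is maximal (no group delay at band center)
  cc <- sapply(-3:3, function(k)
    cor(out10$data[interior, 1], ref[interior + k]))
  expect_equal(which.max(cc), 4L)

  # DC offset removed by the high-pass
  recdc <- make_recording(matrix(1, n, 1))
  outdc <- filter_chain(recdc)
  expect_lt(abs(mean(outdc$data[interior, 1])), 0.01)
})

test_that("filter chain is linear and idempotent in its passband", {
  fs <- 1000
  set.seed(12)
  x <- matrix(rnorm(fs * 8), ncol = 1)
  rec <- make_recording(x)
  out1 <- filter_chain(rec)
  out_scaled <- filter_chain(make_recording(3.7 * x))
  # linear to the numerical accuracy of the filtering routine
  expect_lt(max(abs(out_scaled$data - 3.7 * out1$data)) /
              max(abs(out1$data)), 1e-4)

  # a passband tone survives a second pass within 1%
  t_ax <- (seq_len(fs * 8) - 1) / fs
  tone <- make_recording(matrix(sin(2 * pi * 15 * t_ax), ncol = 1))
  once <- filter_chain(tone)
  twice <- filter_chain(structure(list(data = once$data, fs = 250,
                                       channels = once$channels,
                                       events = once$events),
                                  class = "hp_recording"), fs_out = 250,
                        lp_hz = 100, notch_hz = NULL)
  interior <- seq(250, 1750)
  expect_equal(max(abs(twice$data[interior, 1])),
               max(abs(once$data[interior, 1])), tolerance = 0.01)
})

test_that("epoching cuts complete windows and keeps metadata", {
  fs <- 250
  n <- fs * 300
  set.seed(13)
  ev <- data.frame(onset_s = seq(10, 290, by = 9.5)[1:30],
                   label = rep(c("neutral", "positive", "negative"), 10),
                   picture_id = 1:30)
  rec <- structure(list(data = matrix(rnorm(n * 2), ncol = 2,
                                      dimnames = list(NULL, c("a", "b"))),
                        fs = fs,
                        channels = data.frame(name = c("a", "b"),
                                              kind = "lfp_bipolar",
                                              hemisphere = "left",
                                              contact = NA),
                        events = ev), class = "hp_recording")
  ts <- epoch_trials(rec, window = c(-2.5, 4.5))
  expect_equal(dim(ts$data)[1], 30)
  expect_equal(dim(ts$data)[3], 1750)          # 7 s at 250 Hz
  expect_equal(as.vector(table(ts$trials$condition)), rep(10L, 3))
  # sample values preserved exactly
  k <- round((ev$onset_s[3] - 2.5) * fs) + 1
  expect_identical(ts$data[3, 1, 1], rec$data[k, 1])

  # early event dropped
  ev2 <- rbind(data.frame(onset_s = 1, label = "neutral", picture_id = 0), ev)
  rec$events <- ev2
  expect_message(ts2 <- epoch_trials(rec), "dropped")
  expect_equal(dim(ts2$data)[1], 30)
})

test_that("artifact rejection masks overlapping trials and guards the floor", {
  waves <- replicate(9, matrix(rnorm(2 * 500), 2, 500), simplify = FALSE)
  ts <- make_trialset(waves, conditions = rep(c("neutral", "positive",
                                                "negative"), 3))
  # trial onsets at 3, 13, 23, ... epoch spans onset + [-2.5, -0.5)
  none <- reject_artifacts(ts, list())
  expect_true(all(none$kept))

  one <- reject_artifacts(ts, list(c(21, 22)))   # covers trial 3 only
  expect_equal(which(!one$kept), 3L)

  # removing too many trials of one condition errors
  expect_error(reject_artifacts(ts, list(c(0, 60))), "fewer than 2")

  # amplitude auto-marker catches an injected glitch
  waves[[5]][1, 100] <- 100
  ts2 <- make_trialset(waves, conditions = rep(c("neutral", "positive",
                                                 "negative"), 3))
  auto <- reject_artifacts(ts2, z_thresh = 8)
  expect_false(auto$kept[5])
  expect_equal(sum(auto$kept), 8)
})

test_that("epoched data round-trips through the text serialization", {
  waves <- replicate(3, matrix(rnorm(2 * 100), 2, 100), simplify = FALSE)
  ts <- make_trialset(waves)
  dir <- file.path(tempdir(), "tset_io")
  write_trialset(ts, dir)
  back <- read_trialset(dir)
  expect_equal(back$data, ts$data, tolerance = 1e-12)
  expect_equal(back$time, ts$time, tolerance = 1e-12)
  expect_equal(back$trials$condition, ts$trials$condition)
  unlink(dir, recursive = TRUE)
})
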