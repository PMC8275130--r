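# Helpers to build complex TFRs from explicit linear mixing of sources.
mix_tfr <- function(gain, src, noise_sd = 0, ref = NULL, ref_noise = 0) {
  # gain: sensor x source; src: list over trials of (source x sample) cplx
  n_tr <- length(src)
  ns <- nrow(gain)
  nf <- 1; nt <- ncol(src[[1]])
  has_ref <- !is.null(ref)
  four <- array(0i, dim = c(n_tr, ns + has_ref, nf, nt))
  for (tr in seq_len(n_tr)) {
    sens <- gain %*% src[[tr]]
    if (noise_sd > 0)
      sens <- sens + noise_sd *
        matrix(complex(real = rnorm(ns * nt), imaginary = rnorm(ns * nt)), ns)
    four[tr, seq_len(ns) + has_ref, 1, ] <- sens
    if (has_ref)
      four[tr, 1, 1, ] <- ref[[tr]] + ref_noise *
        complex(real = rnorm(nt), imaginary = rnorm(nt))
  }
  nm <- c(if (has_ref) "ref", sprintf("S%02d", seq_len(ns)))
  structure(list(fourier = four, power = abs(four)^2, freqs = 7,
                 time = seq(0.1, 0.5, length.out = nt),
                 channels = data.frame(name = nm,
                                       kind = c(if (has_ref) "lfp_bipolar",
                                                rep("meg_like", ns)),
                                       stringsAsFactors = FALSE),
                 trials = data.frame(condition = rep("x", n_tr)),
                 fs = 250, n_cycles = 6), class = "hp_tfr")
}

rand_src <- function(k, nt) matrix(complex(real = rnorm(k * nt),
                                           imaginary = rnorm(k * nt)), k)

test_that("band CSD is Hermitian and rank-1 for a single mixed source", {
  set.seed(33)
  lf <- make_leadfield(16, c(3, 3, 3), 5, seed = 1)
  g <- lf$gain[, 10, drop = FALSE]
  src <- replicate(20, rand_src(1, 30), simplify = FALSE)
  tfr <- mix_tfr(g, src)
  csd <- band_csd(tfr, c(5, 10), c(0, 1))
  expect_equal(max(abs(csd$csd - Conj(t(csd$csd)))), 0, tolerance = 1e-12)
  expect_true(all(Re(diag(csd$csd)) >= 0))
  ev <- eigen(csd$csd, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / max(ev[2], 1e-300), 1e6)   # effectively rank 1
  # csd proportional to g g^T
  expect_gt(abs(cor(as.vector(Re(csd$csd)), as.vector(g %*% t(g)))), 0.999)

  # independent sensor noise: off-diagonals small relative to diagonal
  tfr_n <- mix_tfr(matrix(0, 16, 1), replicate(40, rand_src(1, 30),
                                               simplify = FALSE),
                   noise_sd = 1)
  csd_n <- band_csd(tfr_n, c(5, 10), c(0, 1))
  off <- abs(csd_n$csd[upper.tri(csd_n$csd)])
  expect_lt(max(off) / mean(Re(diag(csd_n$csd))), 3 / sqrt(40))
})

test_that("DICS filters satisfy the unit-gain identity", {
  set.seed(34)
  lf <- make_leadfield(20, c(3, 3, 3), 5, seed = 2)
  src <- replicate(15, rand_src(27, 25), simplify = FALSE)
  tfr <- mix_tfr(lf$gain, src, noise_sd = 0.2)
  csd <- band_csd(tfr, c(5, 10), c(0, 1))
  W <- dics_filters(lf, csd)
  unit <- vapply(seq_len(27), function(j) sum(W[j, ] * lf$gain[, j]), 0)
  expect_lt(max(abs(unit - 1)), 1e-10)
})

test_that("single and double sources are localized on the grid", {
  set.seed(35)
  lf <- make_leadfield(24, c(3, 3, 3), 5, seed = 6)
  k <- 14
  src <- replicate(25, rand_src(1, 30), simplify = FALSE)
  tfr <- mix_tfr(lf$gain[, k, drop = FALSE], src, noise_sd = 0.1)
  csd <- band_csd(tfr, c(5, 10), c(0, 1))
  W <- dics_filters(lf, csd)
  pm <- dics_power(W, csd, lf)
  expect_equal(pm$peak_node, k)

  # two incoherent sources: both local maxima within one grid node
  k2 <- c(3, 25)
  src2 <- replicate(40, rand_src(2, 30), simplify = FALSE)
  tfr2 <- mix_tfr(lf$gain[, k2], src2, noise_sd = 0.05)
  csd2 <- band_csd(tfr2, c(5, 10), c(0, 1))
  pm2 <- dics_power(dics_filters(lf, csd2), csd2, lf)
  top <- order(pm2$values, decreasing = TRUE)[1:4]
  d_true <- as.matrix(dist(lf$node_positions))
  for (kk in k2)
    expect_lte(min(d_true[kk, top]), lf$grid_spacing)
})

test_that("coherence maps peak at the reference-coupled node", {
  set.seed(36)
  lf <- make_leadfield(24, c(3, 3, 3), 5, seed = 8)
  k <- 20
  src <- replicate(30, rand_src(1, 40), simplify = FALSE)
  tfr <- mix_tfr(lf$gain[, k, drop = FALSE], src, noise_sd = 0.05,
                 ref = lapply(src, function(s) s[1, ]), ref_noise = 0.05)
  csd <- band_csd(tfr, c(5, 10), c(0, 1), ref = "ref")
  cm <- dics_coherence_map(lf, csd)
  expect_equal(cm$peak_node, k)
  expect_gt(cm$peak_value, 0.9)
  expect_true(all(cm$values[!cm$invalid] <= 1 + 1e-9))

  # reference independent of all sources: map sits near the bias level
  tfr_i <- mix_tfr(lf$gain[, k, drop = FALSE], src, noise_sd = 0.05,
                   ref = replicate(30, rand_src(1, 40)[1, ],
                                   simplify = FALSE))
  csd_i <- band_csd(tfr_i, c(5, 10), c(0, 1), ref = "ref")
  cm_i <- dics_coherence_map(lf, csd_i)
  n_samp <- csd_i$n_averaged
  expect_lt(mean(cm_i$values^2, na.rm = TRUE), 5 / n_samp)
})

test_that("coherence maps are invariant to lead-field column scaling", {
  set.seed(37)
  lf <- make_leadfield(16, c(3, 3, 3), 5, seed = 10, normalize = FALSE)
  k <- 5
  src <- replicate(20, rand_src(1, 30), simplify = FALSE)
  tfr <- mix_tfr(lf$gain[, k, drop = FALSE], src, noise_sd = 0.1,
                 ref = lapply(src, function(s) s[1, ]))
  csd <- band_csd(tfr, c(5, 10), c(0, 1), ref = "ref")
  cm1 <- dics_coherence_map(lf, csd)
  W1 <- dics_filters(lf, csd)
  p1 <- Re(diag(W1 %*% csd$csd %*% Conj(t(W1))))

  lf2 <- lf
  cvec <- rep(1, 27); cvec[k] <- 4
  lf2$gain <- sweep(lf$gain, 2, cvec, "*")
  cm2 <- dics_coherence_map(lf2, csd)
  W2 <- dics_filters(lf2, csd)
  p2 <- Re(diag(W2 %*% csd$csd %*% Conj(t(W2))))
  expect_equal(cm2$values, cm1$values, tolerance = 1e-9)
  expect_equal(p2[k], p1[k] / 16, tolerance = 1e-9)   # power scales as 1/c^2
})

test_that("source power contrasts flag injected condition differences", {
  set.seed(38)
  lf <- make_leadfield(16, c(3, 3, 3), 5, seed = 12)
  n_subj <- 8
  base <- matrix(rnorm(n_subj * 27, 10, 1), n_subj, 27)
  eff <- base
  eff[, 14] <- eff[, 14] + 4        # one active node
  res <- source_power_contrast(eff, base, lf, n_perm = 500, tail = "pos")
  expect_equal(res$peak_node, 14)
  sig <- significant_clusters(res$cluster)
  expect_gte(length(sig), 1)
  expect_true(any(vapply(sig, function(cl) 14 %in% cl$members, TRUE)))
  expect_true(all(res$p_uncorrected >= 0 & res$p_uncorrected <= 1))

  # identical conditions: nothing significant
  res0 <- source_power_contrast(base, base + 0, lf, n_perm = 200)
  expect_equal(length(significant_clusters(res0$cluster)), 0)

  # constant shift at all nodes: one all-node cluster
  resc <- source_power_contrast(base + 3, base, lf, n_perm = 200,
                                tail = "pos")
  sigc <- significant_clusters(resc$cluster)
  expect_equal(length(sigc), 1)
  expect_equal(length(sigc[[1]]$members), 27)
  expect_gt(sigc[[1]]$mass, 0)
})
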