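# Independent brute-force oracle for the cluster permutation test:
# enumerates every sign assignment, computes per-bin t -> z, labels
# clusters by its own recursive flood fill on the explicit grid, and
# accumulates the max-|mass| null.
oracle_tf_cluster <- function(a, b, alpha = 0.05) {
  n <- dim(a)[1]; nf <- dim(a)[2]; nt <- dim(a)[3]
  D <- matrix(a - b, nrow = n)
  thr <- qnorm(1 - alpha / 2)
  zmap <- function(d) {
    tt <- apply(d, 2, function(v) mean(v) / (sd(v) / sqrt(n)))
    sign(tt) * qnorm(pt(abs(tt), n - 1, lower.tail = FALSE),
                     lower.tail = FALSE)
  }
  label_masses <- function(z) {
    zm <- matrix(z, nf, nt)
    seen <- matrix(FALSE, nf, nt)
    masses <- numeric(0)
    flood <- function(i, j, sgn) {
      if (i < 1 || i > nf || j < 1 || j > nt || seen[i, j]) return(0)
      if (sgn > 0 && zm[i, j] <= thr) return(0)
      if (sgn < 0 && zm[i, j] >= -thr) return(0)
      seen[i, j] <<- TRUE
      zm[i, j] + flood(i - 1, j, sgn) + flood(i + 1, j, sgn) +
        flood(i, j - 1, sgn) + flood(i, j + 1, sgn)
    }
    for (i in 1:nf) for (j in 1:nt) {
      if (!seen[i, j] && zm[i, j] > thr) masses <- c(masses, flood(i, j, 1))
      if (!seen[i, j] && zm[i, j] < -thr) masses <- c(masses, flood(i, j, -1))
    }
    masses
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(signs, 1, function(s) {
    m <- label_masses(zmap(s * D))
    if (!length(m)) 0 else max(abs(m))
  })
  obs <- label_masses(zmap(D))
  list(masses = obs,
       p = vapply(obs, function(m) mean(null_max >= abs(m) - 1e-12), 0))
}


# Direct-convolution oracle: the same Morlet kernel applied by explicit
# time-domain correlation at selected time points.
oracle_wavelet_power <- function(x, fs, f, n_cycles, at_idx) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  g <- exp(-tt^2 / (2 * sigma_t^2))
  ker <- g * exp(2i * pi * f * tt) * (2 / sum(g))
  vapply(at_idx, function(s) {
    idx <- s + (-half:half)
    ok <- idx >= 1 & idx <= length(x)
    Mod(sum(Conj(ker[ok]) * x[idx[ok]]))^2
  }, 0)
}

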