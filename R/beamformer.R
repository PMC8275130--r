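# Frequency-domain (DICS-style) beamformer on synthetic lead fields.

#' Band-averaged cross-spectral density
#'
#' Averages, over trials and all (frequency, time) points inside the
#' requested band and window, the outer products of the sensor spectra
#' with their conjugates. Optionally also returns the cross-spectra of a
#' reference channel (e.g. an LFP) against every sensor, plus the
#' reference auto-spectrum, for coherence mapping.
#'
#' @param tfr an `hp_tfr` computed with `keep_complex = TRUE`.
#' @param band Hz interval.
#' @param window seconds interval.
#' @param sensors sensor channel names (default: all `meg_like` channels).
#' @param ref optional reference channel name.
#' @return an `hp_csd`: `csd` (Hermitian sensor x sensor, complex),
#'   `sensors`, `band`, `window`, `n_trials`, and when `ref` is given
#'   `ref_row` (complex vector, ref vs sensor) and `ref_power`.
#' @export
band_csd <- function(tfr, band, window, sensors = NULL, ref = NULL) {
  stopifnot(inherits(tfr, "hp_tfr"))
  if (is.null(tfr$fourier)) stop("TFR lacks complex spectra; use keep_complex = TRUE")
  chn <- tfr$channels$name
  sensors <- sensors %||% chn[tfr$channels$kind == "meg_like"]
  fsel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  tsel <- which(tfr$time >= window[1] & tfr$time <= window[2])
  if (!length(fsel) || !length(tsel)) stop("empty band/window selection")
  n_tr <- dim(tfr$fourier)[1]
  if (n_tr < 2) stop("need >= 2 trials")
  si <- match(sensors, chn)
  if (anyNA(si)) stop("unknown sensors")
  # stack all (trial, f, t) sensor vectors as rows
  sub <- tfr$fourier[, si, fsel, tsel, drop = FALSE]
  X <- matrix(aperm(sub, c(1, 3, 4, 2)), ncol = length(si))
  K <- nrow(X)
  csd <- t(X) %*% Conj(X) / K
  csd <- (csd + Conj(t(csd))) / 2      # enforce exact Hermitian symmetry
  out <- list(csd = csd, sensors = sensors, band = band, window = window,
              n_trials = n_tr, n_averaged = K)
  if (!is.null(ref)) {
    ri <- match(ref, chn)
    if (is.na(ri)) stop("unknown reference channel: ", ref)
    rsub <- tfr$fourier[, ri, fsel, tsel, drop = FALSE]
    R <- as.vector(rsub)
    out$ref_row <- as.vector(t(X) %*% Conj(R)) / K   # E[S_j conj(R)]
    out$ref_power <- mean(abs(R)^2)
    out$ref <- ref
  }
  structure(out, class = "hp_csd")
}

#' DICS spatial filters
#'
#' Per source node with gain column `l`, the unit-gain minimum-variance
#' filter `w = (l' Cr^-1 l)^-1 l' Cr^-1`, with `Cr` the real part of the
#' cross-spectral density regularized by `lambda_frac` times the mean of
#' its diagonal. Filters are real (fixed source orientation).
#'
#' @param L an `hp_leadfield`.
#' @param csd an `hp_csd` (sensor count must match the lead field).
#' @param lambda_frac regularization fraction (default 0.01, i.e. 1%).
#' @return matrix (node x sensor) of filter weights.
#' @export
dics_filters <- function(L, csd, lambda_frac = 0.01) {
  stopifnot(inherits(L, "hp_leadfield"), inherits(csd, "hp_csd"))
  G <- L$gain
  if (nrow(G) != nrow(csd$csd)) stop("sensor count mismatch")
  Cr <- Re(csd$csd)
  lam <- lambda_frac * mean(diag(Cr))
  Cr <- Cr + diag(lam, nrow(Cr))
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop("cross-spectral density is singular even after regularization"))
  W <- matrix(0, ncol(G), nrow(G))
  for (j in seq_len(ncol(G))) {
    l <- G[, j]
    cl <- Ci %*% l
    W[j, ] <- as.vector(cl) / as.numeric(crossprod(l, cl))
  }
  W
}

#' Source power map from DICS filters
#'
#' Node power is `Re(w csd w')` evaluated with the full complex
#' cross-spectral density.
#'
#' @param W filter matrix from [dics_filters()].
#' @param csd an `hp_csd`.
#' @param L the `hp_leadfield` (for node positions).
#' @return an `hp_sourcemap` with per-node power values.
#' @export
dics_power <- function(W, csd, L) {
  vals <- Re(diag(W %*% csd$csd %*% Conj(t(W))))
  new_sourcemap(vals, L, kind = "power")
}

new_sourcemap <- function(values, L, kind, invalid = NULL) {
  pk <- which.max(abs(values))
  structure(list(values = values, node_positions = L$node_positions,
                 grid_dims = L$grid_dims, kind = kind,
                 peak_node = pk, peak_value = values[pk],
                 invalid = invalid %||% logical(length(values))),
            class = "hp_sourcemap")
}

#' Paired source power contrast with cluster inference
#'
#' Per-node paired t statistic over samples (subjects), followed by a
#' one-tailed cluster-based permutation test over the source-grid
#' 6-connectivity; both the corrected cluster p-values and the
#' uncorrected per-node permutation p-values are reported.
#'
#' @param maps_a,maps_b matrices (sample x node) of per-sample source
#'   values (e.g. node power per subject and condition).
#' @param L the `hp_leadfield` defining the grid.
#' @param n_perm permutations (default 1000).
#' @param tail `"pos"` (default; a > b), `"neg"`, or `"two"`.
#' @param seed permutation seed.
#' @return list `t` (per node), `cluster` (`hp_cluster`), `peak_node`,
#'   `peak_t`, `p_uncorrected` (per node, sign-flip permutation).
#' @export
source_power_contrast <- function(maps_a, maps_b, L, n_perm = 1000,
                                  tail = "pos", seed = 1L) {
  stopifnot(is.matrix(maps_a), all(dim(maps_a) == dim(maps_b)),
            ncol(maps_a) == nrow(L$node_positions))
  adj <- volume_adjacency(L$grid_dims)
  res <- cluster_permutation_core(maps_a, maps_b, adj, n_perm, tail,
                                  pre_cluster_alpha = 0.05, seed = seed)
  n <- nrow(maps_a)
  D <- maps_a - maps_b
  t_obs <- perm_t_matrix(D, matrix(1, 1, n))[1, ]
  S <- if (2^n <= n_perm) all_sign_matrix(n) else {
    set.seed(stage_seed(seed, 11L))
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
  }
  Tp <- perm_t_matrix(D, S)
  p_unc <- vapply(seq_along(t_obs), function(j) {
    cmp <- switch(tail,
                  two = abs(Tp[, j]) >= abs(t_obs[j]) - 1e-12,
                  pos = Tp[, j] >= t_obs[j] - 1e-12,
                  neg = Tp[, j] <= t_obs[j] + 1e-12)
    (1 + sum(cmp)) / (nrow(S) + 1)
  }, 0)
  pk <- which.max(if (tail == "neg") -t_obs else abs(t_obs))
  list(t = t_obs, cluster = res, peak_node = pk, peak_t = t_obs[pk],
       p_uncorrected = p_unc)
}

#' Source coherence map referenced to an LFP channel
#'
#' Per node, the magnitude coherence between the beamformed node signal
#' and the reference channel:
#' `|w ref_cross| / sqrt(node_power * ref_power)`, in `[0, 1]`. Nodes with
#' non-positive power are marked invalid.
#'
#' @param L an `hp_leadfield`.
#' @param csd an `hp_csd` computed with a `ref` channel.
#' @param lambda_frac regularization fraction (default 0.01).
#' @return an `hp_sourcemap` of coherence values.
#' @export
dics_coherence_map <- function(L, csd, lambda_frac = 0.01) {
  if (is.null(csd$ref_row)) stop("csd lacks a reference row; pass ref= to band_csd()")
  if (csd$ref_power <= 0) stop("reference auto-spectrum must be > 0")
  W <- dics_filters(L, csd, lambda_frac)
  npow <- Re(diag(W %*% csd$csd %*% Conj(t(W))))
  cross <- as.vector(W %*% csd$ref_row)   # E[(wS) conj(R)]
  invalid <- npow <= 0
  coh <- rep(NA_real_, length(npow))
  coh[!invalid] <- Mod(cross[!invalid]) /
    sqrt(npow[!invalid] * csd$ref_power)
  coh <- pmin(coh, 1)
  m <- new_sourcemap(ifelse(invalid, 0, coh), L, kind = "coherence",
                     invalid = invalid)
  m$values[invalid] <- NA_real_
  m
}

#' Export a source map as a plain table
#' @param map an `hp_sourcemap`.
#' @return data.frame `x, y, z, value`.
#' @export
sourcemap_table <- function(map) {
  stopifnot(inherits(map, "hp_sourcemap"))
  data.frame(x = map$node_positions[, 1], y = map$node_positions[, 2],
             z = map$node_positions[, 3], value = map$values)
}

#' @export
print.hp_sourcemap <- function(x, ...) {
  cat(sprintf("<hp_sourcemap> %s, %d nodes, peak %.4g at node %d\n",
              x$kind, length(x$values), x$peak_value, x$peak_node))
  invisible(x)
}
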