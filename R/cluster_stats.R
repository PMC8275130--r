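# Nonparametric cluster-based permutation inference and permutation tests.

#' 4-connectivity adjacency for a frequency x time grid
#'
#' Bins are indexed column-major as `f + (t - 1) * nf`.
#'
#' @param nf,nt grid dimensions (frequencies, time points).
#' @return list of integer neighbor vectors, one per bin.
#' @export
grid_adjacency <- function(nf, nt) {
  adj <- vector("list", nf * nt)
  for (tt in seq_len(nt)) for (ff in seq_len(nf)) {
    i <- ff + (tt - 1L) * nf
    nb <- integer(0)
    if (ff > 1) nb <- c(nb, i - 1L)
    if (ff < nf) nb <- c(nb, i + 1L)
    if (tt > 1) nb <- c(nb, i - nf)
    if (tt < nt) nb <- c(nb, i + nf)
    adj[[i]] <- nb
  }
  adj
}

#' Sensor adjacency from 2-D layout distances
#'
#' Two sensors are neighbors when their layout distance is below
#' `delta_factor` times the median nearest-neighbor distance (default 1.3,
#' which yields 4-8 neighbors on regular layouts).
#'
#' @param layout data.frame with `x`, `y` (e.g. from [sensor_layout()]).
#' @param delta_factor multiplier on the median nearest-neighbor distance.
#' @return list of integer neighbor vectors, one per sensor.
#' @export
sensor_adjacency <- function(layout, delta_factor = 1.3) {
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  diag(d) <- Inf
  delta <- delta_factor * stats::median(apply(d, 1, min))
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= delta))
}

#' 6-connectivity adjacency for a regular 3-D source grid
#'
#' @param grid_dims integer length-3 node counts per axis; nodes indexed
#'   in `expand.grid(x, y, z)` order.
#' @return list of integer neighbor vectors.
#' @export
volume_adjacency <- function(grid_dims) {
  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  idx <- function(x, y, z) x + (y - 1L) * nx + (z - 1L) * nx * ny
  adj <- vector("list", nx * ny * nz)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    i <- idx(x, y, z)
    nb <- integer(0)
    if (x > 1) nb <- c(nb, idx(x - 1L, y, z))
    if (x < nx) nb <- c(nb, idx(x + 1L, y, z))
    if (y > 1) nb <- c(nb, idx(x, y - 1L, z))
    if (y < ny) nb <- c(nb, idx(x, y + 1L, z))
    if (z > 1) nb <- c(nb, idx(x, y, z - 1L))
    if (z < nz) nb <- c(nb, idx(x, y, z + 1L))
    adj[[i]] <- nb
  }
  adj
}

# Connected components of `nodes` (integer bin indices) under `adj`.
connected_components <- function(nodes, adj) {
  if (!length(nodes)) return(list())
  in_set <- logical(length(adj)); in_set[nodes] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Paired t statistics for all sign-flip assignments at once.
# D: n x nbins difference matrix; S: n_perm x n sign matrix.
# Sign flips leave the per-pair squared differences unchanged, so only the
# mean changes across permutations.
perm_t_matrix <- function(D, S) {
  n <- nrow(D)
  msq <- colMeans(D^2)
  M <- (S %*% D) / n
  V <- sweep(-M^2, 2, msq, "+") * n / (n - 1)
  V[V < 0] <- 0
  M / sqrt(V / n + (V == 0) * .Machine$double.eps)
}

t_to_z <- function(t, df) {
  sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE),
                         lower.tail = FALSE)
}

# Suprathreshold clusters and their z-score masses for one z map.
cluster_masses <- function(z, thr, adj, tail) {
  out <- list()
  if (tail %in% c("two", "pos")) {
    for (comp in connected_components(which(z > thr), adj))
      out[[length(out) + 1L]] <- list(members = comp, mass = sum(z[comp]))
  }
  if (tail %in% c("two", "neg")) {
    for (comp in connected_components(which(z < -thr), adj))
      out[[length(out) + 1L]] <- list(members = comp, mass = sum(z[comp]))
  }
  out
}

all_sign_matrix <- function(n) {
  S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(S) <- NULL
  S
}

# Shared engine for paired cluster-based permutation tests over any
# adjacency structure. a, b: n_samples x nbins matrices (paired rows).
cluster_permutation_core <- function(a, b, adj, n_perm = 1000,
                                     tail = c("two", "pos", "neg"),
                                     pre_cluster_alpha = 0.05, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  if (n < 5) stop("need >= 5 paired samples")
  D <- a - b
  df <- n - 1
  thr <- if (tail == "two") stats::qnorm(1 - pre_cluster_alpha / 2) else
    stats::qnorm(1 - pre_cluster_alpha)

  exhaustive <- 2^n <= n_perm
  S <- if (exhaustive) all_sign_matrix(n) else {
    set.seed(stage_seed(seed, 5L))
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
  }
  Tm <- perm_t_matrix(D, S)
  Z <- t_to_z(Tm, df)

  z_obs <- t_to_z(perm_t_matrix(D, matrix(1, 1, n))[1, ], df)
  clus <- cluster_masses(z_obs, thr, adj, tail)

  null_max <- apply(Z, 1, function(z) {
    cm <- cluster_masses(z, thr, adj, tail)
    if (!length(cm)) 0 else max(abs(vapply(cm, `[[`, 0, "mass")))
  })

  for (k in seq_along(clus)) {
    m <- abs(clus[[k]]$mass)
    clus[[k]]$p <- if (exhaustive) mean(null_max >= m - 1e-12) else
      (1 + sum(null_max >= m - 1e-12)) / (nrow(S) + 1)
  }
  structure(list(clusters = clus, z = z_obs, null_distribution = null_max,
                 n_perm = nrow(S), exhaustive = exhaustive, tail = tail,
                 pre_cluster_alpha = pre_cluster_alpha, threshold = thr),
            class = "hp_cluster")
}

#' Cluster-based permutation test on paired time-frequency maps
#'
#' Per-bin paired t statistics are mapped to standard-normal z-scores;
#' bins beyond the pre-cluster threshold form connected clusters
#' (4-connectivity over the frequency x time grid); each cluster's mass is
#' the sum of its z-scores; the null distribution of the maximum absolute
#' cluster mass is built from sign-flips of the pair assignment (all
#' `2^n` assignments when that count does not exceed `n_perm`, otherwise
#' `n_perm` random flips), and each observed cluster receives
#' `p = (1 + #{perm max >= |mass|}) / (n_perm + 1)` (exact proportion in
#' the exhaustive case).
#'
#' @param a,b arrays (samples x freq x time) of paired condition maps.
#' @param n_perm number of permutations (default 1000).
#' @param tail `"two"` (default), `"pos"`, or `"neg"`.
#' @param pre_cluster_alpha per-bin threshold (default 0.05).
#' @param seed permutation seed.
#' @param freqs,time optional axes stored for reporting.
#' @return an `hp_cluster`; cluster members are (freq, time) bin indices,
#'   with `members_fi`/`members_ti` giving the grid coordinates.
#' @export
tf_cluster_permutation <- function(a, b, n_perm = 1000, tail = "two",
                                   pre_cluster_alpha = 0.05, seed = 1L,
                                   freqs = NULL, time = NULL) {
  stopifnot(length(dim(a)) == 3, all(dim(a) == dim(b)))
  nf <- dim(a)[2]; nt <- dim(a)[3]
  adj <- grid_adjacency(nf, nt)
  am <- matrix(a, nrow = dim(a)[1])
  bm <- matrix(b, nrow = dim(b)[1])
  res <- cluster_permutation_core(am, bm, adj, n_perm, tail,
                                  pre_cluster_alpha, seed)
  res$grid <- c(nf = nf, nt = nt)
  res$freqs <- freqs; res$time <- time
  for (k in seq_along(res$clusters)) {
    mem <- res$clusters[[k]]$members
    res$clusters[[k]]$members_fi <- ((mem - 1L) %% nf) + 1L
    res$clusters[[k]]$members_ti <- ((mem - 1L) %/% nf) + 1L
  }
  res
}

#' Cluster-based permutation test on paired sensor topographies
#'
#' Same algorithm as [tf_cluster_permutation()] over a sensor neighbor
#' graph; singleton clusters are permitted and the graph may be
#' disconnected.
#'
#' @param a,b matrices (samples x sensors) of paired per-sensor values.
#' @param adjacency neighbor list from [sensor_adjacency()].
#' @inheritParams tf_cluster_permutation
#' @return an `hp_cluster`; cluster members are sensor indices.
#' @export
sensor_cluster_permutation <- function(a, b, adjacency, n_perm = 1000,
                                       tail = "two",
                                       pre_cluster_alpha = 0.05, seed = 1L) {
  stopifnot(is.matrix(a), all(dim(a) == dim(b)),
            length(adjacency) == ncol(a))
  cluster_permutation_core(a, b, adjacency, n_perm, tail,
                           pre_cluster_alpha, seed)
}

#' Paired-sample permutation t-test
#'
#' Observed paired t statistic with a sign-flip permutation p-value
#' (exhaustive over all `2^n` assignments when feasible within `n_perm`)
#' and a bootstrap percentile confidence interval of the mean difference.
#'
#' @param x,y paired numeric vectors.
#' @param n_perm permutation count (default 1000).
#' @param tail `"two"` (default), `"pos"` (x > y), or `"neg"`.
#' @param conf confidence level for the CI (default 0.95).
#' @param seed integer seed.
#' @return list `t, p, ci, mean_diff, n_perm, exhaustive, degenerate`.
#' @export
permutation_ttest_paired <- function(x, y, n_perm = 1000, tail = "two",
                                     conf = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  degenerate <- stats::sd(d) == 0
  t_of <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(if (mean(v) == 0) 0 else sign(mean(v)) * Inf)
    mean(v) / (s / sqrt(n))
  }
  t_obs <- t_of(d)
  exhaustive <- 2^n <= n_perm
  S <- if (exhaustive) all_sign_matrix(n) else {
    set.seed(stage_seed(seed, 6L))
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
  }
  t_perm <- apply(S, 1, function(s) t_of(s * d))
  cmp <- switch(tail,
                two = abs(t_perm) >= abs(t_obs) - 1e-12,
                pos = t_perm >= t_obs - 1e-12,
                neg = t_perm <= t_obs + 1e-12)
  p <- if (degenerate && mean(d) != 0) 1 / (nrow(S) + 1)
  else if (exhaustive) mean(cmp)
  else (1 + sum(cmp)) / (nrow(S) + 1)
  set.seed(stage_seed(seed, 8L))
  boot <- replicate(n_perm, mean(d[sample.int(n, n, replace = TRUE)]))
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  list(t = t_obs, p = p, ci = ci, mean_diff = mean(d),
       n_perm = nrow(S), exhaustive = exhaustive, degenerate = degenerate)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation test of (partial) Pearson correlation
#'
#' Pearson correlation of `x` and `y`, each residualized on the optional
#' covariates first. The p-value permutes `y` (all `n!` orderings when
#' that count does not exceed `n_perm`, otherwise `n_perm` random
#' shuffles); the CI is a bootstrap percentile interval.
#'
#' @param x,y numeric vectors (n >= 5).
#' @param covariates optional numeric matrix / data.frame of covariates.
#' @param n_perm permutation count (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list `r, p, ci, n_perm, exhaustive`.
#' @export
permutation_correlation <- function(x, y, covariates = NULL, n_perm = 1000,
                                    conf = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    x <- stats::resid(stats::lm(x ~ cm))
    y <- stats::resid(stats::lm(y ~ cm))
  }
  n <- length(x)
  r_obs <- stats::cor(x, y)
  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    P <- all_permutations(n)
    r_perm <- apply(P, 1, function(idx) stats::cor(x, y[idx]))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  } else {
    set.seed(stage_seed(seed, 9L))
    r_perm <- replicate(n_perm, stats::cor(x, y[sample.int(n)]))
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  }
  set.seed(stage_seed(seed, 10L))
  boot <- replicate(n_perm, {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
    else stats::cor(x[idx], y[idx])
  })
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                               na.rm = TRUE))
  list(r = r_obs, p = p, ci = ci,
       n_perm = if (exhaustive) factorial(n) else n_perm,
       exhaustive = exhaustive)
}

#' Significant clusters of a cluster test result
#' @param res an `hp_cluster`.
#' @param alpha significance level (default 0.05).
#' @return the subset of clusters with `p <= alpha`.
#' @export
significant_clusters <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "hp_cluster"))
  Filter(function(cl) cl$p <= alpha, res$clusters)
}

#' @export
print.hp_cluster <- function(x, ...) {
  cat(sprintf("<hp_cluster> %d cluster(s), %d permutations%s, tail=%s\n",
              length(x$clusters), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$tail))
  for (cl in x$clusters)
    cat(sprintf("  mass=%.2f size=%d p=%.4g\n", cl$mass,
                length(cl$members), cl$p))
  invisible(x)
}
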