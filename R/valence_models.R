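# Random-intercept mixed models of band/window measures vs valence/arousal.

#' Random-intercept linear mixed model of a neural measure
#'
#' Fits `response ~ predictors + (1 | subject_id)` by REML (lme4), with
#' Wald t confidence intervals and p-values on the Satterthwaite
#' denominator degrees of freedom (lmerTest).
#' The canonical usage models one row per subject x condition, the
#' response being a band/window neural measure and the predictors the
#' condition-mean valence and arousal ratings. Marginal R^2 (fixed
#' effects over total variance) is reported as primary, conditional R^2
#' alongside. When the mixed fit is degenerate (zero residual variance,
#' e.g. noiseless synthetic data), the model falls back to ordinary least
#' squares, which the random-intercept model reduces to at zero
#' random-effect variance.
#'
#' @param table data.frame with a `subject_id` column, the response and
#'   the predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns (default
#'   `c("valence", "arousal")`).
#' @param conf confidence level (default 0.95).
#' @return an `hp_lme`: list with `fixed` (data.frame term, estimate, se,
#'   ci_lo, ci_hi, p), `random_intercept_var`, `residual_var`,
#'   `r2_marginal`, `r2_conditional`, `formula`, `fallback_ols`.
#' @export
fit_random_intercept_lme <- function(table, response,
                                     predictors = c("valence", "arousal"),
                                     conf = 0.95) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  miss <- setdiff(c(response, predictors), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(table$subject_id)) < 4) stop("need >= 4 subjects")
  if (min(table(table$subject_id)) < 2)
    stop("need >= 2 observations per subject")
  for (p in predictors) {
    if (stats::sd(table[[p]]) == 0)
      stop("singular design: predictor '", p, "' is constant")
  }
  fml_txt <- paste(response, "~", paste(predictors, collapse = " + "),
                   "+ (1 | subject_id)")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(fml_txt), data = table, REML = TRUE))),
    error = function(e) NULL)
  fallback <- is.null(fit)
  if (!fallback) {
    sm <- suppressWarnings(summary(fit))$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_u <- vc$vcov[vc$grp == "subject_id"]
    var_e <- vc$vcov[vc$grp == "Residual"]
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    pv <- sm[, "Pr(>|t|)"]
    # Wald t intervals on the Satterthwaite denominator df, matching the
    # reference distribution used for the p-values
    tq <- stats::qt(1 - (1 - conf) / 2, pmax(sm[, "df"], 1))
    X <- stats::model.matrix(fit)
    var_f <- stats::var(as.vector(X %*% est))
    fixed <- data.frame(term = rownames(sm), estimate = unname(est),
                        se = unname(se),
                        ci_lo = unname(est - tq * se),
                        ci_hi = unname(est + tq * se),
                        p = unname(pv), row.names = NULL)
  } else {
    ols <- stats::lm(stats::as.formula(
      paste(response, "~", paste(predictors, collapse = " + "))), data = table)
    sm <- suppressWarnings(summary(ols))$coefficients
    var_u <- 0
    var_e <- stats::sigma(ols)^2
    if (!is.finite(var_e)) var_e <- 0
    est <- sm[, 1]; se <- sm[, 2]
    pv <- if (ncol(sm) >= 4) sm[, 4] else rep(NA_real_, length(est))
    tq <- stats::qt(1 - (1 - conf) / 2, max(stats::df.residual(ols), 1))
    var_f <- stats::var(stats::fitted(ols))
    fixed <- data.frame(term = rownames(sm), estimate = unname(est),
                        se = unname(se),
                        ci_lo = unname(est - tq * se),
                        ci_hi = unname(est + tq * se),
                        p = unname(pv), row.names = NULL)
  }
  tot <- var_f + var_u + var_e
  structure(list(fixed = fixed,
                 random_intercept_var = var_u, residual_var = var_e,
                 r2_marginal = if (tot > 0) var_f / tot else NA_real_,
                 r2_conditional = if (tot > 0) (var_f + var_u) / tot else NA_real_,
                 formula = fml_txt, fallback_ols = fallback,
                 n_obs = nrow(table),
                 n_subjects = length(unique(table$subject_id))),
            class = "hp_lme")
}

#' Mixed-model regression of later power on earlier coherence
#'
#' Fits `power ~ coherence + (1 | subject_id)` across subject x condition
#' observations (the canonical use: habenular theta power at a late window
#' regressed on cortico-habenular coherence change at an earlier window),
#' and additionally reports the permutation Pearson correlation pooling
#' all observations.
#'
#' @param table data.frame with columns `subject_id`, `coherence`,
#'   `power`.
#' @param n_perm permutations for the pooled correlation.
#' @param seed integer seed.
#' @return list `lme` (an `hp_lme`), `slope`, `slope_ci`, `slope_p`,
#'   `correlation` (from [permutation_correlation()]).
#' @export
coherence_power_regression <- function(table, n_perm = 1000, seed = 1L) {
  stopifnot(all(c("subject_id", "coherence", "power") %in% names(table)))
  fit <- fit_random_intercept_lme(table, "power", "coherence")
  row <- fit$fixed[fit$fixed$term == "coherence", ]
  pc <- permutation_correlation(table$coherence, table$power,
                                n_perm = n_perm, seed = seed)
  list(lme = fit, slope = row$estimate, slope_ci = c(row$ci_lo, row$ci_hi),
       slope_p = row$p, correlation = pc)
}

#' Window specificity of the coherence-power correlation
#'
#' Correlates a target power measure with coherence measured in several
#' candidate time windows, one permutation correlation per window, and
#' marks the windows passing `alpha`.
#'
#' @param coherence_by_window named list of numeric vectors (one per
#'   window), all paired with `power`.
#' @param power numeric vector of the target measure.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per window.
#' @param seed integer seed.
#' @return data.frame `window, r, ci_lo, ci_hi, p, significant`.
#' @export
control_window_specificity <- function(coherence_by_window, power,
                                       alpha = 0.05, n_perm = 1000,
                                       seed = 1L) {
  stopifnot(is.list(coherence_by_window), length(coherence_by_window) >= 1)
  out <- do.call(rbind, lapply(names(coherence_by_window), function(nm) {
    pc <- permutation_correlation(coherence_by_window[[nm]], power,
                                  n_perm = n_perm, seed = seed)
    data.frame(window = nm, r = pc$r, ci_lo = pc$ci[1], ci_hi = pc$ci[2],
               p = pc$p, stringsAsFactors = FALSE)
  }))
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  out
}

#' @export
print.hp_lme <- function(x, ...) {
  cat(sprintf("<hp_lme> %s%s\n", x$formula,
              if (x$fallback_ols) " [OLS fallback]" else ""))
  print(transform(x$fixed, estimate = signif(estimate, 4),
                  se = signif(se, 4), ci_lo = signif(ci_lo, 4),
                  ci_hi = signif(ci_hi, 4), p = signif(p, 4)))
  cat(sprintf("  R2 marginal=%.3f conditional=%.3f  var(subj)=%.3g var(resid)=%.3g\n",
              x$r2_marginal, x$r2_conditional, x$random_intercept_var,
              x$residual_var))
  invisible(x)
}
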