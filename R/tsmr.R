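#' @title Two-sample MR estimators
#' @name tsmr-estimators
#' @description
#' Estimators operating on a [harmonize()]d instrument table: the Wald ratio
#' (single instrument), inverse-variance-weighted regression through the
#' origin with fixed or multiplicative-random-effects standard errors,
#' MR-Egger with an intercept-based pleiotropy test (plus a row-resampling
#' bootstrap variant), the weighted median, and Cochran's Q heterogeneity
#' statistic.  All estimators are equivariant under a simultaneous sign flip
#' of the outcome betas and invariant to instrument order.
NULL

mr_estimate <- function(method, beta, se, pvalue, n_snp, extras = list()) {
  structure(c(list(method = method, beta = beta, se = se,
                   pvalue = pvalue, n_snp = n_snp), extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.4g), p = %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$pvalue, x$n_snp))
  invisible(x)
}

check_pairs <- function(pairs, min_snps, method) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) < min_snps) {
    stop_mrtriage(
      sprintf("%s needs at least %d instruments, got %d",
              method, min_snps, nrow(pairs)),
      "mrtriage_insufficient_instruments"
    )
  }
  if (any(pairs$beta_exposure == 0)) {
    stop_mrtriage("zero exposure beta among instruments",
                  "mrtriage_undefined_ratio")
  }
  pairs
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_outcome / beta_exposure` with the first-order standard error
#' `se_outcome / |beta_exposure|` (exposure uncertainty ignored, the standard
#' single-instrument fallback).
#'
#' @param pairs one-row [harmonize()]d instrument table.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(pairs) {
  pairs <- check_pairs(pairs, 1L, "wald_ratio")
  stopifnot(nrow(pairs) == 1L)
  b <- pairs$beta_outcome / pairs$beta_exposure
  se <- pairs$se_outcome / abs(pairs$beta_exposure)
  mr_estimate("wald_ratio", b, se, z_to_p(b / se), 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1 / se_outcome^2`.  `model = "fixed"` takes the standard
#' error from the weight sum; `model = "mre"` (multiplicative random
#' effects, the primary model) scales it by the residual standard deviation
#' of the regression, with no lower floor at 1 (see
#' `floor_dispersion = TRUE` to floor it).
#'
#' @param pairs [harmonize()]d instrument table with at least 2 rows.
#' @param model `"mre"` (default) or `"fixed"`.
#' @param floor_dispersion floor the multiplicative dispersion at 1 so the
#'   random-effects SE can never undercut the fixed-effect SE (default
#'   `FALSE`).
#' @return an `mr_estimate` with Q extras (`Q`, `p_Q`).
#' @export
ivw <- function(pairs, model = c("mre", "fixed"), floor_dispersion = FALSE) {
  model <- match.arg(model)
  pairs <- check_pairs(pairs, 2L, "ivw")
  x <- pairs$beta_exposure; y <- pairs$beta_outcome
  w <- 1 / pairs$se_outcome^2
  k <- length(x)
  swx2 <- sum(w * x^2)
  b <- sum(w * x * y) / swx2
  var_fixed <- 1 / swx2
  disp <- sum(w * (y - b * x)^2) / (k - 1)
  if (floor_dispersion) disp <- max(disp, 1)
  se <- sqrt(var_fixed * if (model == "mre") disp else 1)
  q <- cochran_q(pairs)
  mr_estimate(paste0("ivw_", model), b, se, z_to_p(b / se), k,
              extras = list(dispersion = disp, Q = q$Q, p_Q = q$p_Q))
}

# orient rows so every exposure beta is non-negative (Egger convention)
orient_pairs <- function(pairs) {
  s <- sign(pairs$beta_exposure)
  pairs$beta_exposure <- pairs$beta_exposure * s
  pairs$beta_outcome <- pairs$beta_outcome * s
  pairs
}

# closed-form weighted regression with intercept; standard errors carry the
# estimated residual dispersion (k - 2 df), matching summary.lm on weighted fits
egger_fit <- function(pairs) {
  x <- pairs$beta_exposure; y <- pairs$beta_outcome
  w <- 1 / pairs$se_outcome^2
  k <- length(x)
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  sigma2 <- sum(w * (y - intercept - slope * x)^2) / (k - 2L)
  list(intercept = intercept,
       se_intercept = sqrt(sigma2 * (1 / sw + mx^2 / sxx)),
       slope = slope, se_slope = sqrt(sigma2 / sxx), df = k - 2L)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas *with* an intercept,
#' after flipping rows so all exposure betas are non-negative.  The intercept
#' estimates average directional pleiotropy; its p-value (t test, k - 2 df)
#' is the pleiotropy test consumed by [sensitivity_suite()].
#'
#' @param pairs [harmonize()]d instrument table with at least 3 rows.
#' @return an `mr_estimate` with extras `intercept`, `se_intercept`,
#'   `p_intercept`.
#' @export
egger <- function(pairs) {
  pairs <- orient_pairs(check_pairs(pairs, 3L, "egger"))
  f <- egger_fit(pairs)
  mr_estimate("egger", f$slope, f$se_slope,
              t_to_p(f$slope / f$se_slope, f$df), nrow(pairs),
              extras = list(intercept = f$intercept,
                            se_intercept = f$se_intercept,
                            p_intercept = t_to_p(f$intercept / f$se_intercept, f$df)))
}

#' @rdname egger
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed (bootstrap is fully reproducible given the seed).
#' @details `egger_bootstrap()` resamples instrument rows with replacement
#'   `n_boot` times, refits the Egger regression on each resample, and
#'   reports the empirical median and standard deviation of the slope (and
#'   intercept).  Degenerate resamples with fewer than 3 distinct exposure
#'   betas are skipped.
#' @export
egger_bootstrap <- function(pairs, n_boot = 1000, seed = 1) {
  pairs <- orient_pairs(check_pairs(pairs, 3L, "egger_bootstrap"))
  k <- nrow(pairs)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(k, k, replace = TRUE)
      sub <- pairs[idx, ]
      if (length(unique(sub$beta_exposure)) < 3L) next
      f <- egger_fit(sub)
      out[i, ] <- c(f$slope, f$intercept)
    }
    out
  })
  ok <- stats::complete.cases(draws)
  slope <- stats::median(draws[ok, 1])
  se_slope <- stats::sd(draws[ok, 1])
  intercept <- stats::median(draws[ok, 2])
  se_intercept <- stats::sd(draws[ok, 2])
  mr_estimate("egger_bootstrap", slope, se_slope,
              if (is.na(se_slope)) NA_real_ else z_to_p(slope / se_slope), k,
              extras = list(intercept = intercept, se_intercept = se_intercept,
                            p_intercept = if (is.na(se_intercept)) NA_real_
                                          else z_to_p(intercept / se_intercept),
                            n_boot = n_boot, n_boot_ok = sum(ok)))
}

weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)     # standardized cumulative weights
  if (p[1] >= 0.5) return(ratio[1])
  j <- max(which(p < 0.5))
  if (j == length(ratio)) return(ratio[j])
  ratio[j] + (ratio[j + 1] - ratio[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted median estimate
#'
#' Orders the per-instrument Wald ratios and interpolates the 50% point of
#' their standardized inverse-variance cumulative weights
#' (`w_i = 1 / se_ratio_i^2` with the first-order ratio SE).  Consistent when
#' instruments carrying at least half the weight are valid.  The standard
#' error comes from a seeded parametric bootstrap: exposure and outcome betas
#' are redrawn from their sampling distributions and the median recomputed.
#'
#' @param pairs [harmonize()]d instrument table with at least 3 rows.
#' @param n_boot parametric bootstrap draws for the SE (default 1000).
#' @param seed RNG seed.
#' @return an `mr_estimate`.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  pairs <- check_pairs(pairs, 3L, "weighted_median")
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  se_ratio <- pairs$se_outcome / abs(pairs$beta_exposure)
  est <- weighted_median_point(ratio, 1 / se_ratio^2)
  k <- nrow(pairs)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, pairs$beta_exposure, pairs$se_exposure)
      by <- stats::rnorm(k, pairs$beta_outcome, pairs$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      s <- pairs$se_outcome / abs(bx)
      weighted_median_point(r, 1 / s^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", est, se, z_to_p(est / se), k,
              extras = list(n_boot = n_boot))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_i w_i (ratio_i - beta_IVW_fixed)^2` over the per-instrument Wald
#' ratios with inverse-variance weights `w_i = beta_exposure_i^2 /
#' se_outcome_i^2`; referred to chi-squared with k - 1 degrees of freedom.
#' With these weights the fixed-effect IVW slope equals the weighted mean of
#' the ratios, so Q measures instrument disagreement about a single causal
#' effect.
#'
#' @param pairs [harmonize()]d instrument table with at least 2 rows.
#' @return list with `Q`, `p_Q`, `df`.
#' @export
cochran_q <- function(pairs) {
  pairs <- check_pairs(pairs, 2L, "cochran_q")
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  w <- (pairs$beta_exposure / pairs$se_outcome)^2
  b <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - b)^2)
  df <- nrow(pairs) - 1L
  list(Q = q, p_Q = pmax(stats::pchisq(q, df, lower.tail = FALSE),
                         .Machine$double.xmin), df = df)
}

#' Run the full sensitivity suite and recommend an estimator
#'
#' Computes IVW (fixed and multiplicative random effects), MR-Egger, the
#' MR-Egger bootstrap, and the weighted median, together with Cochran's Q and
#' the Egger intercept test.  The recommendation rule: MR-Egger (bootstrap)
#' when the pleiotropy test is significant at `alpha`; otherwise IVW with
#' multiplicative random effects, which both absorbs significant
#' heterogeneity and is the primary estimator in the clean case.  Pleiotropy
#' takes precedence over heterogeneity when both are significant.
#'
#' @param pairs [harmonize()]d instrument table with at least 3 rows.
#' @param alpha significance level for the pleiotropy / heterogeneity calls
#'   (default 0.05).
#' @param n_boot bootstrap draws for the bootstrap-based estimators.
#' @param seed RNG seed.
#' @return a `sensitivity_report` list with all five estimates, `Q`, `p_Q`,
#'   `egger_intercept`, `p_intercept`, and `recommended_method`.
#' @export
sensitivity_suite <- function(pairs, alpha = 0.05, n_boot = 1000, seed = 1) {
  pairs <- check_pairs(pairs, 3L, "sensitivity_suite")
  est <- list(
    ivw_fixed = ivw(pairs, "fixed"),
    ivw_mre = ivw(pairs, "mre"),
    egger = egger(pairs),
    egger_bootstrap = egger_bootstrap(pairs, n_boot = n_boot, seed = seed),
    weighted_median = weighted_median(pairs, n_boot = n_boot, seed = seed + 1L)
  )
  q <- cochran_q(pairs)
  p_int <- est$egger$p_intercept
  recommended <- if (!is.na(p_int) && p_int < alpha) "egger_bootstrap" else "ivw_mre"
  structure(
    list(estimates = est, Q = q$Q, p_Q = q$p_Q,
         egger_intercept = est$egger$intercept, p_intercept = p_int,
         heterogeneity_significant = q$p_Q < alpha,
         pleiotropy_significant = !is.na(p_int) && p_int < alpha,
         recommended_method = recommended),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  for (e in x$estimates) {
    cat(sprintf("  %-16s beta = %8.4f  se = %7.4f  p = %.3g\n",
                e$method, e$beta, e$se, e$pvalue))
  }
  cat(sprintf("  Q = %.3f (p = %.3g); Egger intercept = %.4f (p = %.3g)\n",
              x$Q, x$p_Q, x$egger_intercept, x$p_intercept))
  cat(sprintf("  recommended: %s\n", x$recommended_method))
  invisible(x)
}
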