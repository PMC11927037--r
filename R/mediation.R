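#' @title Product-of-coefficients mediation with distribution-of-product CIs
#' @name mediation
#' @description
#' The mediated (indirect) effect of a gene on the outcome through the
#' mediator is the product `a * b` of the gene-to-mediator effect `a` and the
#' mediator-to-outcome effect `b`, both estimated by two-sample MR.  Because
#' the product of two normal estimates is not normal, confidence intervals
#' come from the exact distribution of the product of two independent normal
#' random variables (the distribution-of-product method), which yields
#' asymmetric intervals with close-to-nominal coverage.
NULL

#' Product-of-coefficients estimate and standard error
#'
#' `estimate = a * b`.  The first-order (delta-method) variance is
#' `a^2 se_b^2 + b^2 se_a^2`; the exact variance of the product of two
#' independent normals adds `se_a^2 se_b^2` (the default, matching the usual
#' distribution-of-product tooling).
#'
#' @param a,se_a path estimate gene -> mediator and its SE (`se_a > 0`, or 0
#'   for a degenerate point mass).
#' @param b,se_b path estimate mediator -> outcome and its SE.
#' @param variance_formula `"exact"` (default) or `"first_order"`.
#' @return list with `estimate` and `se`.
#' @export
product_effect <- function(a, se_a, b, se_b,
                           variance_formula = c("exact", "first_order")) {
  variance_formula <- match.arg(variance_formula)
  stopifnot(se_a >= 0, se_b >= 0)
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (variance_formula == "exact") v <- v + se_a^2 * se_b^2
  list(estimate = a * b, se = sqrt(v))
}

# CDF of the product X*Y of independent X ~ N(a, se_a^2), Y ~ N(b, se_b^2),
# by quadrature over the standardized X: with x = a + se_a * t,
#   P(XY <= q) = E_t[ P(Y <= q/x) 1{x>0} + P(Y >= q/x) 1{x<0} ].
# The integrand is O(1) in t (no spike as se_a -> 0), so adaptive quadrature
# on (t0, 40) and (-40, t0) with t0 = -a/se_a is stable for any z = a/se_a.
prodnorm_cdf <- function(q, a, se_a, b, se_b, rel_tol = 1e-10) {
  if (se_a == 0) {
    if (a == 0) return(as.numeric(q >= 0))
    p <- stats::pnorm((q / a - b) / se_b)
    return(if (a > 0) p else 1 - p)
  }
  if (se_b == 0) return(prodnorm_cdf(q, a = b, se_a = 0, b = a, se_b = se_a))
  t0 <- -a / se_a
  f_pos <- function(t) {
    x <- a + se_a * t
    x[x == 0] <- .Machine$double.xmin
    stats::dnorm(t) * stats::pnorm((q / x - b) / se_b)
  }
  f_neg <- function(t) {
    x <- a + se_a * t
    x[x == 0] <- -.Machine$double.xmin
    stats::dnorm(t) * stats::pnorm((q / x - b) / se_b, lower.tail = FALSE)
  }
  # +/- 12 standardized units hold all but ~1e-32 of X's mass; the narrow
  # interval keeps the adaptive rule stable
  val <- 0
  if (t0 < 12) {
    val <- val + stats::integrate(f_pos, max(t0, -12), 12,
                                  rel.tol = rel_tol, abs.tol = 1e-12,
                                  subdivisions = 400L)$value
  }
  if (t0 > -12) {
    val <- val + stats::integrate(f_neg, -12, min(t0, 12),
                                  rel.tol = rel_tol, abs.tol = 1e-12,
                                  subdivisions = 400L)$value
  }
  min(max(val, 0), 1)
}

# quantile of the product distribution by bisection on the analytic CDF
prodnorm_quantile <- function(p, a, se_a, b, se_b) {
  if (se_a == 0 && se_b == 0) return(a * b)
  if (se_a == 0) {
    if (a == 0) return(0)
    return(if (a > 0) a * stats::qnorm(p, b, se_b)
           else a * stats::qnorm(1 - p, b, se_b))
  }
  if (se_b == 0) return(prodnorm_quantile(p, a = b, se_a = 0, b = a, se_b = se_a))
  m <- a * b
  s <- sqrt(a^2 * se_b^2 + b^2 * se_a^2 + se_a^2 * se_b^2)
  lo <- m - 15 * s; hi <- m + 15 * s
  # widen the bracket if needed (practically never at 15 sd)
  while (prodnorm_cdf(lo, a, se_a, b, se_b) > p) lo <- lo - 15 * s
  while (prodnorm_cdf(hi, a, se_a, b, se_b) < p) hi <- hi + 15 * s
  stats::uniroot(function(q) prodnorm_cdf(q, a, se_a, b, se_b) - p,
                 lower = lo, upper = hi, tol = s * 1e-9,
                 maxiter = 200L)$root
}

#' Distribution-of-product confidence interval for a mediated effect
#'
#' Quantiles of the distribution of the product of two independent normals
#' `N(a, se_a^2) * N(b, se_b^2)`.  The analytic method integrates the product
#' CDF numerically and inverts it by bisection; the Monte Carlo method takes
#' empirical quantiles of seeded draws.  The two agree to well within 0.005
#' for a million draws or more.
#'
#' @inheritParams product_effect
#' @param level confidence level in (0, 1), default 0.95.
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param n_draws Monte Carlo draw count (default 1e6).
#' @param seed RNG seed for the Monte Carlo method.
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
dop_ci <- function(a, se_a, b, se_b, level = 0.95,
                   method = c("analytic", "monte_carlo"),
                   n_draws = 1e6, seed = 1) {
  method <- match.arg(method)
  stopifnot(se_a >= 0, se_b >= 0, level > 0, level < 1)
  alpha <- (1 - level) / 2
  if (method == "analytic") {
    ci <- c(prodnorm_quantile(alpha, a, se_a, b, se_b),
            prodnorm_quantile(1 - alpha, a, se_a, b, se_b))
  } else {
    ci <- with_seed(seed, {
      prod <- stats::rnorm(n_draws, a, se_a) * stats::rnorm(n_draws, b, se_b)
      unname(stats::quantile(prod, c(alpha, 1 - alpha)))
    })
  }
  names(ci) <- c("ci_low", "ci_high")
  ci
}

#' Back-derive a path coefficient from a reported mediated effect
#'
#' Given a published mediated effect `a*b` with its standard error and the
#' published `b` path, solves for `a = mediated / b` and for the `se_a` that
#' reproduces `se_mediated` under the chosen product-variance formula.  When
#' the residual variance `se_mediated^2 - a^2 se_b^2` is negative no real
#' `se_a` exists (which happens for some reported rows once `b` and `se_b`
#' are rounded) and an infeasible-inputs error reporting the residual is
#' raised.
#'
#' @param mediated,se_mediated reported mediated effect and SE.
#' @param b,se_b mediator -> outcome effect and SE (`b` non-zero).
#' @param variance_formula `"first_order"` (default) or `"exact"`.
#' @return list with `a` and `se_a`.
#' @export
back_derive_path <- function(mediated, se_mediated, b, se_b,
                             variance_formula = c("first_order", "exact")) {
  variance_formula <- match.arg(variance_formula)
  if (b == 0) stop_mrtriage("b must be non-zero", "mrtriage_undefined_ratio")
  a <- mediated / b
  resid <- se_mediated^2 - a^2 * se_b^2
  denom <- b^2 + if (variance_formula == "exact") se_b^2 else 0
  if (resid < 0) {
    stop_mrtriage(
      sprintf("no real se_a solves the %s product variance (residual %.3e)",
              variance_formula, resid),
      "mrtriage_infeasible_inputs", residual = resid
    )
  }
  list(a = a, se_a = sqrt(resid / denom))
}

#' Classify a gene by total, direct, and mediated significance
#'
#' Stage-wise rule with per-stage Bonferroni denominators: a gene is
#' `total_significant` when its total (gene -> outcome) TSMR p-value is below
#' `alpha / n_total`; otherwise `direct_significant` when its multivariable
#' MR direct p-value is below `alpha / n_direct`; otherwise `mediation_only`
#' when the 95% distribution-of-product interval for the mediated effect
#' excludes zero; otherwise `none`.  The screen of interest keeps
#' `mediation_only` genes: those acting on the outcome through the mediator
#' alone.
#'
#' @param total_p,direct_p p-values for the total and direct effects.
#' @param ci_low,ci_high distribution-of-product CI for the mediated effect.
#' @param n_total,n_direct realized Bonferroni denominators for the two
#'   stages.
#' @param alpha family-wise level (default 0.05).
#' @return one of `"total_significant"`, `"direct_significant"`,
#'   `"mediation_only"`, `"none"`.
#' @export
classify_gene <- function(total_p, direct_p, ci_low, ci_high,
                          n_total, n_direct, alpha = 0.05) {
  stopifnot(n_total >= 1, n_direct >= 1)
  if (!is.na(total_p) && total_p < alpha / n_total) return("total_significant")
  if (!is.na(direct_p) && direct_p < alpha / n_direct) return("direct_significant")
  if (!is.na(ci_low) && !is.na(ci_high) && (ci_low > 0 || ci_high < 0)) {
    return("mediation_only")
  }
  "none"
}

#' Full mediation decomposition for one gene
#'
#' Combines the total effect (TSMR gene -> outcome), direct effect (MVMR),
#' and mediated effect (product of the TSMR gene -> mediator path `a` and
#' the shared mediator -> outcome path `b`) into one record with the
#' distribution-of-product CI and the stage-wise classification.
#'
#' @param gene_id gene identifier.
#' @param a,se_a gene -> mediator TSMR estimate.
#' @param b,se_b mediator -> outcome TSMR estimate (shared across genes).
#' @param total,se_total,total_p total-effect TSMR estimate.
#' @param direct,se_direct,direct_p MVMR direct-effect estimate.
#' @param n_total,n_direct realized Bonferroni denominators.
#' @param level CI level (default 0.95).
#' @param alpha family-wise level (default 0.05).
#' @param variance_formula passed to [product_effect()].
#' @param ci_method passed to [dop_ci()].
#' @return one-row data.frame (class `mediation_decomposition`).
#' @export
mediation_decomposition <- function(gene_id, a, se_a, b, se_b,
                                    total, se_total, total_p,
                                    direct, se_direct, direct_p,
                                    n_total, n_direct,
                                    level = 0.95, alpha = 0.05,
                                    variance_formula = "exact",
                                    ci_method = "analytic") {
  pe <- product_effect(a, se_a, b, se_b, variance_formula = variance_formula)
  ci <- dop_ci(a, se_a, b, se_b, level = level, method = ci_method)
  out <- data.frame(
    gene_id = gene_id, a = a, se_a = se_a, b = b, se_b = se_b,
    total = total, se_total = se_total, total_p = total_p,
    direct = direct, se_direct = se_direct, direct_p = direct_p,
    mediated = pe$estimate, se_mediated = pe$se,
    ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
    category = classify_gene(total_p, direct_p, ci[["ci_low"]], ci[["ci_high"]],
                             n_total, n_direct, alpha = alpha),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mediation_decomposition", "data.frame")
  out
}
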