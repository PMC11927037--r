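#' Summary-data-based Mendelian randomization (SMR) test
#'
#' Combines an eQTL effect and a GWAS effect at the same variant into a Wald
#' ratio `b_xy = beta_gwas / beta_eqtl`, the causal effect of expression on
#' the trait under a single shared causal variant.  The test statistic is
#' `T_SMR = z_eqtl^2 * z_gwas^2 / (z_eqtl^2 + z_gwas^2)`, referred to a
#' chi-squared distribution with 1 degree of freedom.  The standard error is
#' the first-order delta-method value
#' `sqrt(se_gwas^2/beta_eqtl^2 + beta_gwas^2 se_eqtl^2 / beta_eqtl^4)`,
#' which equals `|b_xy| / sqrt(T_SMR)` whenever the statistic is non-zero.
#'
#' All arguments are vectorized over variants.
#'
#' @param beta_eqtl,se_eqtl top-SNP effect of the variant on expression and
#'   its standard error (must be non-zero / positive).
#' @param beta_gwas,se_gwas effect of the same variant on the trait.
#' @return data.frame with columns `b_xy`, `se_xy`, `p_smr`.
#' @export
smr_test <- function(beta_eqtl, se_eqtl, beta_gwas, se_gwas) {
  if (any(beta_eqtl == 0)) {
    stop_mrtriage("beta_eqtl must be non-zero (undefined Wald ratio)",
                  "mrtriage_undefined_ratio")
  }
  stopifnot(all(se_eqtl > 0), all(se_gwas > 0))
  z_e2 <- (beta_eqtl / se_eqtl)^2
  z_g2 <- (beta_gwas / se_gwas)^2
  t_smr <- ifelse(z_e2 + z_g2 == 0, 0, z_e2 * z_g2 / (z_e2 + z_g2))
  b_xy <- beta_gwas / beta_eqtl
  se_xy <- sqrt(se_gwas^2 / beta_eqtl^2 + beta_gwas^2 * se_eqtl^2 / beta_eqtl^4)
  p_smr <- pmax(stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
                .Machine$double.xmin)
  data.frame(b_xy = b_xy, se_xy = se_xy, p_smr = p_smr, t_smr = t_smr)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (pleiotropy/causality, the
#' configuration SMR assumes) from two distinct causal variants in linkage
#' disequilibrium.  Under a single causal variant every cis SNP estimates the
#' same ratio `b_xy`; HEIDI tests the deviations
#' `d_i = b_xy(snp_i) - b_xy(top)` jointly against zero, accounting for the
#' LD-induced correlation among the `d_i`.
#'
#' SNPs enter the test when their eQTL p-value is below `p_eqtl_select` and
#' their squared correlation with the top SNP lies in `r2_range`; at most
#' `max_snps` SNPs (smallest eQTL p first) are used, and the test is reported
#' as missing (`NA`) when fewer than `min_snps` qualify.  The null
#' distribution of `T_HEIDI = sum_i (d_i / sd(d_i))^2` is a sum of correlated
#' squared normals; its p-value is computed by seeded Monte Carlo from the
#' multivariate normal null with the delta-method correlation implied by LD.
#'
#' @param eqtl,gwas data.frames with columns `snp_id`, `beta`, `se` (and for
#'   `eqtl` a `pvalue` column) over the same locus.
#' @param ld [ld_matrix()] covering the locus.
#' @param p_eqtl_select eQTL p-value ceiling for SNP selection (default
#'   1.57e-3, i.e. |z| > 3.16).
#' @param r2_range inclusive range of r-squared with the top SNP (default
#'   0.05--0.9; the top SNP itself is excluded by the upper bound).
#' @param max_snps cap on the number of test SNPs (default 20).
#' @param min_snps minimum below which the test is not run (default 3).
#' @param n_draws Monte Carlo draws for the null (default 2e4).
#' @param seed RNG seed for the null draws.
#' @return list with `p_heidi` (NA when not run), `n_heidi_snps`, `t_heidi`,
#'   and `top_snp`.
#' @export
heidi_test <- function(eqtl, gwas, ld,
                       p_eqtl_select = 1.57e-3, r2_range = c(0.05, 0.9),
                       max_snps = 20, min_snps = 3,
                       n_draws = 2e4, seed = 1) {
  shared <- Reduce(intersect, list(eqtl$snp_id, gwas$snp_id, ld$snp_ids))
  if (length(shared) == 0L) {
    stop_mrtriage("no SNPs shared across eQTL, GWAS and LD inputs",
                  "mrtriage_ld_coverage_error")
  }
  shared <- sort(shared)   # canonical order: invariant to input row order
  eq <- eqtl[match(shared, eqtl$snp_id), ]
  gw <- gwas[match(shared, gwas$snp_id), ]
  if (is.null(eq$pvalue)) eq$pvalue <- z_to_p(eq$beta / eq$se)

  # smallest p, ties (e.g. floored underflows) broken by |z| then snp_id
  top_i <- order(eq$pvalue, -abs(eq$beta / eq$se), eq$snp_id)[1L]
  top_snp <- shared[top_i]
  r_top <- ld$r[shared, top_snp]
  sel <- which(
    eq$pvalue < p_eqtl_select &
      r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2] &
      shared != top_snp
  )
  sel <- sel[order(eq$pvalue[sel], eq$snp_id[sel])]
  if (length(sel) > max_snps) sel <- sel[seq_len(max_snps)]
  if (length(sel) < min_snps) {
    return(list(p_heidi = NA_real_, n_heidi_snps = length(sel),
                t_heidi = NA_real_, top_snp = top_snp))
  }

  idx <- c(top_i, sel)                      # top first
  be <- eq$beta[idx]; see <- eq$se[idx]
  bg <- gw$beta[idx]; seg <- gw$se[idx]
  if (any(be == 0)) {
    stop_mrtriage("zero eQTL beta among HEIDI SNPs", "mrtriage_undefined_ratio")
  }
  bxy <- bg / be
  r_sub <- ld$r[shared[idx], shared[idx], drop = FALSE]
  # delta-method covariance of the Wald ratios across SNPs in LD; the two
  # studies are independent, so GWAS and eQTL sampling terms add
  cov_b <- r_sub * tcrossprod(seg / be) +
    tcrossprod(bxy) * r_sub * tcrossprod(see / be)
  k <- length(sel)
  d <- bxy[-1L] - bxy[1L]
  cov_d <- cov_b[-1L, -1L, drop = FALSE] -
    outer(cov_b[-1L, 1L], rep(1, k)) -
    outer(rep(1, k), cov_b[1L, -1L]) +
    cov_b[1L, 1L]
  sd_d <- sqrt(diag(cov_d))
  z_d <- d / sd_d
  t_heidi <- sum(z_d^2)
  corr_d <- stats::cov2cor(cov_d)
  ch <- tryCatch(chol(corr_d),
                 error = function(e) chol(corr_d + diag(1e-8, k)))
  t_null <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * k), n_draws, k) %*% ch
    rowSums(z^2)
  })
  p_heidi <- (1 + sum(t_null >= t_heidi)) / (n_draws + 1)
  list(p_heidi = p_heidi, n_heidi_snps = k, t_heidi = t_heidi, top_snp = top_snp)
}

#' Screen genes on SMR, HEIDI and gene-symbol presence
#'
#' A gene passes when its SMR p-value is below `smr_p`, its HEIDI p-value is
#' strictly above `heidi_p` (a missing HEIDI p-value fails), and its gene
#' symbol is non-empty (symbol-less transcripts are excluded).  The stages
#' are applied in that order and the first failing stage is recorded.
#'
#' @param results data.frame with columns `gene_id`, `p_smr`, `p_heidi`, and
#'   `gene_symbol`.
#' @param smr_p,heidi_p stage thresholds (defaults 0.05 / 0.05).
#' @param require_symbol apply the symbol filter (default `TRUE`).
#' @return the input with added `stage` (`"pass"` or the first failing stage
#'   among `"fail_smr"`, `"fail_heidi"`, `"fail_symbol"`) and logical `pass`;
#'   per-stage drop counts in `attr(, "counts")`.
#' @export
smr_screen <- function(results, smr_p = 0.05, heidi_p = 0.05,
                       require_symbol = TRUE) {
  stopifnot(all(c("gene_id", "p_smr", "p_heidi", "gene_symbol") %in% names(results)))
  stage <- rep("pass", nrow(results))
  stage[!(results$p_smr < smr_p)] <- "fail_smr"
  heidi_ok <- !is.na(results$p_heidi) & results$p_heidi > heidi_p
  stage[stage == "pass" & !heidi_ok] <- "fail_heidi"
  if (require_symbol) {
    symbol_ok <- !is.na(results$gene_symbol) & nzchar(results$gene_symbol)
    stage[stage == "pass" & !symbol_ok] <- "fail_symbol"
  }
  results$stage <- stage
  results$pass <- stage == "pass"
  attr(results, "counts") <- c(
    n_in = nrow(results),
    fail_smr = sum(stage == "fail_smr"),
    fail_heidi = sum(stage == "fail_heidi"),
    fail_symbol = sum(stage == "fail_symbol"),
    n_pass = sum(results$pass)
  )
  results
}
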