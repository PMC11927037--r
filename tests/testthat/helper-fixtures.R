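# in-code fixtures and independent oracles shared across the suite

make_records <- function(n = 3,
                         snp_id = sprintf("rs%03d", seq_len(n)),
                         chrom = "1",
                         pos = seq_len(n) * 1e5,
                         ea = "A", oa = "G", eaf = 0.3,
                         beta = 0.1, se = 0.05, pvalue = NULL,
                         n_sample = 10000) {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, n = n_sample,
             stringsAsFactors = FALSE)
}

make_ss <- function(..., trait_id = "trait", trait_type = "eqtl_gene",
                    gene_symbol = "GENE") {
  sumstats(trait_id, trait_type, make_records(...), gene_symbol = gene_symbol)
}

make_pairs <- function(beta_exposure, beta_outcome,
                       se_exposure = rep(0.02, length(beta_exposure)),
                       se_outcome = rep(0.1, length(beta_exposure))) {
  k <- length(beta_exposure)
  out <- data.frame(
    snp_id = sprintf("iv%03d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    pvalue_exposure = pmax(2 * pnorm(-abs(beta_exposure / se_exposure)), 1e-300),
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    pvalue_outcome = pmax(2 * pnorm(-abs(beta_outcome / se_outcome)), 1e-300),
    eaf = 0.3, action_taken = "kept", stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

# independent clumping oracle: iterate candidates in (p, snp_id) order and
# keep each unless it conflicts with an already-kept SNP; checks every
# pairwise constraint explicitly (different control flow than the package's
# eliminate-as-you-go greedy)
clump_oracle <- function(records, r, p_thresh, window_kb, r2_thresh) {
  cand <- records[records$pvalue < p_thresh, , drop = FALSE]
  cand <- cand[order(cand$pvalue, cand$snp_id), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (k in kept) {
      j <- match(k, cand$snp_id)
      if (cand$chrom[i] == cand$chrom[j] &&
          abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000 &&
          r[cand$snp_id[i], k]^2 >= r2_thresh) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, cand$snp_id[i])
  }
  kept
}

# validity + maximality audit of a clumped set against all pairwise constraints
clump_is_valid_maximal <- function(kept, records, r, p_thresh, window_kb, r2_thresh) {
  conflicts <- function(i, j) {
    records$chrom[i] == records$chrom[j] &&
      abs(records$pos[i] - records$pos[j]) <= window_kb * 1000 &&
      r[records$snp_id[i], records$snp_id[j]]^2 >= r2_thresh
  }
  cand <- which(records$pvalue < p_thresh)
  ki <- match(kept, records$snp_id)
  for (a in seq_along(ki)) {
    for (b in seq_along(ki)) {
      if (a < b && conflicts(ki[a], ki[b])) return(FALSE)  # validity
    }
  }
  for (i in setdiff(cand, ki)) {                           # maximality
    if (!any(vapply(ki, function(j) conflicts(i, j), logical(1)))) return(FALSE)
  }
  all(ki %in% cand)
}

# random PSD correlation matrix with unit diagonal
random_corr <- function(k) {
  m <- matrix(rnorm(k * (k + 2)), k + 2, k)
  stats::cov2cor(crossprod(m))
}
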