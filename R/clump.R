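#' Greedy LD clumping of summary statistics
#'
#' Selects an approximately independent set of genome-wide-significant
#' variants by p-value ranking: repeatedly keep the remaining SNP with the
#' smallest p-value (ties broken by lexicographic SNP id) and discard every
#' remaining SNP on the same chromosome within `window_kb` kilobases whose
#' squared correlation with the kept SNP is at least `r2_thresh`.  The window
#' is the full pairwise distance, PLINK-style: a pair conflicts when
#' `|pos_i - pos_j| <= window_kb * 1000` and `r^2 >= r2_thresh`.
#'
#' Defaults follow the conventional genome-wide instrument-selection settings
#' (p < 5e-8, 10 000 kb, r^2 < 0.001).
#'
#' @param ss a [sumstats()] object.
#' @param ld an [ld_matrix()] covering every candidate SNP (p < `p_thresh`).
#' @param p_thresh p-value threshold for candidacy (default `5e-8`).
#' @param window_kb clumping window in kb, full pairwise distance (default 10000).
#' @param r2_thresh r-squared ceiling within the window (default 0.001).
#' @return character vector of retained SNP ids in selection order; an empty
#'   vector when no SNP reaches `p_thresh` (an instrument-less trait is not
#'   an error).
#' @export
clump <- function(ss, ld, p_thresh = 5e-8, window_kb = 10000, r2_thresh = 0.001) {
  stopifnot(inherits(ss, "sumstats"), inherits(ld, "ld_matrix"))
  rec <- ss$records
  cand <- rec[rec$pvalue < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  miss <- setdiff(cand$snp_id, ld$snp_ids)
  if (length(miss) > 0L) {
    stop_mrtriage(
      paste0("LD matrix does not cover candidate SNP(s): ",
             paste(utils::head(miss, 5), collapse = ", ")),
      "mrtriage_ld_coverage_error"
    )
  }
  ord <- order(cand$pvalue, cand$snp_id)
  cand <- cand[ord, ]
  r2 <- ld$r[cand$snp_id, cand$snp_id, drop = FALSE]^2
  window_bp <- window_kb * 1000
  keep <- character(0)
  alive <- rep(TRUE, nrow(cand))
  while (any(alive)) {
    i <- which(alive)[1L]           # smallest p among the living
    keep <- c(keep, cand$snp_id[i])
    conflict <- alive &
      cand$chrom == cand$chrom[i] &
      abs(cand$pos - cand$pos[i]) <= window_bp &
      r2[i, ] >= r2_thresh
    alive[conflict] <- FALSE
    alive[i] <- FALSE
  }
  keep
}
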