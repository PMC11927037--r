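#' Multivariable IVW Mendelian randomization
#'
#' Weighted multiple regression of outcome betas on a matrix of per-exposure
#' betas through the origin, with weights `1 / se_outcome^2`.  Each
#' coefficient is the direct effect of that exposure on the outcome
#' conditional on the others; in the drug-target cascade the matrix holds one
#' gene-expression column and one mediator column, so the gene coefficient is
#' the gene's direct (non-mediated) effect.  Standard errors come from the
#' fixed-weight information matrix (mediator-beta uncertainty is not
#' propagated) and p-values from the normal approximation.  With a single
#' exposure column the result equals univariable fixed-effect [ivw()] on the
#' same rows.
#'
#' @param exposure_beta numeric matrix (SNPs x exposures) of harmonized
#'   per-exposure betas; column names identify the exposures.
#' @param beta_outcome,se_outcome outcome betas and standard errors on the
#'   same allele frame.
#' @param exposure_ids exposure names (defaults to `colnames(exposure_beta)`).
#' @return `mvmr_result`: data.frame with one row per exposure (`exposure`,
#'   `beta`, `se`, `pvalue`) and the instrument count in `attr(, "n_snp")`.
#' @export
mvmr_ivw <- function(exposure_beta, beta_outcome, se_outcome,
                     exposure_ids = colnames(exposure_beta)) {
  x <- as.matrix(exposure_beta)
  if (is.null(exposure_ids)) exposure_ids <- paste0("exposure_", seq_len(ncol(x)))
  k <- nrow(x); p <- ncol(x)
  stopifnot(length(beta_outcome) == k, length(se_outcome) == k, all(se_outcome > 0))
  if (k < p + 1L) {
    stop_mrtriage(
      sprintf("multivariable IVW needs at least %d SNPs for %d exposures, got %d",
              p + 1L, p, k),
      "mrtriage_insufficient_instruments"
    )
  }
  w <- 1 / se_outcome^2
  xw <- x * sqrt(w)
  qr_x <- qr(xw)
  if (qr_x$rank < p) {
    bad <- exposure_ids[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop_mrtriage(
      paste0("collinear exposure column(s): ", paste(bad, collapse = ", ")),
      "mrtriage_collinearity_error"
    )
  }
  xtwx <- crossprod(xw)
  coefs <- solve(xtwx, crossprod(x * w, beta_outcome))[, 1]
  se <- sqrt(diag(solve(xtwx)))
  out <- data.frame(
    exposure = exposure_ids,
    beta = as.numeric(coefs),
    se = se,
    pvalue = z_to_p(coefs / se),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_snp") <- k
  class(out) <- c("mvmr_result", "data.frame")
  out
}

#' Build a multivariable MR instrument table from three summary-stats sets
#'
#' Harmonizes the mediator and the outcome to the gene exposure's allele
#' frame over the given instrument SNPs (the union of the gene's and the
#' mediator's clumped instruments) and assembles the SNPs present in all
#' three sets.
#'
#' @param gene,mediator,outcome [sumstats()] objects.
#' @param snps instrument SNP ids to use.
#' @param ... passed to [harmonize()].
#' @return list with `exposure_beta` (matrix with columns `gene`,
#'   `mediator`), `beta_outcome`, `se_outcome`, `snp_id`.
#' @export
mvmr_input <- function(gene, mediator, outcome, snps, ...) {
  sub <- function(ss, keep) {
    ss$records <- ss$records[ss$records$snp_id %in% keep, , drop = FALSE]
    ss
  }
  hm <- harmonize(sub(gene, snps), sub(mediator, snps), ...)
  ho <- harmonize(sub(gene, snps), sub(outcome, snps), ...)
  shared <- intersect(hm$snp_id, ho$snp_id)
  if (length(shared) == 0L) {
    stop_mrtriage("no instruments present in all three datasets",
                  "mrtriage_no_instruments")
  }
  hm <- hm[match(shared, hm$snp_id), ]
  ho <- ho[match(shared, ho$snp_id), ]
  list(
    exposure_beta = cbind(gene = hm$beta_exposure, mediator = hm$beta_outcome),
    beta_outcome = ho$beta_outcome,
    se_outcome = ho$se_outcome,
    snp_id = shared
  )
}
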