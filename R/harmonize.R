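#' Align exposure and outcome summary statistics to a common effect allele
#'
#' Shared SNPs are re-expressed on the exposure's effect allele: when the
#' outcome reports the same pair of alleles with roles swapped (directly or on
#' the opposite strand) its beta is negated and its effect-allele frequency
#' complemented.  Palindromic SNPs (A/T or C/G) cannot be strand-resolved from
#' alleles alone; under the default policy they are dropped when the minor
#' allele frequency in either study exceeds `eaf_threshold` or when a
#' frequency is missing, and otherwise oriented by frequency agreement.
#'
#' @param exposure,outcome [sumstats()] objects.
#' @param palindrome_policy `"drop_ambiguous"` (default, described above),
#'   `"drop_all"` (drop every palindromic SNP), or `"keep"` (trust identical
#'   strand coding).
#' @param eaf_threshold minor-allele-frequency ceiling above which a
#'   palindromic SNP is considered ambiguous (default 0.42, the conventional
#'   TwoSampleMR cutoff).
#' @return a `harmonized_pairs` data.frame with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `pvalue_exposure`, `beta_outcome`, `se_outcome`, `pvalue_outcome`, `eaf`
#'   (exposure frequency) and `action_taken`; dropped SNPs and their reasons
#'   are kept in `attr(, "dropped")`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all", "keep"),
                      eaf_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  ou <- outcome$records
  if (nrow(ex) == 0L || nrow(ou) == 0L) {
    stop_mrtriage("empty summary statistics", "mrtriage_empty_input")
  }
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (length(shared) == 0L) {
    stop_mrtriage("no shared SNPs between exposure and outcome",
                  "mrtriage_no_instruments")
  }
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- comp[ex$effect_allele] == ex$other_allele

  same  <- (ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele) |
           (comp[ou$effect_allele] == ex$effect_allele & comp[ou$other_allele] == ex$other_allele)
  swap  <- (ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele) |
           (comp[ou$effect_allele] == ex$other_allele & comp[ou$other_allele] == ex$effect_allele)

  action <- rep(NA_character_, length(shared))
  flip <- rep(FALSE, length(shared))

  # non-palindromic: allele patterns identify orientation uniquely
  action[!pal & same] <- "kept"
  action[!pal & swap & !same] <- "flipped"
  flip[!pal & swap & !same] <- TRUE
  action[!pal & !same & !swap] <- "dropped_mismatch"

  # palindromic: same & swap are indistinguishable from alleles
  if (any(pal)) {
    if (palindrome_policy == "drop_all") {
      action[pal] <- "dropped_palindromic"
    } else if (palindrome_policy == "keep") {
      action[pal] <- ifelse(same[pal] | swap[pal], "kept", "dropped_mismatch")
    } else {
      maf_x <- pmin(ex$eaf, 1 - ex$eaf)
      maf_y <- pmin(ou$eaf, 1 - ou$eaf)
      ambiguous <- is.na(ex$eaf) | is.na(ou$eaf) |
        maf_x > eaf_threshold | maf_y > eaf_threshold
      keepable <- pal & (same | swap)
      action[pal & !keepable] <- "dropped_mismatch"
      action[keepable & ambiguous] <- "dropped_palindromic"
      resolve <- keepable & !ambiguous
      # frequencies on the same side of 0.5 => same allele is the effect allele
      agree <- (ex$eaf - 0.5) * (ou$eaf - 0.5) >= 0
      action[resolve & agree] <- "kept"
      action[resolve & !agree] <- "flipped"
      flip[resolve & !agree] <- TRUE
    }
  }

  kept <- !startsWith(action, "dropped")
  out <- data.frame(
    snp_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pvalue_exposure = ex$pvalue,
    beta_outcome = ifelse(flip, -ou$beta, ou$beta),
    se_outcome = ou$se,
    pvalue_outcome = ou$pvalue,
    eaf = ex$eaf,
    action_taken = action,
    stringsAsFactors = FALSE
  )[kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  attr(out, "dropped") <- data.frame(
    snp_id = shared[!kept], reason = action[!kept], stringsAsFactors = FALSE
  )
  out
}
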