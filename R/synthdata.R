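#' @title Summary-statistics simulator with a known causal graph
#' @name synthdata
#' @description
#' Generates GWAS/eQTL summary statistics directly at the summary level (no
#' individual genotypes) under the causal graph
#' instruments -> gene expression -> mediator -> outcome, with optional
#' pleiotropy, over-dispersion, and linkage confounding.  Standard errors
#' follow the analytic single-SNP formulas: `1 / sqrt(2 maf (1 - maf) n)` for
#' a quantitative trait and `sqrt(4 / (n_eff * 2 maf (1 - maf)))` for a
#' case-control trait with effective size `n_eff = 4 / (1/cases +
#' 1/controls)`.  Each gene carries a cis locus with AR(1) LD (for SMR and
#' HEIDI) plus a panel of mutually independent instrument loci placed outside
#' the clumping window (for TSMR and MVMR); sampling noise is drawn
#' multivariate normal with the LD-implied correlation within each cis block.
NULL

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a biobank-scale drug-target
#' screen: a ~30k-sample eQTL panel, a mediator GWAS with 10 154 cases and
#' 454 764 controls, and a rare-outcome GWAS with 216 528 subjects of which
#' 100 are cases, with a mediator -> outcome effect of 1.8 on the log-odds
#' scale.
#'
#' @param n_genes number of exposure genes.
#' @param a length-`n_genes` gene -> mediator effects (per SD of expression).
#' @param delta length-`n_genes` direct gene -> outcome effects.
#' @param b mediator -> outcome effect (log-odds per log-odds).
#' @param n_instruments independent instruments per gene.
#' @param n_cis_snps SNPs in each gene's cis locus.
#' @param cis_beta eQTL effect of the cis causal variant (SD units).
#' @param instrument_beta_range magnitude range of instrument eQTL effects
#'   (signs random).
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param n_eqtl eQTL panel sample size.
#' @param n_mediator_cases,n_mediator_controls mediator GWAS case-control split.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS case-control split.
#' @param n_mediator_instruments genome-wide mediator instruments (for the
#'   mediator -> outcome leg and for MVMR).
#' @param mediator_instrument_beta_range magnitude range of their effects.
#' @param ld_rho AR(1) correlation between adjacent cis SNPs.
#' @param pleiotropy list(`type` in `"none"`/`"balanced"`/`"directional"`,
#'   `scale`): per-instrument direct effects on the mediator bypassing
#'   expression; balanced is mean-zero with sd `scale`, directional has mean
#'   `scale` and sd `scale / 2`.
#' @param heterogeneity_multiplier inflates mediator sampling noise relative
#'   to its reported SE (1 = calibrated; > 1 = over-dispersed instruments).
#' @param linkage length-`n_genes` logical: add a second cis causal variant
#'   (adjacent to the eQTL causal SNP, hence at LD r = `ld_rho`) affecting
#'   the mediator only, the confounding configuration HEIDI must flag.
#' @param linkage_med_beta mediator effect of that second variant.
#' @param palindromic_frac fraction of SNPs given A/T or C/G alleles.
#' @param flip_prob probability that the mediator / outcome study reports a
#'   SNP on the opposite allele (exercises harmonization).
#' @param gene_symbols symbols per gene; empty strings mark symbol-less
#'   transcripts dropped by the screen.
#' @param seed mandatory master seed.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 20,
                       a = rep(0.15, n_genes),
                       delta = rep(0, n_genes),
                       b = 1.8,
                       n_instruments = 30,
                       n_cis_snps = 15,
                       cis_beta = 0.7,
                       instrument_beta_range = c(0.08, 0.2),
                       maf_range = c(0.1, 0.5),
                       n_eqtl = 30000,
                       n_mediator_cases = 10154,
                       n_mediator_controls = 454764,
                       n_outcome_cases = 100,
                       n_outcome_controls = 216428,
                       n_mediator_instruments = 60,
                       mediator_instrument_beta_range = c(0.09, 0.18),
                       ld_rho = 0.8,
                       pleiotropy = list(type = "none", scale = 0),
                       heterogeneity_multiplier = 1,
                       linkage = rep(FALSE, n_genes),
                       linkage_med_beta = 0.15,
                       palindromic_frac = 0.05,
                       flip_prob = 0.3,
                       gene_symbols = sprintf("GENE%02d", seq_len(n_genes)),
                       seed) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(!missing(seed) && is.finite(seed), "seed: mandatory finite integer")
  chk(n_genes >= 1, "n_genes: must be >= 1")
  chk(length(a) == n_genes, "a: one effect per gene")
  chk(length(delta) == n_genes, "delta: one effect per gene")
  chk(length(linkage) == n_genes, "linkage: one flag per gene")
  chk(length(gene_symbols) == n_genes, "gene_symbols: one per gene")
  chk(all(maf_range > 0) && all(maf_range <= 0.5) && diff(maf_range) >= 0,
      "maf_range: must lie in (0, 0.5]")
  chk(all(c(n_eqtl, n_mediator_cases, n_mediator_controls,
            n_outcome_cases, n_outcome_controls) > 0),
      "sample sizes: must be > 0")
  chk(abs(ld_rho) < 1, "ld_rho: |rho| < 1")
  chk(pleiotropy$type %in% c("none", "balanced", "directional"),
      "pleiotropy$type: none/balanced/directional")
  chk(heterogeneity_multiplier > 0, "heterogeneity_multiplier: must be > 0")
  chk(palindromic_frac >= 0 && palindromic_frac <= 1, "palindromic_frac: in [0,1]")
  chk(flip_prob >= 0 && flip_prob <= 1, "flip_prob: in [0,1]")
  if (length(problems) > 0L) {
    stop_mrtriage(paste0("invalid simulation config:\n  ",
                         paste(problems, collapse = "\n  ")),
                  "mrtriage_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' The standard synthetic scenario
#'
#' Twenty genes: 12 mediation-only genes (`a` = 0.15, `delta` = 0), 3 genes
#' with a strong direct effect on the outcome (`a` = 0.15, `delta` = 1.5,
#' expected to be flagged `total_significant`), and 5 null genes.  All other
#' parameters at [sim_config()] defaults.
#'
#' @param seed master seed.
#' @return `sim_config`.
#' @export
standard_scenario <- function(seed) {
  sim_config(
    n_genes = 20,
    a = c(rep(0.15, 15), rep(0, 5)),
    delta = c(rep(0, 12), rep(1.5, 3), rep(0, 5)),
    seed = seed
  )
}

n_effective <- function(cases, controls) 4 / (1 / cases + 1 / controls)

se_quantitative <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

se_case_control <- function(maf, n_eff) sqrt(4 / (n_eff * 2 * maf * (1 - maf)))

ar1_matrix <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# correlated noise: independent N(0, se^2) everywhere except within the given
# blocks, where the correlation is the block's LD matrix
draw_noise <- function(se, blocks) {
  eps <- stats::rnorm(length(se)) * se
  for (bl in blocks) {
    k <- length(bl$idx)
    z <- MASS::mvrnorm(1, mu = rep(0, k), Sigma = bl$r)
    eps[bl$idx] <- z * se[bl$idx]
  }
  eps
}

NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2, byrow = TRUE)

#' Simulate a full drug-target MR study
#'
#' Produces everything [run_cascade()] consumes: one eQTL [sumstats()] per
#' gene (cis locus + independent instruments + null coverage of every other
#' SNP), a mediator and an outcome [sumstats()] covering all SNPs, a global
#' [ld_matrix()], per-gene cis-SNP lists, and a truth table recording each
#' gene's generating effects and expected classification.
#'
#' @param config a [sim_config()].
#' @return list with elements `genes` (named list of
#'   `list(sumstats, cis_snps, symbol)`), `mediator`, `outcome`, `ld`,
#'   `truth` (data.frame), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    gene_ids <- sprintf("G%02d", seq_len(cf$n_genes))

    # ---- SNP registry -----------------------------------------------------
    reg <- list()
    for (g in seq_len(cf$n_genes)) {
      chrom <- as.character((g - 1L) %% 22L + 1L)
      m <- cf$n_cis_snps
      reg[[length(reg) + 1L]] <- data.frame(
        snp_id = sprintf("g%02d_cis%02d", g, seq_len(m)),
        chrom = chrom, pos = 1e6 + (seq_len(m) - 1L) * 5000,
        gene = g, role = "cis", stringsAsFactors = FALSE
      )
      reg[[length(reg) + 1L]] <- data.frame(
        snp_id = sprintf("g%02d_iv%02d", g, seq_len(cf$n_instruments)),
        chrom = chrom,
        pos = 2e7 + (seq_len(cf$n_instruments) - 1L) * 1.1e7,
        gene = g, role = "iv", stringsAsFactors = FALSE
      )
    }
    reg[[length(reg) + 1L]] <- data.frame(
      snp_id = sprintf("med_iv%02d", seq_len(cf$n_mediator_instruments)),
      chrom = as.character((seq_len(cf$n_mediator_instruments) - 1L) %% 22L + 1L),
      pos = 6e8 + ((seq_len(cf$n_mediator_instruments) - 1L) %/% 22L) * 1.1e7,
      gene = 0L, role = "med_iv", stringsAsFactors = FALSE
    )
    reg <- do.call(rbind, reg)
    n_snp <- nrow(reg)

    maf <- stats::runif(n_snp, cf$maf_range[1], cf$maf_range[2])
    eaf <- ifelse(stats::runif(n_snp) < 0.5, maf, 1 - maf)
    pal <- stats::runif(n_snp) < cf$palindromic_frac
    pair_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_snp, replace = TRUE)
    ea <- ifelse(pal, ifelse(stats::runif(n_snp) < 0.5, "A", "C"),
                 NONPALINDROMIC_PAIRS[pair_idx, 1])
    oa <- ifelse(pal, ifelse(ea == "A", "T", "G"), NONPALINDROMIC_PAIRS[pair_idx, 2])

    # ---- LD: AR(1) within each cis block, independence elsewhere ----------
    blocks <- lapply(seq_len(cf$n_genes), function(g) {
      idx <- which(reg$gene == g & reg$role == "cis")
      list(idx = idx, r = ar1_matrix(length(idx), cf$ld_rho))
    })
    r_global <- diag(n_snp)
    for (bl in blocks) r_global[bl$idx, bl$idx] <- bl$r
    ld <- ld_matrix(r_global, snp_ids = reg$snp_id)

    # ---- true effects -----------------------------------------------------
    cis_causal <- ceiling(cf$n_cis_snps / 2)
    beta_eqtl_true <- matrix(0, cf$n_genes, n_snp)   # gene x snp
    for (g in seq_len(cf$n_genes)) {
      ci <- which(reg$gene == g & reg$role == "cis")
      beta_eqtl_true[g, ci] <- cf$ld_rho^abs(seq_along(ci) - cis_causal) * cf$cis_beta
      iv <- which(reg$gene == g & reg$role == "iv")
      mag <- stats::runif(length(iv), cf$instrument_beta_range[1],
                          cf$instrument_beta_range[2])
      beta_eqtl_true[g, iv] <- mag * sample(c(-1, 1), length(iv), replace = TRUE)
    }
    med_iv_idx <- which(reg$role == "med_iv")
    gamma <- stats::runif(length(med_iv_idx),
                          cf$mediator_instrument_beta_range[1],
                          cf$mediator_instrument_beta_range[2]) *
      sample(c(-1, 1), length(med_iv_idx), replace = TRUE)

    med_true <- drop(crossprod(beta_eqtl_true, cf$a))
    med_true[med_iv_idx] <- med_true[med_iv_idx] + gamma
    if (cf$pleiotropy$type != "none") {
      iv_idx <- which(reg$role == "iv")
      pl <- switch(cf$pleiotropy$type,
        balanced = stats::rnorm(length(iv_idx), 0, cf$pleiotropy$scale),
        directional = stats::rnorm(length(iv_idx), cf$pleiotropy$scale,
                                   cf$pleiotropy$scale / 2))
      med_true[iv_idx] <- med_true[iv_idx] + pl
    }
    for (g in which(cf$linkage)) {
      ci <- which(reg$gene == g & reg$role == "cis")
      c2 <- cis_causal + 1L
      med_true[ci] <- med_true[ci] +
        cf$ld_rho^abs(seq_along(ci) - c2) * cf$linkage_med_beta
    }
    out_true <- cf$b * med_true + drop(crossprod(beta_eqtl_true, cf$delta))

    # ---- standard errors and observed estimates ---------------------------
    se_eqtl <- se_quantitative(maf, cf$n_eqtl)
    se_med <- se_case_control(maf, n_effective(cf$n_mediator_cases,
                                               cf$n_mediator_controls))
    se_out <- se_case_control(maf, n_effective(cf$n_outcome_cases,
                                               cf$n_outcome_controls))

    obs <- function(true, se) true + draw_noise(se, blocks)
    make_records <- function(beta, se, n, flip = rep(FALSE, n_snp)) {
      data.frame(
        snp_id = reg$snp_id, chrom = reg$chrom, pos = reg$pos,
        effect_allele = ifelse(flip, oa, ea),
        other_allele = ifelse(flip, ea, oa),
        eaf = ifelse(flip, 1 - eaf, eaf),
        beta = ifelse(flip, -beta, beta),
        se = se, pvalue = z_to_p(beta / se), n = n,
        stringsAsFactors = FALSE
      )
    }

    genes <- vector("list", cf$n_genes)
    names(genes) <- gene_ids
    for (g in seq_len(cf$n_genes)) {
      beta_hat <- obs(beta_eqtl_true[g, ], se_eqtl)
      genes[[g]] <- list(
        sumstats = sumstats(gene_ids[g], "eqtl_gene",
                            make_records(beta_hat, se_eqtl, cf$n_eqtl),
                            gene_symbol = cf$gene_symbols[g]),
        cis_snps = reg$snp_id[reg$gene == g & reg$role == "cis"],
        symbol = cf$gene_symbols[g]
      )
    }
    flip_med <- stats::runif(n_snp) < cf$flip_prob
    flip_out <- stats::runif(n_snp) < cf$flip_prob
    med_hat <- med_true + draw_noise(se_med, blocks) * cf$heterogeneity_multiplier
    out_hat <- obs(out_true, se_out)
    mediator <- sumstats("mediator", "mediator",
                         make_records(med_hat, se_med,
                                      cf$n_mediator_cases + cf$n_mediator_controls,
                                      flip_med))
    outcome <- sumstats("outcome", "outcome",
                        make_records(out_hat, se_out,
                                     cf$n_outcome_cases + cf$n_outcome_controls,
                                     flip_out))

    truth <- data.frame(
      gene_id = gene_ids, symbol = cf$gene_symbols,
      a = cf$a, delta = cf$delta, b = cf$b,
      mediated = cf$a * cf$b,
      linkage = cf$linkage,
      category = ifelse(cf$a == 0 & cf$delta == 0, "none",
                        ifelse(cf$delta != 0, "total_significant",
                               "mediation_only")),
      stringsAsFactors = FALSE
    )

    list(genes = genes, mediator = mediator, outcome = outcome,
         ld = ld, truth = truth, config = cf)
  })
}

#' Simulate a cis locus for HEIDI evaluation
#'
#' Two configurations over an AR(1) locus: `"pleiotropy"` has a single
#' causal variant driving both expression and the trait (effects exactly
#' proportional, the null HEIDI should not reject), while `"linkage"` has a
#' second causal variant adjacent to the eQTL variant (LD r = `rho`) driving
#' the trait only (the alternative HEIDI should flag).
#'
#' @param scenario `"pleiotropy"` or `"linkage"`.
#' @param n_snps locus size (default 15).
#' @param rho AR(1) LD parameter; in the linkage scenario this is also the
#'   correlation between the two causal variants.
#' @param eqtl_beta causal eQTL effect (default 0.4).
#' @param bxy expression -> trait effect scale: the causal trait effect is
#'   `bxy * eqtl_beta` in both scenarios (default 0.3).
#' @param maf shared minor-allele frequency (default 0.3).
#' @param n_eqtl,n_gwas_cases,n_gwas_controls sample sizes (defaults match
#'   [sim_config()]).
#' @param noise add sampling noise (default `TRUE`; `FALSE` gives the
#'   zero-noise proportional locus where T_HEIDI is exactly 0 under
#'   pleiotropy).
#' @param seed RNG seed.
#' @return list with `eqtl`, `gwas` (data.frames with `snp_id`, `beta`,
#'   `se`, `pvalue`) and `ld`.
#' @export
simulate_heidi_locus <- function(scenario = c("pleiotropy", "linkage"),
                                 n_snps = 15, rho = 0.8,
                                 eqtl_beta = 0.4, bxy = 0.3, maf = 0.3,
                                 n_eqtl = 30000,
                                 n_gwas_cases = 10154, n_gwas_controls = 454764,
                                 noise = TRUE, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_snps >= 10)
  snp_id <- sprintf("loc%02d", seq_len(n_snps))
  r <- ar1_matrix(n_snps, rho)
  c1 <- ceiling(n_snps / 2)
  eqtl_true <- r[, c1] * eqtl_beta
  c2 <- if (scenario == "linkage") c1 + 1L else c1
  gwas_true <- r[, c2] * (bxy * eqtl_beta)
  se_e <- rep(se_quantitative(maf, n_eqtl), n_snps)
  se_g <- rep(se_case_control(maf, n_effective(n_gwas_cases, n_gwas_controls)),
              n_snps)
  eps <- if (noise) {
    with_seed(seed, list(
      e = drop(MASS::mvrnorm(1, rep(0, n_snps), r)) * se_e,
      g = drop(MASS::mvrnorm(1, rep(0, n_snps), r)) * se_g
    ))
  } else list(e = 0, g = 0)
  be <- eqtl_true + eps$e
  bg <- gwas_true + eps$g
  list(
    eqtl = data.frame(snp_id = snp_id, beta = be, se = se_e,
                      pvalue = z_to_p(be / se_e), stringsAsFactors = FALSE),
    gwas = data.frame(snp_id = snp_id, beta = bg, se = se_g,
                      pvalue = z_to_p(bg / se_g), stringsAsFactors = FALSE),
    ld = ld_matrix(r, snp_ids = snp_id)
  )
}

#' Simulate a harmonized instrument table directly
#'
#' Instrument-level view of the same generative model as
#' [simulate_study()], for estimator calibration: `k` independent
#' instruments with exposure effects drawn from `beta_range`, outcome betas
#' `true_beta * beta_exposure + pleiotropy + noise`, and analytic standard
#' errors from the given sample sizes.
#'
#' @param k instruments.
#' @param true_beta causal exposure -> outcome effect.
#' @param n_exposure_eff,n_outcome_eff effective sample sizes for the two
#'   studies (defaults: the mediator and outcome scales of [sim_config()]).
#' @param beta_range exposure-effect magnitude range; the default keeps every
#'   instrument genome-wide significant at the worst-case MAF, consistent
#'   with the post-clumping contract of a harmonized instrument table.
#' @param maf_range minor-allele-frequency range.
#' @param pleiotropy_mean,pleiotropy_sd per-instrument direct outcome
#'   effects (defaults 0: valid instruments); the mean acts along the
#'   exposure-increasing direction of each instrument (directional
#'   pleiotropy as the Egger intercept defines it).
#' @param het_multiplier outcome noise inflation (default 1).
#' @param seed RNG seed.
#' @return a `harmonized_pairs` data.frame.
#' @export
simulate_tsmr_pairs <- function(k = 30, true_beta = 1.8,
                                n_exposure_eff = n_effective(10154, 454764),
                                n_outcome_eff = n_effective(100, 216428),
                                beta_range = c(0.2, 0.35),
                                maf_range = c(0.1, 0.5),
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                het_multiplier = 1, seed = 1) {
  with_seed(seed, {
    maf <- stats::runif(k, maf_range[1], maf_range[2])
    se_x <- se_case_control(maf, n_exposure_eff)
    se_y <- se_case_control(maf, n_outcome_eff)
    bx_true <- stats::runif(k, beta_range[1], beta_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    # directional pleiotropy acts relative to the exposure-increasing allele,
    # so it survives the Egger orientation convention
    pl <- stats::rnorm(k, pleiotropy_mean, pleiotropy_sd) * sign(bx_true)
    bx <- bx_true + stats::rnorm(k, 0, se_x)
    by <- true_beta * bx_true + pl + stats::rnorm(k, 0, se_y * het_multiplier)
    out <- data.frame(
      snp_id = sprintf("iv%03d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      beta_exposure = bx, se_exposure = se_x,
      pvalue_exposure = z_to_p(bx / se_x),
      beta_outcome = by, se_outcome = se_y,
      pvalue_outcome = z_to_p(by / se_y),
      eaf = 1 - maf, action_taken = "kept",
      stringsAsFactors = FALSE
    )
    class(out) <- c("harmonized_pairs", "data.frame")
    out
  })
}
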