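#' @title The staged screening cascade
#' @name cascade
#' @description
#' Orchestrates the full screen: SMR + HEIDI + symbol filter on every gene,
#' per-gene TSMR validation against the mediator under a stage-wise
#' Bonferroni threshold, a single mediator -> outcome TSMR estimate, total
#' and direct (MVMR) gene -> outcome effects, the product-of-coefficients
#' mediation decomposition with distribution-of-product CIs, and the final
#' classification.  Every Bonferroni denominator is the realized count of
#' genes entering that stage, never a hard-coded constant, and every
#' stochastic step is seeded from the config so a rerun is byte-identical.
NULL

#' Cascade configuration
#'
#' @param smr_p SMR screening threshold (default 0.05).
#' @param heidi_p HEIDI retention threshold: genes with `p_heidi >` this pass
#'   (default 0.05).
#' @param clump_p,clump_kb,clump_r2 instrument-selection parameters
#'   (defaults 5e-8, 10000 kb, 0.001).
#' @param alpha family-wise level divided by realized stage counts
#'   (default 0.05).
#' @param heidi_draws Monte Carlo draws for each HEIDI null (default 2e4).
#' @param n_boot bootstrap draws in the sensitivity suite (default 1000).
#' @param run_heidi toggle the HEIDI stage (default `TRUE`).
#' @param require_symbol toggle the gene-symbol filter (default `TRUE`).
#' @param seed master seed; per-gene seeds are derived deterministically.
#' @return `cascade_config` list.
#' @export
cascade_config <- function(smr_p = 0.05, heidi_p = 0.05,
                           clump_p = 5e-8, clump_kb = 10000, clump_r2 = 0.001,
                           alpha = 0.05, heidi_draws = 2e4, n_boot = 1000,
                           run_heidi = TRUE, require_symbol = TRUE, seed = 1) {
  stopifnot(smr_p > 0, smr_p <= 1, heidi_p >= 0, heidi_p < 1,
            clump_p > 0, clump_kb > 0, clump_r2 >= 0, clump_r2 <= 1,
            alpha > 0, alpha < 1, heidi_draws >= 1000, n_boot >= 1,
            is.finite(seed))
  structure(as.list(environment()), class = "cascade_config")
}

stage_report <- function(stage, n_in, n_out, threshold, denominator, verdicts) {
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 threshold = threshold, denominator = denominator,
                 verdicts = verdicts),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage %-14s> %3d -> %3d (threshold %s, denominator %s)\n",
              x$stage, x$n_in, x$n_out,
              paste(format(x$threshold, digits = 3), collapse = "/"),
              paste(x$denominator, collapse = "/")))
  invisible(x)
}

# TSMR for one gene against one trait over pre-clumped instruments:
# full sensitivity suite when >= 3 instruments survive harmonization,
# IVW-MRE at 2, Wald ratio at 1
gene_tsmr <- function(gene_ss, trait_ss, instruments, n_boot, seed) {
  sub <- gene_ss
  sub$records <- sub$records[sub$records$snp_id %in% instruments, , drop = FALSE]
  hp <- tryCatch(harmonize(sub, trait_ss),
                 mrtriage_no_instruments = function(e) NULL)
  k <- if (is.null(hp)) 0L else nrow(hp)
  if (k == 0L) return(NULL)
  if (k >= 3L) {
    rep <- sensitivity_suite(hp, n_boot = n_boot, seed = seed)
    est <- rep$estimates$ivw_mre
    list(est = est, recommended = rep$recommended_method,
         Q = rep$Q, p_Q = rep$p_Q, p_intercept = rep$p_intercept, n_snp = k)
  } else {
    est <- if (k == 2L) ivw(hp, "mre") else wald_ratio(hp)
    list(est = est, recommended = est$method,
         Q = NA_real_, p_Q = NA_real_, p_intercept = NA_real_, n_snp = k)
  }
}

#' Run the full screening cascade
#'
#' @param bundle a data bundle as produced by [simulate_study()]: per-gene
#'   eQTL [sumstats()] with cis-SNP lists and symbols, mediator and outcome
#'   [sumstats()], and a global [ld_matrix()].
#' @param config a [cascade_config()].
#' @return `mr_cascade` object: list with `stages` (ordered
#'   [stage_report()]s), `b` (the shared mediator -> outcome `mr_estimate`),
#'   `genes` (final per-gene table with decomposition and category),
#'   `manifest` (seed, thresholds, realized stage counts), and `config`.
#' @export
run_cascade <- function(bundle, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  stages <- list()
  gene_ids <- names(bundle$genes)

  finish <- function(genes_df, b_est = NULL) {
    counts <- vapply(stages, function(s) s$n_out, numeric(1))
    names(counts) <- vapply(stages, function(s) s$stage, character(1))
    structure(
      list(stages = stages, b = b_est, genes = genes_df,
           manifest = list(seed = config$seed, alpha = config$alpha,
                           stage_counts = counts),
           config = config),
      class = "mr_cascade"
    )
  }
  empty_genes <- data.frame()

  # ---- stage 1: SMR + HEIDI + symbol ------------------------------------
  screen_rows <- lapply(seq_along(gene_ids), function(i) {
    gb <- bundle$genes[[i]]
    cis <- gb$cis_snps
    sub <- gb$sumstats
    sub$records <- sub$records[sub$records$snp_id %in% cis, , drop = FALSE]
    hp <- harmonize(sub, bundle$mediator)
    top <- hp[order(hp$pvalue_exposure,
                    -abs(hp$beta_exposure / hp$se_exposure),
                    hp$snp_id)[1L], ]
    smr <- smr_test(top$beta_exposure, top$se_exposure,
                    top$beta_outcome, top$se_outcome)
    p_heidi <- NA_real_
    n_heidi <- NA_integer_
    if (config$run_heidi) {
      hd <- heidi_test(
        eqtl = data.frame(snp_id = hp$snp_id, beta = hp$beta_exposure,
                          se = hp$se_exposure, pvalue = hp$pvalue_exposure),
        gwas = data.frame(snp_id = hp$snp_id, beta = hp$beta_outcome,
                          se = hp$se_outcome),
        ld = ld_subset(bundle$ld, hp$snp_id),
        n_draws = config$heidi_draws, seed = config$seed + i
      )
      p_heidi <- hd$p_heidi
      n_heidi <- hd$n_heidi_snps
    }
    data.frame(gene_id = gene_ids[i], gene_symbol = gb$symbol,
               top_snp = top$snp_id, b_xy = smr$b_xy, se_xy = smr$se_xy,
               p_smr = smr$p_smr, p_heidi = p_heidi, n_heidi_snps = n_heidi,
               stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, screen_rows)
  if (!config$run_heidi) screen$p_heidi <- 1  # stage disabled: everyone passes
  screened <- smr_screen(screen, smr_p = config$smr_p, heidi_p = config$heidi_p,
                         require_symbol = config$require_symbol)
  stages[[length(stages) + 1L]] <- stage_report(
    "smr_heidi", nrow(screened), sum(screened$pass),
    c(smr_p = config$smr_p, heidi_p = config$heidi_p),
    NA_real_, screened
  )
  surv1 <- screened$gene_id[screened$pass]
  if (length(surv1) == 0L) return(finish(empty_genes))

  # ---- stage 2: TSMR gene -> mediator, Bonferroni over entrants ---------
  n2 <- length(surv1)
  thr2 <- config$alpha / n2
  inst <- list()
  rows2 <- list()
  for (i in seq_along(surv1)) {
    gid <- surv1[i]
    gb <- bundle$genes[[gid]]
    snps <- clump(gb$sumstats, bundle$ld, p_thresh = config$clump_p,
                  window_kb = config$clump_kb, r2_thresh = config$clump_r2)
    fit <- if (length(snps) > 0L) {
      gene_tsmr(gb$sumstats, bundle$mediator, snps,
                n_boot = config$n_boot, seed = config$seed + 1000L + i)
    }
    inst[[gid]] <- snps
    rows2[[i]] <- data.frame(
      gene_id = gid,
      n_instruments = length(snps),
      beta_a = if (is.null(fit)) NA_real_ else fit$est$beta,
      se_a = if (is.null(fit)) NA_real_ else fit$est$se,
      p_a = if (is.null(fit)) NA_real_ else fit$est$pvalue,
      n_snp = if (is.null(fit)) 0L else fit$n_snp,
      Q = if (is.null(fit)) NA_real_ else fit$Q,
      p_Q = if (is.null(fit)) NA_real_ else fit$p_Q,
      p_intercept = if (is.null(fit)) NA_real_ else fit$p_intercept,
      recommended = if (is.null(fit)) "no_instruments" else fit$recommended,
      stringsAsFactors = FALSE
    )
  }
  tab2 <- do.call(rbind, rows2)
  tab2$pass <- !is.na(tab2$p_a) & tab2$p_a < thr2
  stages[[length(stages) + 1L]] <- stage_report(
    "tsmr_mediator", n2, sum(tab2$pass), thr2, n2, tab2
  )
  surv2 <- tab2$gene_id[tab2$pass]
  if (length(surv2) == 0L) return(finish(empty_genes))

  # ---- stage 3: mediator -> outcome (estimated once, reused for all) ----
  med_inst <- clump(bundle$mediator, bundle$ld, p_thresh = config$clump_p,
                    window_kb = config$clump_kb, r2_thresh = config$clump_r2)
  med_sub <- bundle$mediator
  med_sub$records <- med_sub$records[med_sub$records$snp_id %in% med_inst, , drop = FALSE]
  hp_b <- harmonize(med_sub, bundle$outcome)
  b_est <- ivw(hp_b, "mre")
  stages[[length(stages) + 1L]] <- stage_report(
    "tsmr_mediator_outcome", 1L, 1L, NA_real_, NA_real_,
    data.frame(exposure = "mediator", beta = b_est$beta, se = b_est$se,
               pvalue = b_est$pvalue, n_snp = b_est$n_snp,
               stringsAsFactors = FALSE)
  )

  # ---- stage 4: total gene -> outcome effects ---------------------------
  n4 <- length(surv2)
  thr4 <- config$alpha / n4
  rows4 <- lapply(seq_along(surv2), function(i) {
    gid <- surv2[i]
    fit <- gene_tsmr(bundle$genes[[gid]]$sumstats, bundle$outcome, inst[[gid]],
                     n_boot = config$n_boot, seed = config$seed + 2000L + i)
    data.frame(gene_id = gid,
               total = if (is.null(fit)) NA_real_ else fit$est$beta,
               se_total = if (is.null(fit)) NA_real_ else fit$est$se,
               total_p = if (is.null(fit)) NA_real_ else fit$est$pvalue,
               stringsAsFactors = FALSE)
  })
  tab4 <- do.call(rbind, rows4)
  tab4$significant <- !is.na(tab4$total_p) & tab4$total_p < thr4
  stages[[length(stages) + 1L]] <- stage_report(
    "tsmr_total", n4, n4, thr4, n4, tab4
  )

  # ---- stage 5: MVMR direct effects (gene + mediator jointly) -----------
  rows5 <- lapply(surv2, function(gid) {
    union_snps <- union(inst[[gid]], med_inst)
    mv <- tryCatch({
      inp <- mvmr_input(bundle$genes[[gid]]$sumstats, bundle$mediator,
                        bundle$outcome, union_snps)
      mvmr_ivw(inp$exposure_beta, inp$beta_outcome, inp$se_outcome)
    }, mrtriage_error = function(e) NULL)
    g_row <- if (!is.null(mv)) mv[mv$exposure == "gene", ]
    data.frame(gene_id = gid,
               direct = if (is.null(mv)) NA_real_ else g_row$beta,
               se_direct = if (is.null(mv)) NA_real_ else g_row$se,
               direct_p = if (is.null(mv)) NA_real_ else g_row$pvalue,
               stringsAsFactors = FALSE)
  })
  tab5 <- do.call(rbind, rows5)
  tab5$significant <- !is.na(tab5$direct_p) & tab5$direct_p < thr4
  stages[[length(stages) + 1L]] <- stage_report(
    "mvmr_direct", n4, n4, thr4, n4, tab5
  )

  # ---- stage 6: mediation decomposition and classification --------------
  decomp <- do.call(rbind, lapply(surv2, function(gid) {
    r2 <- tab2[tab2$gene_id == gid, ]
    r4 <- tab4[tab4$gene_id == gid, ]
    r5 <- tab5[tab5$gene_id == gid, ]
    mediation_decomposition(
      gene_id = gid, a = r2$beta_a, se_a = r2$se_a,
      b = b_est$beta, se_b = b_est$se,
      total = r4$total, se_total = r4$se_total, total_p = r4$total_p,
      direct = r5$direct, se_direct = r5$se_direct, direct_p = r5$direct_p,
      n_total = n4, n_direct = n4, alpha = config$alpha
    )
  }))
  decomp$symbol <- vapply(decomp$gene_id,
                          function(g) bundle$genes[[g]]$symbol, character(1))
  stages[[length(stages) + 1L]] <- stage_report(
    "mediation", n4, sum(decomp$category == "mediation_only"),
    NA_real_, n4, decomp
  )
  finish(decomp, b_est)
}

#' @export
print.mr_cascade <- function(x, ...) {
  cat("<mr_cascade>\n")
  for (s in x$stages) print(s)
  if (!is.null(x$b)) {
    cat(sprintf("mediator -> outcome: beta = %.3f (se %.3f)\n", x$b$beta, x$b$se))
  }
  if (nrow(x$genes) > 0) {
    cat("final categories:\n")
    print(table(x$genes$category))
  }
  invisible(x)
}

#' Write cascade stage reports and the run manifest to a directory
#'
#' Emits one TSV per stage, the final gene table, a forest-plot-ready TSV
#' for the mediator -> outcome estimate, and a plain-text manifest with the
#' seed, thresholds and realized stage counts.
#'
#' @param cascade an `mr_cascade`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cascade_report <- function(cascade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (s in cascade$stages) {
    wt(s$verdicts, sprintf("stage_%s.tsv", s$stage))
  }
  if (nrow(cascade$genes) > 0) wt(cascade$genes, "final_genes.tsv")
  if (!is.null(cascade$b)) {
    wt(data.frame(label = "mediator -> outcome",
                  beta = cascade$b$beta, se = cascade$b$se,
                  ci_low = cascade$b$beta - 1.96 * cascade$b$se,
                  ci_high = cascade$b$beta + 1.96 * cascade$b$se,
                  pvalue = cascade$b$pvalue, n_snp = cascade$b$n_snp),
       "forest_mediator_outcome.tsv")
  }
  manifest <- c(
    sprintf("seed\t%s", cascade$manifest$seed),
    sprintf("alpha\t%s", cascade$manifest$alpha),
    sprintf("stage_%s\t%s", names(cascade$manifest$stage_counts),
            cascade$manifest$stage_counts)
  )
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
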