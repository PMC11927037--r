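test_that("invalid configurations are rejected with named fields", {
  err <- tryCatch(sim_config(n_genes = 2, a = c(0.1, 0.2, 0.3), maf_range = c(0, 0.9),
                             seed = 1),
                  error = identity)
  expect_s3_class(err, "mrtriage_config_error")
  expect_match(conditionMessage(err), "a:")
  expect_match(conditionMessage(err), "maf_range")
  expect_error(sim_config(n_genes = 2, a = c(0, 0), delta = c(0, 0),
                          linkage = c(FALSE, FALSE),
                          gene_symbols = c("A", "B")),
               class = "mrtriage_config_error")  # missing seed
})

test_that("reported standard errors follow the analytic formulas exactly", {
  cfg <- sim_config(n_genes = 2, a = c(0.2, 0), delta = c(0, 0),
                    linkage = c(FALSE, FALSE), gene_symbols = c("A", "B"),
                    seed = 5)
  bundle <- simulate_study(cfg)
  rec <- bundle$genes[[1]]$sumstats$records
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  expect_equal(rec$se, 1 / sqrt(2 * maf * (1 - maf) * cfg$n_eqtl), tolerance = 1e-12)
  med <- bundle$mediator$records
  n_eff <- 4 / (1 / cfg$n_mediator_cases + 1 / cfg$n_mediator_controls)
  maf_m <- pmin(med$eaf, 1 - med$eaf)
  expect_equal(med$se, sqrt(4 / (n_eff * 2 * maf_m * (1 - maf_m))), tolerance = 1e-12)
})

test_that("doubling the eQTL sample size shrinks its SEs by exactly sqrt(2)", {
  base <- sim_config(n_genes = 1, a = 0.2, delta = 0, linkage = FALSE,
                     gene_symbols = "A", seed = 9)
  dbl <- sim_config(n_genes = 1, a = 0.2, delta = 0, linkage = FALSE,
                    gene_symbols = "A", n_eqtl = 2 * base$n_eqtl, seed = 9)
  s1 <- simulate_study(base)$genes[[1]]$sumstats$records$se
  s2 <- simulate_study(dbl)$genes[[1]]$sumstats$records$se
  expect_equal(s1 / s2, rep(sqrt(2), length(s1)), tolerance = 1e-12)
})

test_that("identical seeds give byte-identical studies", {
  cfg <- standard_scenario(seed = 77)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- simulate_study(standard_scenario(seed = 78))
  expect_false(identical(serialize(b1, NULL), serialize(b3, NULL)))
})

test_that("null z-scores are standard normal across the generated panels", {
  cfg <- sim_config(n_genes = 15, a = rep(0, 15), delta = rep(0, 15),
                    linkage = rep(FALSE, 15), gene_symbols = sprintf("S%02d", 1:15),
                    n_instruments = 40, seed = 123)
  bundle <- simulate_study(cfg)
  # each gene's eQTL panel is null at every other gene's instrument SNPs,
  # and with a = delta = 0 the mediator and outcome are null at all
  # instrument SNPs; pool the independent ones
  z <- c()
  for (g in seq_along(bundle$genes)) {
    rec <- bundle$genes[[g]]$sumstats$records
    other_iv <- grepl("_iv", rec$snp_id) & !grepl(sprintf("^g%02d", g), rec$snp_id) &
      !grepl("^med", rec$snp_id)
    z <- c(z, rec$beta[other_iv] / rec$se[other_iv])
  }
  iv <- grepl("^g", bundle$mediator$records$snp_id) &
    grepl("_iv", bundle$mediator$records$snp_id)
  z <- c(z, bundle$mediator$records$beta[iv] / bundle$mediator$records$se[iv],
         bundle$outcome$records$beta[iv] / bundle$outcome$records$se[iv])
  expect_gt(length(z), 9000)
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("gene -> mediator TSMR is calibrated for null genes", {
  p <- vapply(1:400, function(i) {
    pairs <- simulate_tsmr_pairs(k = 20, true_beta = 0,
                                 n_exposure_eff = 30000,
                                 n_outcome_eff = 39730, seed = 3000 + i)
    ivw(pairs, "mre")$pvalue
  }, numeric(1))
  reject <- mean(p < 0.05)
  expect_lt(abs(reject - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
})

test_that("heidi locus scenarios expose the intended causal configurations", {
  pl <- simulate_heidi_locus("pleiotropy", noise = FALSE)
  # proportional effects: the GWAS/eQTL ratio is constant across the locus
  ratio <- pl$gwas$beta / pl$eqtl$beta
  expect_lt(diff(range(ratio)), 1e-12)
  ln <- simulate_heidi_locus("linkage", noise = FALSE)
  ratio_ln <- ln$gwas$beta / ln$eqtl$beta
  expect_gt(diff(range(ratio_ln)), 0.1)
  # determinism
  a <- simulate_heidi_locus("linkage", seed = 4)
  b <- simulate_heidi_locus("linkage", seed = 4)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
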