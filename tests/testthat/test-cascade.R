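test_that("the cascade recovers mediation-only genes with clean audit trails", {
  bundle <- simulate_study(standard_scenario(seed = 11))
  cas <- run_cascade(bundle, cascade_config(seed = 11))

  stages <- setNames(cas$stages, vapply(cas$stages, `[[`, "", "stage"))
  # monotone attrition and realized Bonferroni denominators
  gene_stages <- stages[c("smr_heidi", "tsmr_mediator", "tsmr_total",
                          "mvmr_direct", "mediation")]
  n_out <- vapply(gene_stages, `[[`, numeric(1), "n_out")
  expect_true(all(diff(n_out) <= 0))
  for (s in gene_stages) expect_lte(s$n_out, s$n_in)
  expect_equal(stages$tsmr_mediator$denominator, stages$smr_heidi$n_out)
  expect_equal(stages$tsmr_total$denominator, stages$tsmr_mediator$n_out)
  expect_equal(stages$mvmr_direct$denominator, stages$tsmr_mediator$n_out)

  # classification against the generating truth
  truth <- bundle$truth
  med_true <- truth$gene_id[truth$category == "mediation_only"]
  med_est <- cas$genes$gene_id[cas$genes$category == "mediation_only"]
  recovered <- length(intersect(med_est, med_true))
  expect_gte(recovered, ceiling(0.75 * length(med_true)))
  false_pos <- length(setdiff(med_est, med_true))
  expect_lte(false_pos, 1L)

  # the shared mediator -> outcome estimate is in the right neighbourhood
  expect_lt(abs(cas$b$beta - truth$b[1]), 4 * cas$b$se)

  # null genes never reach the final table
  null_genes <- truth$gene_id[truth$category == "none"]
  expect_length(intersect(cas$genes$gene_id, null_genes), 0L)
})

test_that("disabling the HEIDI stage lets linkage-confounded genes through", {
  cfg <- sim_config(n_genes = 6,
                    a = c(0.15, 0.15, 0.15, 0.15, 0, 0),
                    delta = rep(0, 6),
                    linkage = c(rep(FALSE, 4), TRUE, TRUE),
                    gene_symbols = sprintf("L%02d", 1:6),
                    seed = 31)
  bundle <- simulate_study(cfg)
  with_h <- run_cascade(bundle, cascade_config(seed = 31))
  without_h <- run_cascade(bundle, cascade_config(seed = 31, run_heidi = FALSE))
  n_with <- with_h$stages[[1]]$n_out
  n_without <- without_h$stages[[1]]$n_out
  expect_gt(n_without, n_with)
  # the linkage genes are exactly the ones HEIDI removes
  v <- with_h$stages[[1]]$verdicts
  expect_true(any(v$stage == "fail_heidi" & v$gene_id %in% c("G05", "G06")))
})

test_that("an all-null study yields at most one spurious survivor and stops cleanly", {
  cfg <- sim_config(n_genes = 20, a = rep(0, 20), delta = rep(0, 20),
                    linkage = rep(FALSE, 20),
                    gene_symbols = sprintf("N%02d", 1:20), seed = 41)
  cas <- run_cascade(simulate_study(cfg), cascade_config(seed = 41))
  stages <- setNames(cas$stages, vapply(cas$stages, `[[`, "", "stage"))
  if (!is.null(stages$tsmr_mediator)) {
    expect_lte(stages$tsmr_mediator$n_out, 1L)
  } else {
    expect_equal(stages$smr_heidi$n_out, 0L)
  }
  expect_s3_class(cas, "mr_cascade")
  expect_lte(nrow(cas$genes), 1L)
})

test_that("symbol-less genes are excluded at the screening stage", {
  cfg <- sim_config(n_genes = 3, a = rep(0.2, 3), delta = rep(0, 3),
                    linkage = rep(FALSE, 3),
                    gene_symbols = c("SYM1", "", "SYM3"), seed = 53)
  cas <- run_cascade(simulate_study(cfg), cascade_config(seed = 53))
  v <- cas$stages[[1]]$verdicts
  expect_equal(v$stage[v$gene_id == "G02"], "fail_symbol")
})

test_that("cascade reports round-trip through the report writer", {
  cfg <- sim_config(n_genes = 4, a = c(0.2, 0.2, 0, 0), delta = rep(0, 4),
                    linkage = rep(FALSE, 4),
                    gene_symbols = sprintf("W%02d", 1:4), seed = 67)
  cas <- run_cascade(simulate_study(cfg), cascade_config(seed = 67))
  dir <- withr::local_tempdir()
  write_cascade_report(cas, dir)
  expect_true(file.exists(file.path(dir, "stage_smr_heidi.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  manifest <- readLines(file.path(dir, "manifest.tsv"))
  expect_true(any(grepl("^seed\t67$", manifest)))
  back <- read.delim(file.path(dir, "stage_smr_heidi.tsv"))
  expect_equal(nrow(back), 4L)
})
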