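test_that("identical allele coding leaves betas untouched", {
  exp <- make_ss(n = 3, beta = c(0.1, -0.2, 0.3))
  out <- make_ss(n = 3, beta = c(0.5, 0.6, -0.7), trait_type = "outcome")
  hp <- harmonize(exp, out)
  expect_equal(hp$beta_outcome, c(0.5, 0.6, -0.7))
  expect_true(all(hp$action_taken == "kept"))
})

test_that("swapped outcome alleles negate the beta and complement the frequency", {
  exp <- make_ss(n = 2, ea = "A", oa = "G", beta = 0.1, eaf = 0.3)
  rec <- make_records(n = 2, ea = "G", oa = "A", beta = 0.5, eaf = 0.7)
  out <- sumstats("o", "outcome", rec)
  hp <- harmonize(exp, out)
  expect_equal(hp$beta_outcome, c(-0.5, -0.5))
  expect_equal(hp$effect_allele, c("A", "A"))
  expect_true(all(hp$action_taken == "flipped"))
  # strand-complement swap (T/C reported for an A/G exposure SNP) also flips
  rec2 <- make_records(n = 2, ea = "C", oa = "T", beta = 0.5)
  hp2 <- harmonize(exp, sumstats("o", "outcome", rec2))
  expect_equal(hp2$beta_outcome, c(-0.5, -0.5))
})

test_that("palindromic handling follows the frequency policy", {
  exp <- make_ss(n = 3, ea = "A", oa = "T", eaf = c(0.5, 0.2, 0.2), beta = 0.1)
  out <- sumstats("o", "outcome",
                  make_records(n = 3, ea = "A", oa = "T",
                               eaf = c(0.5, 0.25, 0.8), beta = 0.4))
  hp <- harmonize(exp, out)
  # eaf 0.50 -> ambiguous -> dropped under the default policy
  expect_false("rs001" %in% hp$snp_id)
  expect_true("dropped_palindromic" %in% attr(hp, "dropped")$reason)
  # eaf agreement (0.2 vs 0.25) -> kept as-is
  expect_equal(hp$beta_outcome[hp$snp_id == "rs002"], 0.4)
  # eaf disagreement (0.2 vs 0.8) -> flipped
  expect_equal(hp$beta_outcome[hp$snp_id == "rs003"], -0.4)
  # missing frequency -> dropped
  exp2 <- make_ss(n = 1, ea = "C", oa = "G", eaf = NA_real_)
  out2 <- sumstats("o", "outcome", make_records(n = 1, ea = "C", oa = "G"))
  expect_equal(nrow(harmonize(exp2, out2)), 0L)
  # drop_all and keep policies
  expect_equal(nrow(harmonize(exp, out, palindrome_policy = "drop_all")), 0L)
  expect_equal(nrow(harmonize(exp, out, palindrome_policy = "keep")), 3L)
})

test_that("harmonization is involutive under allele flips", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 8
    ea <- sample(c("A", "C"), n, replace = TRUE)
    oa <- ifelse(ea == "A", "G", "T")
    beta <- rnorm(n)
    exp <- sumstats("e", "eqtl_gene",
                    make_records(n = n, ea = ea, oa = oa, beta = rnorm(n)))
    out_rec <- make_records(n = n, ea = ea, oa = oa, beta = beta)
    base <- harmonize(exp, sumstats("o", "outcome", out_rec))
    flip2 <- out_rec
    flip2[c("effect_allele", "other_allele")] <- flip2[c("other_allele", "effect_allele")]
    flip2$beta <- -flip2$beta
    flip2$eaf <- 1 - flip2$eaf
    flip2[c("effect_allele", "other_allele")] <- flip2[c("other_allele", "effect_allele")]
    flip2$beta <- -flip2$beta
    flip2$eaf <- 1 - flip2$eaf
    twice <- harmonize(exp, sumstats("o", "outcome", flip2))
    expect_identical(twice, base)
  }
})

test_that("an empty SNP intersection is a no-instruments error", {
  exp <- make_ss(n = 2)
  out <- sumstats("o", "outcome",
                  make_records(n = 2, snp_id = c("other1", "other2")))
  expect_error(harmonize(exp, out), class = "mrtriage_no_instruments")
})
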