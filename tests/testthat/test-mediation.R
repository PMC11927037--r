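test_that("product_effect evaluates both variance formulas", {
  # a = 0: estimate 0, first-order se = |b| * se_a
  p0 <- product_effect(0, 0.1, 2, 0.3, "first_order")
  expect_equal(p0$estimate, 0)
  expect_equal(p0$se, 2 * 0.1)
  # degenerate point masses multiply exactly
  expect_equal(product_effect(1, 0, 2, 0, "first_order"), list(estimate = 2, se = 0))
  expect_equal(product_effect(1, 0, 2, 0, "exact"), list(estimate = 2, se = 0))
  # exact adds the cross term
  pf <- product_effect(0.3, 0.1, 1.8, 0.36, "first_order")
  pe <- product_effect(0.3, 0.1, 1.8, 0.36)
  expect_equal(pe$se^2 - pf$se^2, 0.1^2 * 0.36^2, tolerance = 1e-12)
})

test_that("the exact product SE matches a large Monte Carlo oracle within 1%", {
  pe <- product_effect(0.3, 0.1, 1.8, 0.36)
  sd_mc <- with_seed(202, sd(rnorm(1e7, 0.3, 0.1) * rnorm(1e7, 1.8, 0.36)))
  expect_lt(abs(pe$se - sd_mc) / sd_mc, 0.01)
})

test_that("dop_ci is symmetric for centred factors and sign-equivariant", {
  ci <- dop_ci(0, 0.2, 0, 0.5)
  expect_equal(ci[["ci_low"]], -ci[["ci_high"]], tolerance = 1e-6)
  a_ci <- dop_ci(0.3, 0.1, 1.8, 0.36)
  n_ci <- dop_ci(-0.3, 0.1, 1.8, 0.36)
  expect_equal(n_ci[["ci_low"]], -a_ci[["ci_high"]], tolerance = 1e-7)
  expect_equal(n_ci[["ci_high"]], -a_ci[["ci_low"]], tolerance = 1e-7)
})

test_that("analytic and Monte Carlo interval methods agree", {
  grid <- list(c(0.3, 0.1, 1.8, 0.36), c(0.05, 0.04, 0.9, 0.3),
               c(-0.4, 0.15, 1.2, 0.5), c(0, 0.1, 0, 0.1))
  for (g in grid) {
    ca <- dop_ci(g[1], g[2], g[3], g[4])
    cm <- dop_ci(g[1], g[2], g[3], g[4], method = "monte_carlo",
                 n_draws = 2e6, seed = 7)
    expect_lt(max(abs(ca - cm)), 0.005)
  }
})

test_that("dop_ci collapses to the normal-theory interval as se_a vanishes", {
  ci <- dop_ci(0.25, 1e-9, 1.8, 0.36)
  ref <- 0.25 * 1.8 + c(-1, 1) * qnorm(0.975) * 0.25 * 0.36
  expect_equal(unname(ci), ref, tolerance = 1e-5)
})

test_that("published worked-example rows reproduce their reported intervals", {
  med <- published_mediation_effects()
  b <- published_mediator_effect()
  for (gene in c("THOC6", "PSMA4", "WNK2")) {
    row <- med[med$gene == gene, ]
    path <- back_derive_path(row$estimate, row$se, b$beta, b$se)
    ci <- dop_ci(path$a, path$se_a, b$beta, b$se)
    expect_lt(abs(ci[["ci_low"]] - row$ci_low), 0.02)
    expect_lt(abs(ci[["ci_high"]] - row$ci_high), 0.02)
  }
})

test_that("back_derive_path inverts product_effect and flags infeasible rows", {
  # round trip at machine precision
  fwd <- product_effect(0.2269, 0.0174, 1.8, 0.36, "first_order")
  back <- back_derive_path(fwd$estimate, fwd$se, 1.8, 0.36, "first_order")
  expect_equal(back$a, 0.2269, tolerance = 1e-12)
  expect_equal(back$se_a, 0.0174, tolerance = 1e-12)
  fwd2 <- product_effect(0.31, 0.052, 1.8, 0.36, "exact")
  back2 <- back_derive_path(fwd2$estimate, fwd2$se, 1.8, 0.36, "exact")
  expect_equal(back2$a, 0.31, tolerance = 1e-12)
  expect_equal(back2$se_a, 0.052, tolerance = 1e-12)

  # the published PSMA4 row back-derives to the documented path coefficients
  med <- published_mediation_effects()
  psma4 <- med[med$gene == "PSMA4", ]
  path <- back_derive_path(psma4$estimate, psma4$se, 1.8, 0.36)
  expect_lt(abs(path$a - 0.2269), 5e-4)
  expect_lt(abs(path$se_a - 0.0174), 5e-4)

  # the published ERVH48-1 row admits no real se_a under the rounded b path
  erv <- med[med$gene == "ERVH48-1", ]
  err <- tryCatch(back_derive_path(erv$estimate, erv$se, 1.8, 0.36),
                  error = identity)
  expect_s3_class(err, "mrtriage_infeasible_inputs")
  expect_lt(err$residual, 0)
  expect_error(back_derive_path(0.1, 0.1, 0, 0.1),
               class = "mrtriage_undefined_ratio")
})

test_that("classify_gene applies the staged Bonferroni rule", {
  expect_equal(classify_gene(1e-5, 0.5, -1, 1, n_total = 72, n_direct = 72),
               "total_significant")
  expect_equal(classify_gene(0.5, 1e-5, -1, 1, n_total = 72, n_direct = 72),
               "direct_significant")
  expect_equal(classify_gene(0.5, 0.5, 0.24, 0.59, n_total = 72, n_direct = 72),
               "mediation_only")
  expect_equal(classify_gene(0.5, 0.5, -0.1, 0.59, n_total = 72, n_direct = 72),
               "none")
  # boundary: p just above alpha / n fails the stage
  expect_equal(classify_gene(0.05 / 10, 0.5, -0.1, 0.2, n_total = 10, n_direct = 10),
               "none")
})

test_that("mediation_decomposition keeps mediated = a*b inside its interval", {
  d <- mediation_decomposition("G1", a = 0.25, se_a = 0.05, b = 1.8, se_b = 0.36,
                               total = 0.4, se_total = 0.3, total_p = 0.2,
                               direct = 0.05, se_direct = 0.2, direct_p = 0.8,
                               n_total = 10, n_direct = 10)
  expect_equal(d$mediated, 0.25 * 1.8)
  expect_lte(d$ci_low, d$mediated)
  expect_gte(d$ci_high, d$mediated)
  expect_equal(d$category, "mediation_only")
})
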