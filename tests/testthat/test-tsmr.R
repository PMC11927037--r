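test_that("wald_ratio scales the outcome by the exposure effect", {
  expect_equal(wald_ratio(make_pairs(1, 0.5, se_outcome = 0.1))$beta, 0.5)
  expect_equal(wald_ratio(make_pairs(1, 0.5, se_outcome = 0.1))$se, 0.1)
  r <- wald_ratio(make_pairs(2, 1, se_outcome = 0.2))
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(wald_ratio(make_pairs(-2, 1, se_outcome = 0.2))$beta, -0.5)
  expect_error(wald_ratio(make_pairs(0, 1)), class = "mrtriage_undefined_ratio")
})

test_that("ivw reduces to the weighted ratio average and degenerates cleanly", {
  # equal weights, ratios 0.5 and 1.0 -> 0.75
  p <- make_pairs(c(1, 1), c(0.5, 1.0))
  expect_equal(ivw(p, "fixed")$beta, 0.75)
  # identical ratios: estimate c, zero dispersion and Q
  p2 <- make_pairs(c(0.5, 1, 2), c(0.5, 1, 2) * 0.3)
  fit <- ivw(p2, "mre")
  expect_equal(fit$beta, 0.3)
  expect_lt(fit$dispersion, 1e-20)
  expect_lt(fit$Q, 1e-10)
  expect_error(ivw(make_pairs(1, 1)), class = "mrtriage_insufficient_instruments")
})

test_that("ivw agrees with a weighted-least-squares oracle to 1e-10", {
  set.seed(31)
  for (i in 1:25) {
    k <- 50
    p <- make_pairs(rnorm(k, 0.3, 0.1), rnorm(k, 0.2, 0.15),
                    se_outcome = runif(k, 0.05, 0.3))
    w <- 1 / p$se_outcome^2
    fit_lm <- lm(beta_outcome ~ 0 + beta_exposure, data = p, weights = w)
    s <- summary(fit_lm)$coefficients
    fixed <- ivw(p, "fixed"); mre <- ivw(p, "mre")
    expect_equal(fixed$beta, unname(s[1, 1]), tolerance = 1e-10)
    expect_equal(mre$beta, unname(s[1, 1]), tolerance = 1e-10)
    # lm reports dispersion-scaled SEs = the multiplicative-random-effects SE
    expect_equal(mre$se, unname(s[1, 2]), tolerance = 1e-10)
    expect_equal(fixed$se, unname(s[1, 2]) / summary(fit_lm)$sigma, tolerance = 1e-10)
  }
})

test_that("egger recovers an exact affine relationship", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  p <- make_pairs(x, 0.1 + 0.5 * x)
  fit <- egger(p)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_error(egger(make_pairs(c(1, 1), c(1, 1))),
               class = "mrtriage_insufficient_instruments")
})

test_that("egger orientation forces exposure betas non-negative", {
  x <- c(0.2, -0.4, 0.6, -0.8)
  y <- 0.1 * sign(x) + 0.5 * x           # affine in the oriented frame
  fit <- egger(make_pairs(x, y))
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
})

test_that("egger bootstrap is reproducible given a seed", {
  p <- simulate_tsmr_pairs(k = 15, true_beta = 1, seed = 4)
  a <- egger_bootstrap(p, n_boot = 50, seed = 9)
  b <- egger_bootstrap(p, n_boot = 50, seed = 9)
  expect_identical(a, b)
  c <- egger_bootstrap(p, n_boot = 1, seed = 9)
  d <- egger_bootstrap(p, n_boot = 1, seed = 9)
  expect_identical(c$beta, d$beta)
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights, ratios (0.4, 0.5, 10): cumulative standardized weight
  # hits 0.5 exactly at the middle ratio
  p <- make_pairs(c(1, 1, 1), c(0.4, 0.5, 10))
  expect_equal(weighted_median(p, n_boot = 20, seed = 1)$beta, 0.5)
  # identical ratios return that ratio
  p2 <- make_pairs(c(0.5, 1, 2), c(0.5, 1, 2) * 0.7)
  expect_equal(weighted_median(p2, n_boot = 20, seed = 1)$beta, 0.7)
})

test_that("weighted median resists a single outlying instrument where IVW does not", {
  set.seed(5)
  k <- 20
  x <- runif(k, 0.5, 1)
  y <- 0.5 * x + rnorm(k, 0, 0.005)
  y[k] <- 5 * x[k]                        # one invalid instrument
  p <- make_pairs(x, y, se_outcome = rep(0.05, k))
  wm <- weighted_median(p, n_boot = 100, seed = 2)
  expect_lt(abs(wm$beta - 0.5), 0.05)
  expect_gt(abs(ivw(p, "mre")$beta - 0.5), 0.05)
})

test_that("cochran_q matches hand evaluation and an independent meta-analysis fit", {
  # identical ratios: no heterogeneity
  q0 <- cochran_q(make_pairs(c(1, 2), c(0.3, 0.6)))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p_Q, 1)
  # two unit-weight instruments with ratios 0 and 1: Q = 0.5
  q1 <- cochran_q(make_pairs(c(1, 1), c(0, 1), se_outcome = c(1, 1)))
  expect_equal(q1$Q, 0.5)
  # random problems against metafor's fixed-effect QE statistic
  set.seed(8)
  for (i in 1:10) {
    k <- 12
    p <- make_pairs(runif(k, 0.5, 1.5), rnorm(k, 0.4, 0.2),
                    se_outcome = runif(k, 0.05, 0.2))
    ratio <- p$beta_outcome / p$beta_exposure
    sei <- p$se_outcome / abs(p$beta_exposure)
    oracle <- suppressWarnings(metafor::rma(yi = ratio, sei = sei, method = "FE"))
    q <- cochran_q(p)
    expect_equal(q$Q, unname(oracle$QE), tolerance = 1e-8)
    expect_equal(q$p_Q, unname(oracle$QEp), tolerance = 1e-8)
  }
})

test_that("Q is calibrated under homogeneity", {
  set.seed(12)
  qs <- replicate(1000, {
    p <- make_pairs(runif(10, 0.5, 1), 0.3 * runif(10, 0.5, 1), se_outcome = 0.1)
    p$beta_outcome <- 0.3 * p$beta_exposure + rnorm(10, 0, 0.1)
    cochran_q(p)$Q / 9
  })
  expect_lt(abs(mean(qs) - 1), 3 * sd(qs) / sqrt(1000))
})

test_that("all estimators are sign-equivariant in the outcome", {
  p <- simulate_tsmr_pairs(k = 20, true_beta = 0.8, seed = 21)
  neg <- p; neg$beta_outcome <- -neg$beta_outcome
  for (fit in list(function(d) ivw(d, "fixed"), function(d) ivw(d, "mre"),
                   egger)) {
    a <- fit(p); b <- fit(neg)
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
  expect_equal(ivw(neg, "mre")$Q, ivw(p, "mre")$Q, tolerance = 1e-12)
  # the weighted-median point estimate negates exactly; its bootstrap SE only
  # approximately (fresh draws around the negated means)
  wm_a <- weighted_median(p, n_boot = 400, seed = 3)
  wm_b <- weighted_median(neg, n_boot = 400, seed = 3)
  expect_equal(wm_b$beta, -wm_a$beta, tolerance = 1e-12)
  expect_equal(wm_b$se, wm_a$se, tolerance = 0.25 * wm_a$se)
})

test_that("sensitivity_suite recommends by pleiotropy, then heterogeneity, then the primary", {
  clean <- sensitivity_suite(simulate_tsmr_pairs(k = 30, true_beta = 1.8, seed = 61),
                             seed = 1)
  expect_equal(clean$recommended_method, "ivw_mre")
  expect_false(clean$pleiotropy_significant)

  het <- sensitivity_suite(
    simulate_tsmr_pairs(k = 30, true_beta = 1.8, het_multiplier = 4, seed = 62),
    seed = 1
  )
  expect_true(het$heterogeneity_significant)
  expect_equal(het$recommended_method, "ivw_mre")

  # intercept identification needs spread in instrument strength
  pleio <- sensitivity_suite(
    simulate_tsmr_pairs(k = 30, true_beta = 1.8, beta_range = c(0.08, 0.45),
                        pleiotropy_mean = 0.3, pleiotropy_sd = 0.05, seed = 63),
    seed = 1
  )
  expect_true(pleio$pleiotropy_significant)
  expect_equal(pleio$recommended_method, "egger_bootstrap")
})

test_that("ivw-mre recovers a strong causal effect across replicates", {
  est <- vapply(1:100, function(i) {
    ivw(simulate_tsmr_pairs(k = 30, true_beta = 1.8, seed = 700 + i), "mre")$beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.8), 2 * mc_se + 0.02)
})
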