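test_that("wald_ratios implement the ratio and first-order SE", {
  h <- make_h(c(0.1, 0.1, -0.05), c(0.2, 0, 0.1), se_Gamma = rep(0.05, 3))
  wr <- wald_ratios(h)
  expect_equal(wr$beta, c(2.0, 0, -2.0))
  expect_equal(wr$se, c(0.5, 0.5, 1.0))
  expect_error(wald_ratios(make_h(c(0.1, 0), c(0.1, 0.1))), "zero")
})

test_that("IVW handles the symmetric, perfect-fit and boundary cases", {
  h <- make_h(c(1, 1), c(0.3, 0.5), se_Gamma = c(0.1, 0.1))
  r <- mr_ivw(h)
  expect_equal(r$beta, 0.4)

  # perfect proportionality: Q = 0, fixed and random SEs coincide
  h2 <- make_h(c(0.1, 0.2, 0.3), 0.7 * c(0.1, 0.2, 0.3))
  rf <- mr_ivw(h2, "fixed"); rr <- mr_ivw(h2, "random")
  expect_equal(rr$beta, 0.7)
  expect_equal(rr$extras$q, 0)
  expect_equal(rf$se, rr$se)

  expect_error(mr_ivw(make_h(0.1, 0.2)), "J >= 2")
})

test_that("closed-form IVW equals weighted least squares through the origin", {
  for (s in 1:20) {
    h <- rand_h(15, seed = 100 + s)
    w <- 1 / h$se_Gamma^2
    fit <- lm(h$Gamma ~ 0 + h$gamma, weights = w)
    r <- mr_ivw(h, "fixed")
    expect_equal(r$beta, unname(coef(fit)), tolerance = 1e-10)
    sigma_hat <- sqrt(sum(w * resid(fit)^2) / (length(h$gamma) - 1))
    expect_equal(r$se, unname(summary(fit)$coefficients[1, 2]) / sigma_hat,
                 tolerance = 1e-10)
  }
})

test_that("IVW random-effects CI covers the truth at near-nominal rate", {
  covered <- vapply(1:500, function(s) {
    h <- sim_pair(sim_config(n_snps = 50, theta_xy_direct = 0.5, seed = s))
    r <- mr_ivw(h, "random")
    r$ci_low <= 0.5 && 0.5 <= r$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("Egger recovers exact affine data and respects the df boundary", {
  gamma <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_h(gamma, 0.02 + 0.5 * gamma)
  r <- mr_egger(h)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  expect_equal(r$extras$intercept, 0.02, tolerance = 1e-12)
  expect_equal(r$extras$q, 0, tolerance = 1e-20)

  h3 <- make_h(c(0.1, 0.2, 0.3), c(0.06, 0.11, 0.14))
  r3 <- mr_egger(h3)
  expect_true(is.finite(r3$se) && r3$se > 0)
  expect_true(is.finite(r3$extras$intercept_se))
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.1, 0.1))), "J >= 3")
})

test_that("Egger is invariant to joint sign flips of individual SNPs", {
  h <- rand_h(12, seed = 7)
  h2 <- h
  flip <- c(2, 5, 9)
  h2$gamma[flip] <- -h2$gamma[flip]
  h2$Gamma[flip] <- -h2$Gamma[flip]
  r1 <- mr_egger(h); r2 <- mr_egger(h2)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
  expect_equal(r1$extras$intercept, r2$extras$intercept, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted 50th percentile", {
  # equal weights, ratios (1, 2, 9): the midpoint convention gives exactly 2
  h <- make_h(c(1, 1, 1), c(1, 2, 9), se_Gamma = c(1, 1, 1))
  r <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(r$beta, 2)
  expect_error(mr_weighted_median(make_h(c(1, 1), c(1, 2)), seed = 1), "J >= 3")
})

test_that("bootstrap SEs are exactly reproducible under a fixed seed", {
  h <- rand_h(20, seed = 9)
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  m1 <- mr_mode(h, n_boot = 100, seed = 42)
  m2 <- mr_mode(h, n_boot = 100, seed = 42)
  expect_identical(m1$se, m2$se)
  c2 <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c2$se))
})

test_that("mode estimator finds the dominant cluster and degenerate limit", {
  h <- make_h(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 5.0), se_Gamma = rep(1, 4))
  r <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(r$beta - 0.5), 0.05)

  hc <- make_h(c(1, 2, 4), c(0.7, 1.4, 2.8))
  rc <- mr_mode(hc, n_boot = 50, seed = 1)
  expect_equal(rc$beta, 0.7)   # all ratios identical -> common ratio
  expect_error(mr_mode(make_h(c(1, 1), c(1, 1)), seed = 1), "J >= 3")
})

test_that("weighted mode is near the truth in a majority-valid scenario", {
  h <- sim_pair(sim_config(n_snps = 100, theta_xy_direct = 0.5,
                           n_exposure = 5e5, n_outcome = 5e5,
                           gamma_dist = list(min = 0.05, max = 0.15, sign = "positive"),
                           pleiotropy = list(mode = "directional",
                                             scale = 0.03, frac = 0.3),
                           seed = 77))
  r <- mr_mode(h, weighted = TRUE, n_boot = 50, seed = 77)
  expect_lt(abs(r$beta - 0.5), 0.1)
})

test_that("or_from_beta exponentiates with a 1.96-normal interval", {
  expect_equal(unname(or_from_beta(0, 0.1)["or"]), 1)
  expect_equal(unname(or_from_beta(log(2), 0.1)["or"]), 2)
  o <- or_from_beta(log(0.703), 0.166)
  expect_equal(unname(round(o["or"], 3)), 0.703)
  expect_lt(o["or_low"], o["or"]); expect_gt(o["or_high"], o["or"])
})

test_that("all five estimators agree under no pleiotropy at large J", {
  h <- sim_pair(sim_config(n_snps = 150, theta_xy_direct = 0.4,
                           n_exposure = 5e5, n_outcome = 5e5, seed = 5))
  res <- mr_all(h, n_boot = 100, seed = 5)
  expect_named(res, c("ivw_re", "egger", "weighted_median",
                      "simple_mode", "weighted_mode"))
  betas <- vapply(res, function(r) r$beta, 1)
  ses <- vapply(res, function(r) r$se, 1)
  for (m in names(betas))
    expect_lt(abs(betas[[m]] - betas[["ivw_re"]]), 3 * max(ses[[m]], ses[["ivw_re"]]))
})

test_that("mr_result invariants hold on random inputs", {
  for (s in 1:10) {
    h <- rand_h(10, seed = 300 + s)
    for (r in list(mr_ivw(h), mr_egger(h),
                   mr_weighted_median(h, n_boot = 50, seed = s))) {
      expect_lt(r$ci_low, r$beta); expect_gt(r$ci_high, r$beta)
      expect_equal(r$or, exp(r$beta))
      expect_true(r$pvalue > 0 && r$pvalue <= 1)
    }
  }
})
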