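make_mv <- function(J = 12, seed = 1, theta = c(0.3, -0.2), intercept = 0,
                    noise = 0) {
  mrmediate:::with_seed(seed, {
    X <- cbind(x1 = runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE),
               x2 = runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE))
    # bake the intercept into the orientation frame used by mv_egger
    s <- sign(X[, 1]); s[s == 0] <- 1
    Gamma <- drop(X %*% theta) + s * intercept + rnorm(J, 0, noise)
    mvmr_input(sprintf("rs%03d", 1:J), X,
               matrix(0.01, J, 2, dimnames = list(NULL, c("x1", "x2"))),
               Gamma, rep(0.05, J))
  })
}

test_that("mv_ivw recovers noiseless two-exposure effects exactly", {
  inp <- make_mv(theta = c(0.3, -0.2))
  r <- mv_ivw(inp)
  expect_equal(r$table$beta, c(0.3, -0.2), tolerance = 1e-10)
  expect_equal(r$q, 0, tolerance = 1e-18)
})

test_that("mv_ivw enforces J > K and detects collinear exposures", {
  inp <- make_mv(J = 12)
  expect_error(mvmr_input(inp$snp_ids[1:2], inp$exposure_betas[1:2, ],
                          inp$exposure_ses[1:2, ], inp$Gamma[1:2],
                          inp$se_Gamma[1:2]), "J > K")
  bad <- inp
  bad$exposure_betas[, 2] <- 2 * bad$exposure_betas[, 1]
  expect_error(mv_ivw(bad), "collinear")
})

test_that("mv_ivw with one exposure equals univariable fixed-effects IVW", {
  h <- rand_h(15, seed = 61)
  fit <- mrmediate:::mvmr_fit(list(exposure_betas = matrix(h$gamma, ncol = 1,
                                                           dimnames = list(NULL, "x")),
                                   Gamma = h$Gamma, se_Gamma = h$se_Gamma))
  uni <- mr_ivw(h, "random")  # multiplicative overdispersion in both
  expect_equal(unname(fit$coef), uni$beta, tolerance = 1e-10)
  expect_equal(unname(fit$se), uni$se, tolerance = 1e-10)
})

test_that("mv_egger recovers a baked-in intercept and is orientation-invariant", {
  inp <- make_mv(theta = c(0.3, -0.2), intercept = 0.01)
  r <- mv_egger(inp)
  expect_equal(r$intercept, 0.01, tolerance = 1e-10)
  expect_equal(r$table$beta, c(0.3, -0.2), tolerance = 1e-10)

  flipped <- inp
  j <- 4
  flipped$exposure_betas[j, ] <- -flipped$exposure_betas[j, ]
  flipped$Gamma[j] <- -flipped$Gamma[j]
  r2 <- mv_egger(flipped)
  expect_equal(r2$table$beta, r$table$beta, tolerance = 1e-12)

  expect_error(mv_egger(make_mv(J = 3)), "J > K \\+ 1")
})

test_that("mv_ivw CIs cover true direct effects at near-nominal rate", {
  covered <- vapply(1:300, function(s) {
    trip <- simulate_triplet(sim_config(n_snps = 40, n_mediator_snps = 40,
                                        theta_xz = 0.4, theta_zy = -0.28,
                                        theta_xy_direct = -0.33,
                                        n_exposure = 3e5, n_mediator = 3e5,
                                        n_outcome = 3e5, seed = 4000 + s))
    inp <- build_mvmr_input(list(trip$exposure, trip$mediator), trip$outcome,
                            ld = trip$ld)
    tab <- mv_ivw(inp)$table
    all(tab$ci_low <= c(-0.33, -0.28) & c(-0.33, -0.28) <= tab$ci_high)
  }, TRUE)
  # joint coverage of two near-independent 95% CIs is ~0.95^2 = 0.9025;
  # the overdispersion floor adds a little conservatism on top
  expect_gte(mean(covered), 0.885)
})

test_that("mv_ivw per-exposure CIs each cover at near-nominal rate", {
  hits <- matrix(NA, 100, 2)
  for (s in 1:100) {
    trip <- simulate_triplet(sim_config(n_snps = 40, n_mediator_snps = 40,
                                        theta_xz = 0.4, theta_zy = -0.28,
                                        theta_xy_direct = -0.33,
                                        n_exposure = 3e5, n_mediator = 3e5,
                                        n_outcome = 3e5, seed = 7000 + s))
    inp <- build_mvmr_input(list(trip$exposure, trip$mediator), trip$outcome,
                            ld = trip$ld)
    tab <- mv_ivw(inp)$table
    hits[s, ] <- tab$ci_low <= c(-0.33, -0.28) & c(-0.33, -0.28) <= tab$ci_high
  }
  expect_gte(mean(hits[, 1]), 0.90)
  expect_gte(mean(hits[, 2]), 0.90)
})

test_that("build_mvmr_input unions, deduplicates and drops missing SNPs", {
  trip <- simulate_triplet(sim_config(n_snps = 15, n_mediator_snps = 15,
                                      theta_xz = 0.4, seed = 90))
  # drop one exposure-significant SNP from the outcome file
  sel <- select_by_pvalue(trip$exposure)
  drop_id <- sel$data$snp[1]
  out2 <- summary_dataset(trip$outcome$data[trip$outcome$data$snp != drop_id, ],
                          "outcome", "binary")
  inp <- build_mvmr_input(list(trip$exposure, trip$mediator), out2, ld = trip$ld)
  expect_false(drop_id %in% inp$snp_ids)
  expect_false(anyDuplicated(inp$snp_ids) > 0)
  expect_true(all(attr(inp, "log") != ""))
  expect_gt(length(inp$snp_ids), 2)
})

test_that("mediate reproduces the product-of-coefficients arithmetic", {
  m <- mediate(log(0.703), log(2.103), -0.277, ses = c(0.05, 0.03, 0.06))
  expect_equal(m$indirect, log(2.103) * -0.277)
  expect_identical(m$direct + m$indirect, m$total)   # machine-exact identity
  expect_equal(m$proportion, 100 * m$indirect / m$total)
  expect_false(m$opposite_signs)
  # delta-method SE of the product
  expect_equal(m$indirect_se,
               sqrt(log(2.103)^2 * 0.06^2 + 0.277^2 * 0.03^2))

  z <- mediate(-0.5, 0, 0.3)
  expect_equal(z$indirect, 0); expect_equal(z$proportion, 0)
  expect_equal(z$direct, -0.5)

  f <- mediate(-0.4, 0.8, -0.5)
  expect_equal(f$proportion, 100); expect_equal(f$direct, 0)

  expect_error(mediate(0, 0.1, 0.1), "nonzero")
})

test_that("mediate flags opposite-sign indirect/total effects", {
  m <- mediate(-0.3, 0.5, 0.4)
  expect_true(m$opposite_signs)
  expect_lt(m$proportion, 0)
})

test_that("decomposition identity holds for arbitrary inputs", {
  set.seed(77)
  for (i in 1:50) {
    tot <- rnorm(1); if (tot == 0) tot <- 0.1
    m <- mediate(tot, rnorm(1), rnorm(1), ses = abs(rnorm(3)))
    expect_identical(m$direct + m$indirect, m$total)
  }
})
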