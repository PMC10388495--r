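# Shared fixture builders: everything is constructed in code, no data files.

make_h <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                   se_Gamma = rep(0.05, length(gamma)),
                   snp_ids = sprintf("rs%03d", seq_along(gamma)), ...) {
  harmonized_set(snp_ids, gamma, se_gamma, Gamma, se_Gamma, ...)
}

# random harmonized set for property loops (no true pleiotropy; slope `theta`)
rand_h <- function(J, seed, theta = 0.3, noise = 0.05) {
  mrmediate:::with_seed(seed, {
    gamma <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE)
    se_g <- runif(J, 0.005, 0.02)
    se_G <- runif(J, 0.02, 0.08)
    Gamma <- theta * gamma + rnorm(J, 0, noise)
    make_h(gamma, Gamma, se_g, se_G)
  })
}

make_ds <- function(snp, beta, se, p = NULL, chr = "1",
                    pos = seq_along(snp) * 2e7, ea = "A", oa = "G",
                    eaf = 0.3, n = 1e5, trait_name = "trait",
                    trait_type = "quantitative") {
  if (is.null(p)) p <- pmax(pmin(2 * pnorm(-abs(beta / se)), 1), 1e-300)
  summary_dataset(data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
                             eaf = eaf, beta = beta, se = se, p = p, n = n,
                             stringsAsFactors = FALSE),
                  trait_name, trait_type)
}

# harmonize a simulated triplet pair without any filtering
sim_pair <- function(config, which = "outcome") {
  trip <- simulate_triplet(config)
  harmonize(trip$exposure, trip[[which]])
}
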