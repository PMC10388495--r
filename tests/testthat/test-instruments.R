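test_that("select_by_pvalue filters strictly and relaxes when short", {
  set.seed(1)
  p <- c(runif(88, 1e-5, 1), runif(12, 1e-12, 1e-9))
  ds <- make_ds(sprintf("rs%03d", 1:100), rnorm(100, 0, 0.1), rep(0.01, 100), p = p)
  sel <- select_by_pvalue(ds)
  expect_equal(n_snps(sel), 12L)
  expect_false(attr(sel, "relaxed"))
  expect_equal(attr(sel, "threshold_used"), 5e-8)

  # 2 strict hits, 10 relaxed, min 3 -> relaxation recorded
  p2 <- c(rep(1e-9, 2), rep(1e-7, 8), rep(0.5, 40))
  ds2 <- make_ds(sprintf("rs%03d", 1:50), rep(0.1, 50), rep(0.01, 50), p = p2)
  sel2 <- select_by_pvalue(ds2, min_instruments = 3)
  expect_equal(n_snps(sel2), 10L)
  expect_true(attr(sel2, "relaxed"))
  expect_equal(attr(sel2, "threshold_used"), 5e-6)

  ds3 <- make_ds(c("rs1", "rs2"), c(0.1, 0.1), c(0.01, 0.01), p = c(0.5, 0.9))
  expect_error(select_by_pvalue(ds3), "no instruments")
})

test_that("ld_clump keeps the best SNP among linked neighbours", {
  # 5 kb apart, r2 = 0.5: only the smaller p survives
  ds <- make_ds(c("a", "b"), c(0.1, 0.1), c(0.01, 0.01), p = c(1e-10, 1e-9),
                pos = c(1e6, 1e6 + 5e3))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  out <- ld_clump(ds, ld_matrix(r2))
  expect_equal(out$data$snp, "a")

  # different chromosomes: distance condition fails, both kept
  ds2 <- make_ds(c("a", "b"), c(0.1, 0.1), c(0.01, 0.01), p = c(1e-10, 1e-9),
                 chr = c("1", "2"), pos = c(1e6, 1e6))
  out2 <- ld_clump(ds2, ld_matrix(r2))
  expect_equal(n_snps(out2), 2L)

  # mutually independent SNPs: no-op regardless of p ordering
  ds3 <- make_ds(c("a", "b", "c"), c(0.1, 0.2, 0.05), rep(0.01, 3),
                 p = c(1e-9, 1e-12, 1e-10), pos = c(1, 2, 3) * 1e3)
  eye3 <- diag(3)
  dimnames(eye3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  out3 <- ld_clump(ds3, ld_matrix(eye3))
  expect_equal(out3$data$snp, c("a", "b", "c"))

  expect_error(ld_clump(ds3, ld_matrix(r2)), "missing from LD matrix")
})

test_that("ld_clump without LD falls back to distance-only with a warning", {
  ds <- make_ds(c("a", "b"), c(0.1, 0.1), c(0.01, 0.01), p = c(1e-10, 1e-9),
                pos = c(1e6, 1e6 + 5e3))
  expect_warning(out <- ld_clump(ds), "distance-only")
  expect_equal(out$data$snp, "a")
})

test_that("clumped output is a subset with no surviving linked pair", {
  for (s in 1:5) {
    cfg <- sim_config(n_snps = 30, seed = s,
                      ld_blocks = list(list(size = 4, r2 = 0.8),
                                       list(size = 3, r2 = 0.5)))
    trip <- simulate_triplet(cfg)
    cl <- ld_clump(trip$exposure, trip$ld)
    expect_true(all(cl$data$snp %in% trip$exposure$data$snp))
    ids <- cl$data$snp
    if (length(ids) > 1) {
      sub <- trip$ld$r2[ids, ids]
      pos <- cl$data$pos; chr <- cl$data$chr
      for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
        linked <- sub[i, j] >= 0.001 &&
          chr[i] == chr[j] && abs(pos[i] - pos[j]) <= 1e7
        expect_false(linked)
      }
    }
    # each block contributes exactly one survivor
    expect_equal(sum(cl$data$snp %in% sprintf("rs%06d", 1:4)), 1L)
    expect_equal(sum(cl$data$snp %in% sprintf("rs%06d", 5:7)), 1L)
  }
})

test_that("harmonize aligns alleles across swap and strand cases", {
  ex <- make_ds(c("s1", "s2", "s3"), c(0.1, 0.1, 0.05), rep(0.01, 3),
                ea = c("A", "A", "C"), oa = c("G", "G", "T"), eaf = 0.3)
  ou <- summary_dataset(data.frame(
    snp = c("s1", "s2", "s3"), chr = "1", pos = c(2e7, 4e7, 6e7),
    ea = c("G", "T", "C"), oa = c("A", "C", "T"),
    eaf = c(0.7, 0.3, 0.3), beta = c(0.05, 0.05, 0.02), se = 0.01,
    p = 0.001, n = 1e5), "out", "binary")
  h <- harmonize(ex, ou)
  expect_equal(h$snp_ids, c("s1", "s2", "s3"))
  expect_equal(h$Gamma, c(-0.05, 0.05, 0.02))  # swap flip, strand-complement keep, exact
  acts <- setNames(h$provenance$action, h$provenance$snp)
  expect_equal(unname(acts["s1"]), "flipped")
  expect_equal(unname(acts["s2"]), "strand_corrected")
})

test_that("palindromic SNPs with intermediate or missing frequency are removed", {
  ex <- make_ds(c("p1", "p2", "p3"), c(0.1, 0.1, 0.1), rep(0.01, 3),
                ea = "A", oa = "T", eaf = c(0.50, 0.30, 0.30))
  ou <- make_ds(c("p1", "p2", "p3"), c(0.05, 0.05, 0.05), rep(0.01, 3),
                ea = "A", oa = "T", eaf = c(0.50, 0.30, NA),
                trait_type = "binary")
  h <- harmonize(ex, ou, palindrome_band = 0.08)
  # p1 intermediate removed; p3's governing (exposure) eaf is present -> kept
  expect_setequal(h$snp_ids, c("p2", "p3"))
  expect_setequal(h$provenance$action[h$provenance$snp == "p1"],
                  "removed_palindrome_intermediate")
  h3 <- harmonize(ex, ou, palindrome_band = 0.08, freq_source = "outcome")
  expect_false("p3" %in% h3$snp_ids)  # outcome governs and is missing
})

test_that("palindrome with discordant frequency sides is strand-flipped", {
  ex <- make_ds("p1", 0.1, 0.01, ea = "C", oa = "G", eaf = 0.2)
  ou <- make_ds("p1", 0.05, 0.01, ea = "C", oa = "G", eaf = 0.8)
  h <- harmonize(ex, ou)
  expect_equal(h$Gamma, -0.05)
})

test_that("irreconcilable allele pairs are removed with a logged reason", {
  ex <- make_ds(c("s1", "s2"), c(0.1, 0.1), c(0.01, 0.01), ea = "A", oa = "G")
  ou <- make_ds(c("s1", "s2"), c(0.05, 0.05), c(0.01, 0.01),
                ea = c("A", "A"), oa = c("G", "C"))
  h <- harmonize(ex, ou)
  expect_equal(h$snp_ids, "s1")
  expect_true("removed_mismatch" %in% h$provenance$action)
  # kept + removed covers the full intersection
  expect_equal(nrow(h$provenance), 2L)
})

test_that("harmonization is idempotent", {
  cfg <- sim_config(n_snps = 25, theta_xy_direct = 0.3, seed = 3)
  trip <- simulate_triplet(cfg)
  h1 <- harmonize(trip$exposure, trip$outcome)
  # rebuild the outcome in the exposure frame and harmonize again
  exd <- trip$exposure$data[match(h1$snp_ids, trip$exposure$data$snp), ]
  ou2 <- summary_dataset(data.frame(snp = h1$snp_ids, chr = exd$chr, pos = exd$pos,
                                    ea = exd$ea, oa = exd$oa, eaf = h1$eaf,
                                    beta = h1$Gamma, se = h1$se_Gamma,
                                    p = pmax(2 * pnorm(-abs(h1$Gamma / h1$se_Gamma)), 1e-300),
                                    n = 1e5), "out2", "binary")
  h2 <- harmonize(trip$exposure, ou2)
  expect_equal(h2$snp_ids, h1$snp_ids)
  expect_equal(h2$Gamma, h1$Gamma)
  expect_equal(h2$gamma, h1$gamma)
})

test_that("f_statistics implements F = (beta/se)^2 with weak flags", {
  h <- make_h(c(0.1, 0.03, 0), c(0.1, 0.1, 0.1), se_gamma = rep(0.01, 3))
  fs <- f_statistics(h)
  expect_equal(fs$f_stat, c(100, 9, 0))
  expect_equal(fs$weak_flags, c(FALSE, TRUE, TRUE))
  expect_equal(fs$mean_f, mean(c(100, 9, 0)))
})

test_that("empty exposure/outcome intersection is a hard error", {
  ex <- make_ds("a", 0.1, 0.01)
  ou <- make_ds("b", 0.1, 0.01)
  expect_error(harmonize(ex, ou), "no shared SNPs")
})
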