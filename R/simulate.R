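# Seeded generator of GWAS summary-statistic triplets (exposure X, mediator
# Z, outcome Y) under the structural model
#   X <- gamma_j ;  Z = theta_xz * X + direct Z effects + pleiotropy
#   Y = theta_direct * X + theta_zy * Z + direct Y effects + pleiotropy
# Summary statistics are generated directly (no individual-level genotypes):
# observed betas are truth plus normal noise with the standardized-trait
# standard error 1/sqrt(2 n maf (1-maf)); binary traits are interpreted on
# the log-odds scale with the same variance form, so `n` should be an
# effective sample size (4 / (1/ncases + 1/ncontrols)) for case-control GWAS.

#' Simulation configuration
#'
#' Encodes the X -> Z -> Y causal diagram with known ground truth.
#' Besides the `n_snps` exposure instruments, the generated genome can carry
#' `n_mediator_snps` variants acting directly on the mediator (required for
#' multivariable MR to be identified) and `n_outcome_snps` variants acting
#' directly on the outcome (what a reverse-direction analysis selects).
#'
#' @param n_snps exposure-instrument SNPs (total SNPs must be >= 4).
#' @param n_mediator_snps,n_outcome_snps direct mediator-/outcome-effect SNPs.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100;
#'   effective sizes for binary traits).
#' @param maf_range allele-frequency interval, subset of (0, 0.5].
#' @param gamma_dist list `min`, `max`, `sign` (`"both"` or `"positive"`):
#'   true instrument effect magnitudes are uniform on `[min, max]` with
#'   random or all-positive sign. Also used for direct mediator effects.
#' @param theta_xz,theta_zy,theta_xy_direct true structural effects.
#' @param pleiotropy list `mode` (`"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`), `scale`, `frac` (fraction of exposure
#'   instruments affected). Balanced: `alpha ~ N(0, scale^2)`; directional:
#'   `alpha ~ N(scale, (scale/2)^2)`; inside-violating: alpha correlated
#'   with the instrument strength gamma. Independent draws feed the
#'   mediator and outcome channels.
#' @param n_outlier_snps,outlier_scale planted outcome-channel outliers:
#'   `outlier_scale` times that SNP's outcome SE added to its true outcome
#'   effect (targets for MR-PRESSO).
#' @param outcome_snp_dist list `min`, `max`, `scale`: direct outcome
#'   effects drawn uniform on the beta scale (`scale = "beta"`) or as
#'   z-score multiples of the outcome SE (`scale = "z"`, emulating
#'   detection-margin susceptibility loci), random sign.
#' @param ld_blocks optional list of `list(size =, r2 =)` blocks of
#'   physically adjacent exposure SNPs in mutual LD (clumping tests).
#' @param trait_types length-3 types for exposure/mediator/outcome.
#' @param seed master integer seed; per-trait noise uses derived substreams
#'   so adding a trait never perturbs another trait's draws.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_mediator_snps = 0, n_outcome_snps = 0,
                       n_exposure = 100000, n_mediator = 100000,
                       n_outcome = 200000,
                       maf_range = c(0.1, 0.4),
                       gamma_dist = list(min = 0.05, max = 0.15, sign = "both"),
                       theta_xz = 0, theta_zy = 0, theta_xy_direct = 0,
                       pleiotropy = list(mode = "none", scale = 0.01, frac = 1),
                       n_outlier_snps = 0, outlier_scale = 10,
                       outcome_snp_dist = list(min = 0.05, max = 0.15, scale = "beta"),
                       ld_blocks = NULL,
                       trait_types = c("quantitative", "binary", "binary"),
                       seed = 1L) {
  J <- n_snps + n_mediator_snps + n_outcome_snps
  assert_that(J >= 4, "total SNP count must be >= 4")
  assert_that(all(c(n_exposure, n_mediator, n_outcome) >= 100),
              "sample sizes must be >= 100")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
              maf_range[1] <= maf_range[2], "maf_range must lie within (0, 0.5]")
  pl_default <- list(mode = "none", scale = 0.01, frac = 1)
  pleiotropy <- modifyList(pl_default, pleiotropy)
  assert_that(pleiotropy$mode %in% c("none", "balanced", "directional", "inside_violating"),
              "unknown pleiotropy mode")
  assert_that(n_outlier_snps <= n_snps, "more planted outliers than exposure SNPs")
  structure(list(n_snps = n_snps, n_mediator_snps = n_mediator_snps,
                 n_outcome_snps = n_outcome_snps,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, maf_range = maf_range,
                 gamma_dist = gamma_dist, theta_xz = theta_xz,
                 theta_zy = theta_zy, theta_xy_direct = theta_xy_direct,
                 pleiotropy = pleiotropy, n_outlier_snps = n_outlier_snps,
                 outlier_scale = outlier_scale,
                 outcome_snp_dist = outcome_snp_dist,
                 ld_blocks = ld_blocks, trait_types = trait_types, seed = seed),
            class = "sim_config")
}

draw_effect <- function(n, dist) {
  mag <- runif(n, dist$min, dist$max)
  s <- if (identical(dist$sign %||% "both", "positive")) 1 else
    sample(c(-1, 1), n, replace = TRUE)
  mag * s
}

draw_pleiotropy <- function(n, mode, scale, gamma) {
  switch(mode,
         none = rep(0, n),
         balanced = rnorm(n, 0, scale),
         directional = rnorm(n, scale, scale / 2),
         inside_violating = scale * gamma / mean(abs(gamma)) + rnorm(n, 0, scale / 4))
}

analytic_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Non-palindromic by construction would be unrealistic: allele pairs are
# drawn uniformly from ordered distinct pairs, so ~1/3 are palindromic, as
# in real data; intermediate-frequency ones are then removed downstream.
draw_alleles <- function(J) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1), "")
  list(ea = ea, oa = unname(oa))
}

#' Simulate an exposure/mediator/outcome summary-statistic triplet
#'
#' @param config a [sim_config()].
#' @return list with `exposure`, `mediator`, `outcome`
#'   ([summary_dataset()]s over the same SNPs), `ld` ([ld_matrix()]:
#'   identity except configured blocks), and `truth` (a `truth_record`).
#' @export
simulate_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps + config$n_mediator_snps + config$n_outcome_snps
  seeds <- derive_seeds(config$seed, 4L)
  role <- rep(c("exposure", "mediator", "outcome"),
              c(config$n_snps, config$n_mediator_snps, config$n_outcome_snps))
  is_x <- role == "exposure"; is_z <- role == "mediator"; is_y <- role == "outcome"

  truth <- with_seed(seeds[1], {
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    al <- draw_alleles(J)
    gamma_x <- ifelse(is_x, 1, 0) * draw_effect(J, config$gamma_dist)
    delta_z <- ifelse(is_z, 1, 0) * draw_effect(J, config$gamma_dist)
    se_y <- analytic_se(config$n_outcome, maf)
    od <- config$outcome_snp_dist
    delta_y_raw <- draw_effect(J, od)
    delta_y <- ifelse(is_y, 1, 0) *
      if (identical(od$scale %||% "beta", "z")) delta_y_raw * se_y else delta_y_raw
    pl <- config$pleiotropy
    affected <- rep(FALSE, J)
    xi <- which(is_x)
    if (pl$mode != "none" && length(xi))
      affected[sample(xi, max(0, round(pl$frac * length(xi))))] <- TRUE
    alpha_z <- alpha_y <- rep(0, J)
    if (any(affected)) {
      alpha_z[affected] <- draw_pleiotropy(sum(affected), pl$mode, pl$scale,
                                           gamma_x[affected])
      alpha_y[affected] <- draw_pleiotropy(sum(affected), pl$mode, pl$scale,
                                           gamma_x[affected])
    }
    outlier <- rep(FALSE, J)
    if (config$n_outlier_snps > 0)
      outlier[sample(xi, config$n_outlier_snps)] <- TRUE
    list(maf = maf, al = al, gamma_x = gamma_x, delta_z = delta_z,
         delta_y = delta_y, alpha_z = alpha_z, alpha_y = alpha_y,
         outlier = outlier)
  })

  # genome layout: block SNPs adjacent (50 kb apart) on their own
  # chromosome, the rest far apart so only the configured blocks can clump
  chrom <- character(J); pos <- numeric(J)
  idx <- seq_len(J); b <- 0L
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (blk in config$ld_blocks) {
      b <- b + 1L
      sel <- at:(at + blk$size - 1L)
      chrom[sel] <- as.character(b)
      pos[sel] <- 1e6 + (seq_along(sel) - 1) * 5e4
      at <- at + blk$size
    }
    idx <- setdiff(seq_len(J), seq_len(at - 1L))
  }
  chrom[idx] <- as.character(((seq_along(idx) - 1L) %% 22L) + 1L)
  pos[idx] <- 5e8 + ((seq_along(idx) - 1L) %/% 22L) * 2e7

  snp <- sprintf("rs%06d", seq_len(J))
  b_x <- truth$gamma_x
  b_z <- config$theta_xz * truth$gamma_x + truth$delta_z + truth$alpha_z
  se_y_vec <- analytic_se(config$n_outcome, truth$maf)
  b_y <- config$theta_xy_direct * truth$gamma_x + config$theta_zy * b_z +
    truth$delta_y + truth$alpha_y +
    ifelse(truth$outlier, config$outlier_scale * se_y_vec, 0)

  make_ds <- function(b_true, n, type, name, noise_seed) {
    se <- analytic_se(n, truth$maf)
    obs <- with_seed(noise_seed, b_true + rnorm(J, 0, se))
    summary_dataset(data.frame(snp = snp, chr = chrom, pos = pos,
                               ea = truth$al$ea, oa = truth$al$oa,
                               eaf = truth$maf, beta = obs, se = se,
                               p = two_sided_p_norm(obs / se), n = n,
                               stringsAsFactors = FALSE),
                    trait_name = name, trait_type = type)
  }
  exposure <- make_ds(b_x, config$n_exposure, config$trait_types[1], "exposure", seeds[2])
  mediator <- make_ds(b_z, config$n_mediator, config$trait_types[2], "mediator", seeds[3])
  outcome <- make_ds(b_y, config$n_outcome, config$trait_types[3], "outcome", seeds[4])

  r2 <- diag(J)
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (blk in config$ld_blocks) {
      sel <- at:(at + blk$size - 1L)
      r2[sel, sel] <- blk$r2
      at <- at + blk$size
    }
    diag(r2) <- 1
  }
  dimnames(r2) <- list(snp, snp)

  implied_total <- config$theta_xy_direct + config$theta_xz * config$theta_zy
  truth_rec <- structure(list(
    per_snp = data.frame(snp = snp, role = role, maf = truth$maf,
                         gamma_x = truth$gamma_x, delta_z = truth$delta_z,
                         delta_y = truth$delta_y, alpha_z = truth$alpha_z,
                         alpha_y = truth$alpha_y, outlier = truth$outlier,
                         stringsAsFactors = FALSE),
    theta_xz = config$theta_xz, theta_zy = config$theta_zy,
    theta_direct = config$theta_xy_direct,
    implied_total = implied_total,
    implied_proportion = if (implied_total == 0) NA_real_ else
      100 * config$theta_xz * config$theta_zy / implied_total),
    class = "truth_record")

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld_matrix(r2), truth = truth_rec)
}

#' Simulate under the global null (all structural effects zero)
#'
#' Instruments keep their nonzero effects on the exposure, but
#' `theta_xz = theta_zy = theta_xy_direct = 0`, so every causal test's
#' rejection is a type-I error. Used for calibration suites.
#'
#' @param config a [sim_config()]; its thetas are overridden to zero.
#' @return as [simulate_triplet()] (truth `implied_total` is exactly 0).
#' @export
simulate_null <- function(config) {
  config$theta_xz <- 0; config$theta_zy <- 0; config$theta_xy_direct <- 0
  simulate_triplet(config)
}

#' Packaged scenario shaped like the motivating LDL-C / CAD / HCC study
#'
#' True effects: exposure-on-mediator `log(2.103)`, adjusted
#' mediator-on-outcome `-0.277`, direct exposure-on-outcome `-0.146`; the
#' implied total effect is `-0.352` (= `log(0.703)` to 3 dp) and the implied
#' proportion mediated ~58.5%. Sample sizes mirror the source GWAS at
#' effective scale: 72,866 (quantitative exposure), ~101,000 (mediator,
#' effective size of a 29,319-case/183,134-control GWAS) and ~7,400
#' (outcome, effective size of a 1,866-case/195,745-control GWAS). Direct
#' outcome loci are drawn at the detection margin (|z| in 3.6-4.8) so a
#' reverse-direction analysis typically needs the relaxed p-value
#' threshold, as a small-case-count outcome GWAS does in practice.
#'
#' @param n_snps,n_mediator_snps,n_outcome_snps SNP counts (defaults 100/100/15).
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
paper_shaped_scenario <- function(n_snps = 100, n_mediator_snps = 100,
                                  n_outcome_snps = 15, seed = 1L) {
  sim_config(n_snps = n_snps, n_mediator_snps = n_mediator_snps,
             n_outcome_snps = n_outcome_snps,
             n_exposure = 72866, n_mediator = 101000, n_outcome = 7400,
             theta_xz = log(2.103), theta_zy = -0.277, theta_xy_direct = -0.146,
             pleiotropy = list(mode = "balanced", scale = 0.005, frac = 0.5),
             outcome_snp_dist = list(min = 3.6, max = 4.8, scale = "z"),
             trait_types = c("quantitative", "binary", "binary"),
             seed = seed)
}
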