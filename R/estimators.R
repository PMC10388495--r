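# Two-sample MR estimators: per-SNP Wald ratios, IVW (fixed/random effects),
# MR-Egger, weighted median, and the simple/weighted mode estimators.
# All operate on a harmonized_set; causal effects for binary outcomes are on
# the log-odds scale and are reported alongside OR and 95% CI.

new_mr_result <- function(method, beta, se, pvalue, n_snps, df = Inf, extras = list()) {
  crit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
                 pvalue = pvalue, n_snps = n_snps, extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta = %.4f (se %.4f), OR = %s, p = %.3g, J = %d\n",
              x$method, x$beta, x$se,
              format_or(x$or, x$or_low, x$or_high), x$pvalue, x$n_snps))
  invisible(x)
}

#' Coerce an MR result to a one-row data frame
#' @param x an `mr_result`.
#' @param ... unused.
#' @return one-row data.frame (method, n_snps, beta, se, CI, OR, p).
#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             or = x$or, or_low = x$or_low, or_high = x$or_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The building block of all summary-data MR estimators: `beta_j =
#' Gamma_j / gamma_j` with first-order standard error
#' `se_j = se_Gamma_j / |gamma_j|` (the approximation implied by IVW
#' weighting, which conditions on the exposure betas).
#'
#' @param h a `harmonized_set`; every `gamma` must be nonzero.
#' @return data.frame with `snp`, `beta`, `se`.
#' @export
wald_ratios <- function(h) {
  assert_that(all(h$gamma != 0), "wald_ratios: zero exposure beta(s) present")
  data.frame(snp = h$snp_ids, beta = h$Gamma / h$gamma,
             se = h$se_Gamma / abs(h$gamma), stringsAsFactors = FALSE)
}

ivw_weights <- function(h) 1 / h$se_Gamma^2

ivw_point <- function(h) {
  w <- ivw_weights(h)
  sum(w * h$gamma * h$Gamma) / sum(w * h$gamma^2)
}

#' Inverse-variance weighted estimate
#'
#' Weighted combination of Wald ratios, equivalent to weighted least squares
#' of outcome betas on exposure betas through the origin with weights
#' `1/se_Gamma^2`. The random-effects variant uses multiplicative
#' overdispersion: the fixed-effects SE is scaled by
#' `max(1, sqrt(Q/(J-1)))`, so it nests the fixed-effects model when there
#' is no excess heterogeneity. Inference is normal-based.
#'
#' @param h a `harmonized_set` with J >= 2.
#' @param effects `"random"` (default, the primary analysis model) or
#'   `"fixed"`.
#' @return an `mr_result`; `extras$scale` holds the overdispersion factor,
#'   `extras$q` Cochran's Q at the estimate.
#' @export
mr_ivw <- function(h, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  J <- length(h$gamma)
  if (J < 2)
    stop("mr_ivw requires J >= 2 instruments; use wald_ratios for a single SNP",
         call. = FALSE)
  w <- ivw_weights(h)
  denom <- sum(w * h$gamma^2)
  beta <- sum(w * h$gamma * h$Gamma) / denom
  se_fixed <- sqrt(1 / denom)
  q <- sum(w * (h$Gamma - beta * h$gamma)^2)
  scale <- if (effects == "random") max(1, sqrt(q / (J - 1))) else 1
  se <- se_fixed * scale
  p <- two_sided_p_norm(beta / se)
  new_mr_result(if (effects == "random") "ivw_re" else "ivw_fe",
                beta, se, p, J, extras = list(q = q, scale = scale))
}

# Orient instruments so every exposure beta is non-negative (joint sign flip
# of gamma_j and Gamma_j leaves the causal model invariant).
orient_positive <- function(h) {
  s <- sign(h$gamma)
  s[s == 0] <- 1
  h$Gamma <- h$Gamma * s
  h$gamma <- h$gamma * s
  h
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas WITH an
#' intercept (weights `1/se_Gamma^2`), after orienting every instrument so
#' its exposure beta is non-negative. The slope estimates the causal effect;
#' the intercept estimates average directional pleiotropy and is the basis
#' of the Egger pleiotropy test. SEs carry a multiplicative overdispersion
#' factor floored at 1; inference uses t with J-2 degrees of freedom.
#'
#' @param h a `harmonized_set` with J >= 3.
#' @return an `mr_result`; `extras` holds `intercept`, `intercept_se`,
#'   `intercept_p`, `q` (Egger heterogeneity) and `scale`.
#' @export
mr_egger <- function(h) {
  J <- length(h$gamma)
  if (J < 3) stop("mr_egger requires J >= 3 instruments", call. = FALSE)
  ho <- orient_positive(h)
  w <- 1 / ho$se_Gamma^2
  X <- cbind(1, ho$gamma)
  A <- crossprod(X, w * X)
  bhat <- solve(A, crossprod(X, w * ho$Gamma))
  resid <- ho$Gamma - X %*% bhat
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (J - 2)))
  ses <- sqrt(diag(solve(A))) * scale
  slope <- bhat[2]; intercept <- bhat[1]
  p_slope <- two_sided_p_t(slope / ses[2], J - 2)
  p_int <- two_sided_p_t(intercept / ses[1], J - 2)
  new_mr_result("egger", slope, ses[2], p_slope, J, df = J - 2,
                extras = list(intercept = intercept, intercept_se = ses[1],
                              intercept_p = p_int, q = q, scale = scale))
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(h, n_boot, seed, point_fun) {
  with_seed(seed, {
    J <- length(h$gamma)
    est <- vapply(seq_len(n_boot), function(i) {
      g <- rnorm(J, h$gamma, h$se_gamma)
      G <- rnorm(J, h$Gamma, h$se_Gamma)
      point_fun(g, G)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted median estimator
#'
#' Median of the ordered Wald ratios under inverse-variance weights
#' `w_j = gamma_j^2 / se_Gamma_j^2` (midpoint convention: the weighted
#' empirical CDF is interpolated at 0.5). Consistent when valid instruments
#' carry at least half the weight. The SE comes from a seeded parametric
#' bootstrap resampling both exposure and outcome betas from their reported
#' normal sampling distributions.
#'
#' @param h a `harmonized_set` with J >= 3.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed (mandatory: SEs must be reproducible).
#' @return an `mr_result`; `extras$n_boot` records the replicate count.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed) {
  J <- length(h$gamma)
  if (J < 3) stop("mr_weighted_median requires J >= 3 instruments", call. = FALSE)
  # deterministic tie-break: pre-sort instruments by snp id
  ordid <- order(h$snp_ids)
  h <- subset_harmonized(h, ordid)
  point <- function(g, G) weighted_median_point(G / g, g^2 / h$se_Gamma^2)
  beta <- point(h$gamma, h$Gamma)
  se <- boot_se(h, n_boot, seed, point)
  p <- two_sided_p_norm(beta / se)
  new_mr_result("weighted_median", beta, se, p, J,
                extras = list(n_boot = n_boot))
}

mode_point <- function(ratio, weight, phi) {
  s <- min(sd(ratio), (quantile(ratio, 0.75, names = FALSE) -
                       quantile(ratio, 0.25, names = FALSE)) / 1.349)
  bw <- phi * 0.9 * s * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])  # all ratios identical
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512)
  dens <- vapply(grid, function(x)
    sum(weight * exp(-0.5 * ((x - ratio) / bw)^2)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator (simple or weighted mode)
#'
#' The mode of the kernel-smoothed Wald-ratio distribution, consistent when
#' the largest homogeneous subset of instruments is valid. Normal kernel
#' with bandwidth `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)` on the ratio
#' estimates, evaluated on a 512-point grid spanning the ratio range padded
#' by three bandwidths. The simple mode weights each ratio equally; the
#' weighted mode weights it by inverse variance. SE via seeded parametric
#' bootstrap.
#'
#' @param h a `harmonized_set` with J >= 3.
#' @param weighted use inverse-variance weights in the density (default TRUE).
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @return an `mr_result`.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 5000, seed) {
  J <- length(h$gamma)
  if (J < 3) stop("mr_mode requires J >= 3 instruments", call. = FALSE)
  wfun <- if (weighted) function(g, seG) g^2 / seG^2 else function(g, seG) rep(1, length(g))
  point <- function(g, G) mode_point(G / g, wfun(g, h$se_Gamma), phi)
  beta <- point(h$gamma, h$Gamma)
  se <- boot_se(h, n_boot, seed, point)
  p <- two_sided_p_norm(beta / se)
  new_mr_result(if (weighted) "weighted_mode" else "simple_mode",
                beta, se, p, J, extras = list(n_boot = n_boot, phi = phi))
}

#' Odds ratio and 95\% confidence interval from a log-odds effect
#' @param beta effect on the log-odds scale.
#' @param se its standard error (> 0).
#' @return named vector `or`, `or_low`, `or_high`.
#' @export
or_from_beta <- function(beta, se) {
  assert_that(all(se > 0), "se must be > 0")
  crit <- qnorm(0.975)
  c(or = exp(beta), or_low = exp(beta - crit * se), or_high = exp(beta + crit * se))
}

#' Run the standard battery of five MR estimators
#'
#' Random-effects IVW (the primary analysis), MR-Egger, weighted median,
#' simple mode and weighted mode on one harmonized set; methods whose
#' minimum instrument count is not met are skipped with a message.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param phi mode bandwidth multiplier.
#' @param seed integer seed for the bootstrap SEs.
#' @param methods subset of
#'   `c("ivw_re","egger","weighted_median","simple_mode","weighted_mode")`.
#' @return named list of `mr_result`s.
#' @export
mr_all <- function(h, n_boot = 5000, phi = 1, seed,
                   methods = c("ivw_re", "egger", "weighted_median",
                               "simple_mode", "weighted_mode")) {
  J <- length(h$gamma)
  out <- list()
  run <- function(name, min_j, fun) {
    if (!(name %in% methods)) return()
    if (J < min_j) { message(sprintf("mr_all: skipping %s (J = %d < %d)", name, J, min_j)); return() }
    out[[name]] <<- fun()
  }
  run("ivw_re", 2, function() mr_ivw(h, "random"))
  run("egger", 3, function() mr_egger(h))
  run("weighted_median", 3, function() mr_weighted_median(h, n_boot, seed))
  run("simple_mode", 3, function() mr_mode(h, weighted = FALSE, phi = phi,
                                           n_boot = n_boot, seed = seed))
  run("weighted_mode", 3, function() mr_mode(h, weighted = TRUE, phi = phi,
                                             n_boot = n_boot, seed = seed))
  out
}
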